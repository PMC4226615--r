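#' Strand-bias model for the simulator
#'
#' The generative counterpart of the observed coverage bias: plus-strand
#' sampling intensity is down-weighted as a monotone non-increasing function
#' of local two-letter base-class content, while the minus strand keeps
#' weight 1.  The mechanism behind the real bias (amplification enzymes) is
#' not modelled; the weight function is user-supplied.
#'
#' @param pair_class Two-letter base class driving the bias (e.g. `"AC"`).
#' @param window Width (nt) of the centered window over which local content
#'   is measured; default 150, matching the analysis bin width.
#' @param weight_fn Vectorized function mapping content fraction in
#'   \[0, 1\] to a plus-strand weight in \[0, 1\]; must satisfy
#'   `weight_fn(0) == 1` and be non-increasing.
#' @return An object of class `bias_model`.
#' @seealso [step_weight()] for the step function used throughout the
#'   examples and tests.
#' @export
bias_model <- function(pair_class, window = 150L, weight_fn) {
  pair_class <- toupper(pair_class)
  stopifnot(pair_class %in% PAIR_CLASSES, is.function(weight_fn))
  grid <- seq(0, 1, by = 0.01)
  w <- vapply(grid, function(g) as.numeric(weight_fn(g)[1]), numeric(1))
  if (any(w < -1e-9 | w > 1 + 1e-9)) {
    stop("weight_fn must map [0, 1] into [0, 1]")
  }
  if (abs(w[1] - 1) > 1e-9) stop("weight_fn(0) must equal 1")
  if (any(diff(w) > 1e-9)) stop("weight_fn must be non-increasing")
  structure(list(pair_class = pair_class, window = as.integer(window),
                 weight_fn = weight_fn),
            class = "bias_model")
}

#' Step weight function for bias models
#'
#' Weight 1 below the content threshold, `low` at or above it.
#'
#' @param threshold Content fraction at which suppression sets in.
#' @param low Plus-strand weight at or above the threshold.
#' @return A vectorized weight function.
#' @export
step_weight <- function(threshold = 0.8, low = 0.02) {
  force(threshold); force(low)
  function(content) ifelse(content < threshold, 1, low)
}

#' Simulation configuration
#'
#' @param mean_depth Expected total (plus + minus) read depth per position.
#' @param error_rate Per-sequenced-base substitution probability in
#'   \[0, 0.05\]; each erroneous base is replaced uniformly by one of the
#'   three other bases.
#' @param variants `NULL` or a `data.frame` with columns `position`
#'   (1-based), `ref`, `alt` (single bases) and `fraction` (allele fraction
#'   in \[0, 1\]).
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mean_depth, error_rate = 0, variants = NULL,
                       seed = 1L) {
  stopifnot(is.numeric(mean_depth), mean_depth > 0,
            is.numeric(error_rate), error_rate >= 0, error_rate <= 0.05)
  if (!is.null(variants)) {
    stopifnot(is.data.frame(variants),
              all(c("position", "ref", "alt", "fraction") %in%
                    names(variants)))
    stopifnot(all(variants$fraction >= 0 & variants$fraction <= 1),
              all(toupper(variants$ref) %in% BASES),
              all(toupper(variants$alt) %in% BASES))
  }
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 variants = variants, seed = as.integer(seed)),
            class = "sim_config")
}

new_base_counts <- function(plus, minus, ref_name, L) {
  stopifnot(is.matrix(plus), is.matrix(minus),
            nrow(plus) == L, nrow(minus) == L,
            ncol(plus) == 4L, ncol(minus) == 4L)
  colnames(plus) <- colnames(minus) <- BASES
  structure(list(plus = plus, minus = minus, ref_name = ref_name,
                 genome_length = L),
            class = "base_counts")
}

#' @export
print.base_counts <- function(x, ...) {
  cat(sprintf("<base_counts> %s: %d positions, mean depth %.1f (+%.1f/-%.1f)\n",
              x$ref_name, x$genome_length,
              mean(rowSums(x$plus) + rowSums(x$minus)),
              mean(rowSums(x$plus)), mean(rowSums(x$minus))))
  invisible(x)
}

# Substitute errors out of one source-base count vector: n errors per
# position are split uniformly over the three alternative bases.
scatter_errors <- function(n) {
  x1 <- rbinom(length(n), n, 1 / 3)
  x2 <- rbinom(length(n), n - x1, 1 / 2)
  cbind(x1, x2, n - x1 - x2)
}

#' Simulate strand-resolved per-position base counts
#'
#' Pileup-level generative model of LR-PCR-amplified mtDNA resequencing.
#' Per position, plus- and minus-strand depths are independent Poisson draws
#' with rates `mean_depth / 2 * w` and `mean_depth / 2`, where `w` is the
#' bias model's weight at the local base-class content (`w = 1` everywhere
#' when `bias` is `NULL`, giving an expected total depth of `mean_depth`
#' split 50/50).  Heteroplasmic alt alleles are assigned per read at their
#' target fractions, then each sequenced base is substituted uniformly to
#' one of the three other bases with probability `error_rate`.  Substitution
#' errors only: indel and homopolymer error modes are out of scope.
#'
#' @param ref A [reference_genome()].
#' @param cfg A [sim_config()].
#' @param bias A [bias_model()] or `NULL` for unbiased sampling.
#' @return A list with elements `counts` (a `base_counts` object) and
#'   `manifest` (a `truth_manifest`: config echo, realized per-variant
#'   allele fractions, realized genome-wide error rate).
#' @examples
#' ref <- generate_reference(1000, data.frame(pair_class = "GC",
#'   target = 0.5, length = 1000), seed = 1)
#' sim <- simulate_base_counts(ref, sim_config(100, error_rate = 0, seed = 1))
#' mean(rowSums(sim$counts$plus) + rowSums(sim$counts$minus))
#' @export
simulate_base_counts <- function(ref, cfg, bias = NULL) {
  stopifnot(inherits(ref, "reference_genome"), inherits(cfg, "sim_config"))
  if (!is.null(bias)) stopifnot(inherits(bias, "bias_model"))
  L <- length(ref)
  chars <- ref_chars(ref)
  ref_idx <- match(chars, BASES)
  vars <- cfg$variants
  if (!is.null(vars) && nrow(vars) > 0) {
    vars$position <- as.integer(vars$position)
    vars$ref <- toupper(vars$ref); vars$alt <- toupper(vars$alt)
    if (any(vars$position < 1L | vars$position > L)) {
      stop("variant position outside the genome (length ", L, ")")
    }
    mism <- chars[vars$position] != vars$ref
    if (any(mism)) {
      stop("variant ref base mismatch at position ",
           vars$position[which(mism)[1]], ": reference has '",
           chars[vars$position[which(mism)[1]]], "'")
    }
    if (anyDuplicated(vars$position)) {
      stop("duplicate variant positions are not supported")
    }
  }

  set.seed(cfg$seed)
  w <- if (is.null(bias)) {
    rep(1, L)
  } else {
    content <- local_pair_content(ref, bias$pair_class, bias$window)
    pmin(pmax(as.numeric(bias$weight_fn(content)), 0), 1)
  }
  d_plus <- rpois(L, cfg$mean_depth / 2 * w)
  d_minus <- rpois(L, cfg$mean_depth / 2)

  counts <- list(plus = matrix(0L, L, 4L), minus = matrix(0L, L, 4L))
  realized <- NULL
  for (s in c("plus", "minus")) {
    depth <- if (s == "plus") d_plus else d_minus
    m <- counts[[s]]
    m[cbind(seq_len(L), ref_idx)] <- depth
    if (!is.null(vars) && nrow(vars) > 0) {
      alt_n <- rbinom(nrow(vars), depth[vars$position], vars$fraction)
      p <- vars$position
      m[cbind(p, match(vars$ref, BASES))] <-
        m[cbind(p, match(vars$ref, BASES))] - alt_n
      m[cbind(p, match(vars$alt, BASES))] <-
        m[cbind(p, match(vars$alt, BASES))] + alt_n
      realized <- if (is.null(realized)) alt_n else realized + alt_n
    }
    counts[[s]] <- m
  }

  n_errors <- 0L
  if (cfg$error_rate > 0) {
    for (s in c("plus", "minus")) {
      m <- counts[[s]]
      for (b in 1:4) {
        err <- rbinom(L, m[, b], cfg$error_rate)
        if (!any(err > 0)) next
        n_errors <- n_errors + sum(err)
        m[, b] <- m[, b] - err
        dest <- setdiff(1:4, b)
        m[, dest] <- m[, dest] + scatter_errors(err)
      }
      counts[[s]] <- m
    }
  }

  bc <- new_base_counts(counts$plus, counts$minus, ref$name, L)
  total_bases <- sum(d_plus) + sum(d_minus)
  manifest_vars <- if (!is.null(vars) && nrow(vars) > 0) {
    depth_at <- d_plus[vars$position] + d_minus[vars$position]
    data.frame(position = vars$position, ref = vars$ref, alt = vars$alt,
               target_fraction = vars$fraction,
               realized_fraction = ifelse(depth_at > 0,
                                          realized / depth_at, NA_real_))
  } else {
    data.frame(position = integer(0), ref = character(0),
               alt = character(0), target_fraction = numeric(0),
               realized_fraction = numeric(0))
  }
  manifest <- structure(list(
    reference = ref$name,
    genome_length = L,
    mean_depth = cfg$mean_depth,
    error_rate = cfg$error_rate,
    seed = cfg$seed,
    bias = if (is.null(bias)) NULL else
      list(pair_class = bias$pair_class, window = bias$window),
    variants = manifest_vars,
    realized_mean_depth = total_bases / L,
    realized_error_rate = if (total_bases > 0) n_errors / total_bases else 0
  ), class = "truth_manifest")
  list(counts = bc, manifest = manifest)
}

#' Simulate individual reads and their alignments (read-level mode)
#'
#' Alternative to the pileup-level model of [simulate_base_counts()]:
#' fixed-length single-end reads with uniform start positions, strand chosen
#' by the bias weight at the read centre, heteroplasmic alleles and
#' substitution errors applied per read base.  Reads are not wrapped across
#' the circular origin (start positions are confined to
#' `[1, L - read_length + 1]`), so the pileup-level model remains the
#' default for circular analyses.  Use [write_sam()] to emit the reads as a
#' SAM file for [depth_from_alignments()] round-trips.
#'
#' @inheritParams simulate_base_counts
#' @param read_length Read length (nt); the number of reads is
#'   `round(mean_depth * L / read_length)`.
#' @return A list with `reads` (a `data.frame`: `qname`, `flag`, `pos`,
#'   `cigar`, `seq`), `depth` (a `strand_depth` profile the reads imply)
#'   and `n_reads`.
#' @export
simulate_reads <- function(ref, cfg, bias = NULL, read_length = 150L) {
  stopifnot(inherits(ref, "reference_genome"), inherits(cfg, "sim_config"))
  L <- length(ref)
  read_length <- as.integer(read_length)
  if (read_length > L) stop("read_length exceeds the genome length")
  set.seed(cfg$seed)
  n_reads <- max(1L, as.integer(round(cfg$mean_depth * L / read_length)))
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  centers <- starts + read_length %/% 2L
  w <- if (is.null(bias)) {
    rep(1, n_reads)
  } else {
    content <- local_pair_content(ref, bias$pair_class, bias$window)
    pmin(pmax(as.numeric(bias$weight_fn(content[centers])), 0), 1)
  }
  is_plus <- runif(n_reads) < w / (1 + w)

  chars <- ref_chars(ref)
  vars <- cfg$variants
  var_at <- integer(0)
  if (!is.null(vars) && nrow(vars) > 0) {
    var_at <- setNames(seq_len(nrow(vars)), vars$position)
  }
  seqs <- vapply(seq_len(n_reads), function(i) {
    idx <- starts[i]:(starts[i] + read_length - 1L)
    b <- chars[idx]
    if (length(var_at)) {
      hit <- which(as.character(idx) %in% names(var_at))
      for (h in hit) {
        v <- var_at[[as.character(idx[h])]]
        if (runif(1) < vars$fraction[v]) b[h] <- toupper(vars$alt[v])
      }
    }
    if (cfg$error_rate > 0) {
      err <- which(runif(read_length) < cfg$error_rate)
      for (e in err) b[e] <- sample(setdiff(BASES, b[e]), 1L)
    }
    paste(b, collapse = "")
  }, character(1))

  d_plus <- integer(L); d_minus <- integer(L)
  for (i in seq_len(n_reads)) {
    idx <- starts[i]:(starts[i] + read_length - 1L)
    if (is_plus[i]) d_plus[idx] <- d_plus[idx] + 1L
    else d_minus[idx] <- d_minus[idx] + 1L
  }
  reads <- data.frame(
    qname = sprintf("read%06d", seq_len(n_reads)),
    flag = ifelse(is_plus, 0L, 16L),
    pos = starts,
    cigar = paste0(read_length, "M"),
    seq = seqs,
    stringsAsFactors = FALSE
  )
  list(reads = reads,
       depth = strand_depth(d_plus, d_minus),
       n_reads = n_reads)
}
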