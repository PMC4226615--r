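#' Strand-resolved depth profile
#'
#' @param plus_depth,minus_depth Integer vectors of per-position read depth
#'   on the plus (reference / light) and minus (heavy) strand.
#' @return An object of class `strand_depth`.
#' @export
strand_depth <- function(plus_depth, minus_depth) {
  stopifnot(length(plus_depth) == length(minus_depth),
            all(plus_depth >= 0), all(minus_depth >= 0))
  structure(list(plus_depth = as.numeric(plus_depth),
                 minus_depth = as.numeric(minus_depth),
                 genome_length = length(plus_depth)),
            class = "strand_depth")
}

#' Construct a strand-resolved base-count matrix
#'
#' @param plus,minus Numeric matrices (positions x 4, columns A, C, G, T)
#'   of observed base counts per strand.
#' @param ref_name Reference label.
#' @return An object of class `base_counts`.
#' @export
base_counts <- function(plus, minus, ref_name = "ref") {
  plus <- as.matrix(plus); minus <- as.matrix(minus)
  new_base_counts(plus, minus, ref_name, nrow(plus))
}

#' Depth profile implied by a base-count matrix
#'
#' @param counts A `base_counts` object.
#' @return A [strand_depth()] profile (row sums per strand).
#' @export
depth_from_counts <- function(counts) {
  stopifnot(inherits(counts, "base_counts"))
  strand_depth(rowSums(counts$plus), rowSums(counts$minus))
}

sam_to_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                     overwrite = TRUE, indexDestination = TRUE)
  } else {
    if (!file.exists(paste0(path, ".bai"))) {
      Rsamtools::indexBam(path)
    }
    path
  }
}

check_reference_name <- function(bam, ref) {
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!ref$name %in% names(targets)) {
    stop("reference '", ref$name, "' not found in alignment file; ",
         "file declares: ", paste(names(targets), collapse = ", "))
  }
  invisible(targets[[ref$name]])
}

#' Read mapped primary alignments from a SAM/BAM file
#'
#' Yields mapped, primary, non-supplementary records.  SAM input is
#' converted to sorted, indexed BAM in a temporary file.
#'
#' @param path SAM or BAM file.
#' @return An object of class `alignment_stream`: a list with `path` (the
#'   BAM actually read), `records` (a `data.frame` with `qname`, `flag`,
#'   `rname`, `strand`, `pos`, `cigar`) and `n_skipped` (unmapped or
#'   non-primary records dropped).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- sam_to_bam(path)
  param_all <- Rsamtools::ScanBamParam(what = "flag")
  n_total <- length(Rsamtools::scanBam(bam, param = param_all)[[1]]$flag)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  records <- data.frame(qname = rec$qname, flag = rec$flag,
                        rname = as.character(rec$rname),
                        strand = as.character(rec$strand),
                        pos = rec$pos, cigar = rec$cigar,
                        stringsAsFactors = FALSE)
  n_skipped <- n_total - nrow(records)
  if (n_skipped > 0) {
    message(n_skipped, " unmapped or non-primary record(s) skipped")
  }
  structure(list(path = bam, records = records, n_skipped = n_skipped),
            class = "alignment_stream")
}

#' Strand-resolved depth and base counts from alignments
#'
#' Counts, at every reference position, the aligned read bases per strand.
#' A read contributes to the plus profile if it aligned to the forward
#' strand, else to the minus profile.  Counting is base-level: reference
#' positions deleted in a read add to neither the base counts nor the depth
#' (the error index downstream divides by observed bases).  Unmapped,
#' secondary and supplementary records are skipped.
#'
#' @param alignments Path to a SAM/BAM file or an [read_alignments()]
#'   stream.
#' @param ref A [reference_genome()]; its name must match the alignment
#'   file's reference.
#' @return A list with `depth` (a [strand_depth()]) and `counts` (a
#'   `base_counts` object).
#' @export
depth_from_alignments <- function(alignments, ref) {
  stopifnot(inherits(ref, "reference_genome"))
  bam <- if (inherits(alignments, "alignment_stream")) {
    alignments$path
  } else {
    if (!file.exists(alignments)) {
      stop("alignment file not found: ", alignments)
    }
    sam_to_bam(alignments)
  }
  check_reference_name(bam, ref)
  L <- length(ref)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(flag = flag),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 1000000L, min_base_quality = 0L, min_mapq = 0L,
      min_nucleotide_depth = 1L, distinguish_strands = TRUE,
      distinguish_nucleotides = TRUE, include_deletions = FALSE,
      include_insertions = FALSE))
  p <- p[as.character(p$seqnames) == ref$name &
           as.character(p$nucleotide) %in% BASES, , drop = FALSE]
  plus <- matrix(0L, L, 4L); minus <- matrix(0L, L, 4L)
  if (nrow(p) > 0) {
    if (any(p$pos > L)) {
      stop("pileup position beyond the declared genome length ", L)
    }
    nuc <- match(as.character(p$nucleotide), BASES)
    is_plus <- as.character(p$strand) == "+"
    idx_p <- cbind(p$pos[is_plus], nuc[is_plus])
    idx_m <- cbind(p$pos[!is_plus], nuc[!is_plus])
    # positions are unique per (strand, nucleotide) in pileup output
    plus[idx_p] <- plus[idx_p] + p$count[is_plus]
    minus[idx_m] <- minus[idx_m] + p$count[!is_plus]
  }
  counts <- new_base_counts(plus, minus, ref$name, L)
  list(depth = depth_from_counts(counts), counts = counts)
}

#' Relative coverage per position and strand
#'
#' Relative coverage at a position is its read depth divided by the mean
#' depth over all reference positions; it is computed for the pooled total
#' and for each strand separately, each series normalized by its own mean.
#' By construction the mean of every defined series is exactly 1.
#'
#' @param depth A [strand_depth()] profile (or a `base_counts` object).
#' @return An object of class `relative_coverage`: list with `rc_total`,
#'   `rc_plus`, `rc_minus` (a series whose strand has zero coverage
#'   everywhere is `NULL`, flagged in `undefined`) and `denominators`, the
#'   three mean depths used.
#' @examples
#' rc <- relative_coverage(strand_depth(c(10, 0, 30), c(10, 10, 10)))
#' rc$rc_plus  # 0.75 0.00 2.25
#' @export
relative_coverage <- function(depth) {
  if (inherits(depth, "base_counts")) depth <- depth_from_counts(depth)
  stopifnot(inherits(depth, "strand_depth"))
  total <- depth$plus_depth + depth$minus_depth
  series <- list(total = total, plus = depth$plus_depth,
                 minus = depth$minus_depth)
  denominators <- vapply(series, mean, numeric(1))
  out <- list(rc_total = NULL, rc_plus = NULL, rc_minus = NULL)
  undefined <- character(0)
  for (nm in names(series)) {
    if (denominators[[nm]] > 0) {
      out[[paste0("rc_", nm)]] <- series[[nm]] / denominators[[nm]]
    } else {
      undefined <- c(undefined, nm)
    }
  }
  if ("total" %in% undefined) {
    stop("all positions have zero depth; relative coverage is undefined")
  }
  out$denominators <- denominators
  out$undefined <- undefined
  out$genome_length <- depth$genome_length
  structure(out, class = "relative_coverage")
}

#' @export
print.relative_coverage <- function(x, ...) {
  cat(sprintf(
    "<relative_coverage> %d positions; mean depth %.1f (+%.1f/-%.1f)\n",
    x$genome_length, x$denominators[["total"]],
    x$denominators[["plus"]], x$denominators[["minus"]]))
  if (length(x$undefined)) {
    cat("  undefined series:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

frac_below <- function(x, thr) 100 * mean(x < thr)

#' Coverage-fraction threshold table
#'
#' For each relative-coverage threshold, the percentage of positions whose
#' relative coverage is strictly below it, per series (Total / Plus / Min).
#' With the default thresholds this is the standard QC table for comparing
#' library preparations: e.g. the percentage of the genome whose plus-strand
#' relative coverage falls below 0.10 quantifies strand dropout.
#'
#' @param rc A [relative_coverage()] profile, or a bare numeric vector
#'   (treated as a single `Total` series).
#' @param thresholds Strictly descending thresholds in (0, 1); default
#'   `c(0.50, 0.25, 0.10, 0.05, 0.01)`.
#' @return A `data.frame` of class `coverage_fraction_table` with column
#'   `threshold` and one percentage column per defined series.  Full
#'   precision is retained; `print()` rounds to two decimals.
#' @export
coverage_fraction_table <- function(rc,
                                    thresholds = c(0.50, 0.25, 0.10,
                                                   0.05, 0.01)) {
  stopifnot(length(thresholds) >= 1,
            all(thresholds > 0), all(thresholds < 1),
            all(diff(thresholds) < 0))
  if (is.numeric(rc)) {
    series <- list(Total = rc)
  } else {
    stopifnot(inherits(rc, "relative_coverage"))
    series <- list(Total = rc$rc_total, Plus = rc$rc_plus,
                   Min = rc$rc_minus)
    series <- series[!vapply(series, is.null, logical(1))]
  }
  out <- data.frame(threshold = thresholds)
  for (nm in names(series)) {
    out[[nm]] <- vapply(thresholds, function(t) frac_below(series[[nm]], t),
                        numeric(1))
  }
  structure(out, class = c("coverage_fraction_table", "data.frame"))
}

#' @export
print.coverage_fraction_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$threshold <- sprintf("<%.2f", y$threshold)
  for (nm in setdiff(names(y), "threshold")) {
    y[[nm]] <- sprintf("%.2f", y[[nm]])
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Down-sample a base-count matrix to a target mean depth
#'
#' Per-base binomial thinning: every observed base is kept independently
#' with probability `target_mean / current_mean`, so strand and base
#' proportions are preserved in expectation.  This is the pileup-level
#' analogue of read subsampling, used to put datasets of different depth on
#' a comparable footing (e.g. a mean of 3000) before coverage analysis.
#'
#' @param counts A `base_counts` object.
#' @param target_mean Target mean total depth; must not exceed the current
#'   mean (otherwise the input is returned unchanged with a warning).
#' @param seed Integer seed.
#' @return A thinned `base_counts` object.
#' @export
downsample_counts <- function(counts, target_mean, seed = 1L) {
  stopifnot(inherits(counts, "base_counts"), target_mean > 0)
  current <- (sum(counts$plus) + sum(counts$minus)) / counts$genome_length
  if (target_mean > current) {
    warning("target mean ", target_mean, " exceeds current mean ",
            round(current, 2), "; input returned unchanged")
    return(counts)
  }
  p <- target_mean / current
  set.seed(as.integer(seed))
  thin <- function(m) {
    v <- as.integer(m)
    matrix(rbinom(length(v), v, p), nrow = nrow(m))
  }
  new_base_counts(thin(counts$plus), thin(counts$minus),
                  counts$ref_name, counts$genome_length)
}
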