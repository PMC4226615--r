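#' Construct a (circular) reference genome
#'
#' A lightweight container for a single reference sequence.  The human
#' mitochondrial genome, the main use case, is a 16,569-bp circular
#' molecule whose reference (rCRS) strand is the C-rich light strand; all
#' coordinates in this package are 1-based on that plus strand.
#'
#' @param name Text label (used as the sequence name in FASTA/SAM output).
#' @param sequence Character string over A, C, G, T (upper-cased on input;
#'   `N` is tolerated only when `allow_n = TRUE`).
#' @param circular Logical; circular genomes wrap windows and bins around
#'   the origin.
#' @param allow_n Tolerate `N` characters (they belong to no base class).
#' @return An object of class `reference_genome` with fields `name`,
#'   `sequence` and `circular`.
#' @seealso [generate_reference()], [read_fasta()]
#' @export
reference_genome <- function(name, sequence, circular = TRUE,
                             allow_n = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("reference sequence must have length >= 1")
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gregexpr(paste0("[^", alphabet, "]"), sequence)[[1]]
  if (bad[1] != -1L) {
    stop("non-", alphabet, " symbol '",
         substr(sequence, bad[1], bad[1]), "' at position ", bad[1])
  }
  structure(list(name = name, sequence = sequence,
                 circular = isTRUE(circular)),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %d bp, %s\n", x$name,
              nchar(x$sequence), if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.reference_genome <- function(x) nchar(x$sequence)

ref_chars <- function(ref) strsplit(ref$sequence, "")[[1]]

#' Generate a reference with controlled base-class composition
#'
#' Builds a circular reference as a concatenation of segments, each with an
#' exact target content of one two-letter base class.  Within a segment,
#' `round(target * length)` positions are assigned (uniformly at random) a
#' base from the class and the rest a base from the complementary class, so
#' the realized content matches the target to within half a base.  This
#' gives downstream bias analyses a genome whose local AC/CT/GC content is
#' known by construction.
#'
#' @param length Total genome length (bp).
#' @param segments A `data.frame` with columns `pair_class`, `target`
#'   (content fraction in \[0, 1\]) and `length`, or a list of
#'   `list(pair_class, target, length)` triples.  Segment lengths must sum
#'   to `length`.
#' @param seed Integer seed; identical calls are reproducible.
#' @param name Sequence label.
#' @return A [reference_genome()].
#' @examples
#' ref <- generate_reference(600, data.frame(
#'   pair_class = "AC", target = c(0.8, 0.4), length = c(300, 300)), seed = 7)
#' pair_content(substr(ref$sequence, 1, 300), "AC")
#' @export
generate_reference <- function(length, segments, seed, name = "synthetic") {
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- do.call(rbind, lapply(segments, function(s) {
      data.frame(pair_class = s[[1]],
                 target = as.numeric(s[[2]]),
                 length = as.integer(s[[3]]))
    }))
  }
  stopifnot(is.data.frame(segments),
            all(c("pair_class", "target", "length") %in% names(segments)))
  if (sum(segments$length) != length) {
    stop("segment lengths sum to ", sum(segments$length),
         " but total genome length is ", length)
  }
  if (any(segments$target < 0 | segments$target > 1)) {
    stop("segment target fractions must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  parts <- vapply(seq_len(nrow(segments)), function(i) {
    cls <- pair_class_bases(segments$pair_class[i])
    other <- setdiff(BASES, cls)
    n <- segments$length[i]
    n_in <- round(segments$target[i] * n)
    base <- sample(other, n, replace = TRUE)
    if (n_in > 0) {
      in_idx <- sample.int(n, n_in)
      base[in_idx] <- sample(cls, n_in, replace = TRUE)
    }
    paste(base, collapse = "")
  }, character(1))
  reference_genome(name, paste(parts, collapse = ""), circular = TRUE)
}
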