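#' Two-letter base-class content of a sequence
#'
#' Percentage of positions whose base belongs to the given two-letter class
#' (e.g. "AC content" = % of bases that are A or C).  This is base-class
#' content, not adjacent-dinucleotide frequency: an "80% AC-rich" window is
#' one where 80% of the positions carry an A or a C.
#'
#' @param sequence Character string over ACGT, or a [reference_genome()].
#' @param pair_class One of `"GC"`, `"AT"`, `"AC"`, `"GT"`, `"CT"`, `"AG"`.
#' @return Percentage in \[0, 100\].
#' @examples
#' pair_content("ACACAC", "AC")  # 100
#' pair_content("ACACAC", "GC")  # 50
#' @export
pair_content <- function(sequence, pair_class) {
  if (inherits(sequence, "reference_genome")) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% BASES)
  if (length(bad)) {
    stop("non-ACGT symbol '", chars[bad[1]], "' at position ", bad[1])
  }
  cls <- pair_class_bases(pair_class)
  100 * mean(chars %in% cls)
}

# Per-position base-class content of a centered window, with circular
# wrap-around.  For even windows the extra position goes to the right.
#' Local base-class content in a centered sliding window
#'
#' @param ref A [reference_genome()].
#' @param pair_class Two-letter base class.
#' @param window Window width in nt (default 150, the analysis bin width).
#' @return Numeric vector (length of the genome) of content fractions in
#'   \[0, 1\].
#' @export
local_pair_content <- function(ref, pair_class, window = 150L) {
  stopifnot(inherits(ref, "reference_genome"))
  window <- as.integer(window)
  L <- length(ref)
  if (window < 1L || window > L) stop("window must lie in [1, genome length]")
  x <- as.numeric(ref_chars(ref) %in% pair_class_bases(pair_class))
  half_l <- (window - 1L) %/% 2L
  half_r <- window - 1L - half_l
  left <- if (half_l > 0) x[(L - half_l + 1L):L] else numeric(0)
  right <- if (half_r > 0) x[seq_len(half_r)] else numeric(0)
  ext <- c(left, x, right)
  cs <- c(0, cumsum(ext))
  (cs[seq_len(L) + window] - cs[seq_len(L)]) / window
}

# 1-based position indices of each fixed-width bin; on a circular genome the
# final short bin wraps around to borrow its missing bases from the start.
bin_positions <- function(L, bin_size, wrap = TRUE) {
  n_bins <- ceiling(L / bin_size)
  starts <- seq(1L, by = bin_size, length.out = n_bins)
  lapply(starts, function(s) {
    idx <- s:(s + bin_size - 1L)
    if (max(idx) > L) {
      if (wrap) idx <- ((idx - 1L) %% L) + 1L else idx <- idx[idx <= L]
    }
    idx
  })
}

#' Base-class composition in fixed-width genome bins
#'
#' Splits the genome into consecutive non-overlapping bins of `bin_size`
#' positions, starting at position 1, and reports the content percentage of
#' all six two-letter base classes per bin.  On a circular genome the final
#' short remainder bin wraps around the origin so that every bin has exactly
#' `bin_size` bases (16,569 = 110 x 150 + 69: the 111th bin covers
#' 16,501–16,569 plus 1–81); set `wrap = FALSE` for a truncated final bin.
#'
#' @param ref A [reference_genome()].
#' @param bin_size Bin width in nt (default 150).
#' @param wrap Wrap the final bin on circular genomes (default: the
#'   genome's circularity flag).
#' @return A `data.frame` of class `composition_bins` with columns `bin`,
#'   `start`, `end` and one percentage column per class (`GC`, `AT`, `AC`,
#'   `GT`, `CT`, `AG`).  Complementary classes sum to 100 per bin.
#' @export
binned_composition <- function(ref, bin_size = 150L, wrap = ref$circular) {
  stopifnot(inherits(ref, "reference_genome"))
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L) stop("bin_size must be >= 1")
  L <- length(ref)
  chars <- ref_chars(ref)
  bins <- bin_positions(L, bin_size, wrap = wrap)
  out <- data.frame(
    bin = seq_along(bins),
    start = vapply(bins, `[`, integer(1), 1L),
    end = vapply(bins, function(i) i[length(i)], integer(1))
  )
  for (cls in PAIR_CLASSES) {
    member <- chars %in% pair_class_bases(cls)
    out[[cls]] <- vapply(bins, function(i) 100 * mean(member[i]), numeric(1))
  }
  structure(out, class = c("composition_bins", "data.frame"),
            bin_size = bin_size, genome_length = L, wrap = wrap)
}

#' Mean relative coverage per composition bin
#'
#' @param bins A [binned_composition()] result.
#' @param rc A [relative_coverage()] profile on the same genome.
#' @param strand `"total"`, `"plus"` or `"minus"`.
#' @return Numeric vector of per-bin mean relative coverage.
#' @export
bin_mean_rc <- function(bins, rc, strand = c("total", "plus", "minus")) {
  strand <- match.arg(strand)
  stopifnot(inherits(bins, "composition_bins"),
            inherits(rc, "relative_coverage"))
  L <- attr(bins, "genome_length")
  series <- rc[[paste0("rc_", strand)]]
  if (is.null(series)) {
    stop("relative coverage for the ", strand, " series is undefined")
  }
  if (length(series) != L) {
    stop("bins were computed on a genome of length ", L,
         " but the coverage profile has length ", length(series))
  }
  pos <- bin_positions(L, attr(bins, "bin_size"), wrap = attr(bins, "wrap"))
  vapply(pos, function(i) mean(series[i]), numeric(1))
}

#' Coverage-bias curve: relative coverage versus base-class content
#'
#' Groups composition bins into content bands (default 10 percentage points
#' wide: \[0,10), \[10,20), ..., \[90,100\]) and reports, per band, the mean
#' of the bins' mean relative coverage and the number of bins.  The plus
#' strand curve of the AC (and CT) class is where amplification-driven
#' strand bias shows up on mtDNA: plus-strand relative coverage collapses
#' towards zero in bands of 80% content and above.
#'
#' @inheritParams bin_mean_rc
#' @param pair_class Two-letter base class whose per-bin content defines the
#'   bands.
#' @param band_width Band width in percentage points (must divide 100).
#' @return A `data.frame` of class `bias_curve` with columns `band_low`,
#'   `band_high`, `mean_rc` (NA where `n_bins` = 0) and `n_bins`.
#' @export
bias_curve <- function(bins, rc, pair_class,
                       strand = c("total", "plus", "minus"),
                       band_width = 10) {
  strand <- match.arg(strand)
  stopifnot(band_width > 0, 100 %% band_width == 0)
  content <- bins[[match.arg(toupper(pair_class), PAIR_CLASSES)]]
  rc_bin <- bin_mean_rc(bins, rc, strand)
  n_bands <- as.integer(100 / band_width)
  # left-closed, right-open bands; the top band is closed at 100
  band_id <- pmin(floor(content / band_width), n_bands - 1L) + 1L
  mean_rc <- rep(NA_real_, n_bands)
  n_bins <- integer(n_bands)
  for (b in seq_len(n_bands)) {
    in_b <- band_id == b
    n_bins[b] <- sum(in_b)
    if (n_bins[b] > 0) mean_rc[b] <- mean(rc_bin[in_b])
  }
  structure(
    data.frame(band_low = band_width * (seq_len(n_bands) - 1L),
               band_high = band_width * seq_len(n_bands),
               mean_rc = mean_rc, n_bins = n_bins),
    class = c("bias_curve", "data.frame"),
    pair_class = toupper(pair_class), strand = strand,
    band_width = band_width
  )
}
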