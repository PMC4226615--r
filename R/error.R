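#' Per-position non-reference base fraction
#'
#' The sequencing-error index: at every covered position, the fraction of
#' observed bases (both strands pooled) that differ from the reference
#' base.  Positions carrying true variants are excluded via `exclude` so
#' genuine heteroplasmy does not inflate the error baseline.  Deletions are
#' not counted (substitution-only index).
#'
#' @param counts A `base_counts` object.
#' @param ref A [reference_genome()] of the same length.
#' @param exclude Integer vector of 1-based positions to mask (true
#'   variants).
#' @return An object of class `position_error`: list with `fraction`
#'   (per-position non-reference fraction, `NA` where uncovered or masked),
#'   `total` (observed bases per position) and `excluded` (logical mask).
#' @export
position_error <- function(counts, ref, exclude = integer(0)) {
  stopifnot(inherits(counts, "base_counts"),
            inherits(ref, "reference_genome"))
  L <- length(ref)
  if (counts$genome_length != L) {
    stop("counts cover ", counts$genome_length,
         " positions but the reference has ", L)
  }
  ref_idx <- match(ref_chars(ref), BASES)
  total <- rowSums(counts$plus) + rowSums(counts$minus)
  ref_n <- counts$plus[cbind(seq_len(L), ref_idx)] +
    counts$minus[cbind(seq_len(L), ref_idx)]
  fraction <- ifelse(total > 0, (total - ref_n) / total, NA_real_)
  excluded <- rep(FALSE, L)
  exclude <- as.integer(exclude)
  if (length(exclude)) {
    stopifnot(all(exclude >= 1L & exclude <= L))
    excluded[exclude] <- TRUE
    fraction[excluded] <- NA_real_
  }
  structure(list(fraction = fraction, total = total, excluded = excluded,
                 genome_length = L),
            class = "position_error")
}

#' Average sequencing-error rate
#'
#' Unweighted mean of the per-position non-reference fractions over
#' unmasked covered positions.  Given several profiles (one per sample),
#' per-sample means are aggregated into an across-sample mean and a sample
#' (n-1) standard deviation — the error baseline against which candidate
#' low-level heteroplasmies are judged.
#'
#' @param profile A [position_error()] object, or a list of them (one per
#'   sample).
#' @return An object of class `error_summary`: list with `mean_error`,
#'   `per_sample` (named numeric vector of per-sample means), `sd`
#'   (`NA` for a single sample) and `n_samples`.  `mean_error` is `NA`
#'   (with a warning) if no usable position exists.
#' @examples
#' # across-sample mean of per-sample error rates 0.27% and 0.19%
#' s <- structure(list(mean_error = NA, per_sample = c(a = 0.0027,
#'   b = 0.0019)), class = "error_summary")
#' @export
average_error_rate <- function(profile) {
  if (inherits(profile, "position_error")) profile <- list(profile)
  stopifnot(is.list(profile), length(profile) >= 1,
            all(vapply(profile, inherits, logical(1), "position_error")))
  per_sample <- vapply(profile, function(p) {
    ok <- !is.na(p$fraction)
    if (!any(ok)) NA_real_ else mean(p$fraction[ok])
  }, numeric(1))
  nm <- names(profile)
  names(per_sample) <- if (is.null(nm)) {
    paste0("sample", seq_along(per_sample))
  } else nm
  if (all(is.na(per_sample))) {
    warning("no covered, unmasked positions; error rate is undefined")
  }
  usable <- per_sample[!is.na(per_sample)]
  structure(list(
    mean_error = if (length(usable)) mean(usable) else NA_real_,
    per_sample = per_sample,
    sd = if (length(usable) >= 2) sd(usable) else NA_real_,
    n_samples = length(per_sample)
  ), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> mean error %.4f%% over %d sample(s)",
              100 * x$mean_error, x$n_samples))
  if (!is.na(x$sd)) cat(sprintf(", sd %.4f%%", 100 * x$sd))
  cat("\n")
  invisible(x)
}

#' Heteroplasmy detection threshold from the error baseline
#'
#' Policy: `max(floor, multiplier * mean error)`, rounded up to the nearest
#' whole percent.  At the MiSeq-like error baselines of 0.2–0.35% this
#' yields the 2% working point; the floor guards against an implausibly low
#' threshold when the measured error is near zero.  The paper's platforms
#' were operated at 5% for historical comparability — pass
#' `multiplier`/`floor` accordingly or override the result.
#'
#' @param summary An [average_error_rate()] summary, or a bare mean error
#'   rate (fraction).
#' @param multiplier Safety factor over the mean error (default 5).
#' @param floor Minimum threshold as a fraction (default 0.01 = 1%).
#' @return Detection threshold as a fraction (e.g. `0.02` for 2%).
#' @seealso [is_callable()]
#' @examples
#' detection_threshold(0.003)  # 0.015 -> rounds up to 0.02
#' @export
detection_threshold <- function(summary, multiplier = 5, floor = 0.01) {
  m <- if (inherits(summary, "error_summary")) summary$mean_error
       else as.numeric(summary)
  if (is.na(m)) stop("error summary is undefined")
  stopifnot(m >= 0, multiplier > 0, floor >= 0)
  thr <- max(floor, multiplier * m)
  ceiling(round(thr * 100, 9)) / 100
}

#' Is a candidate allele fraction callable?
#'
#' Strictly above the detection threshold: a candidate exactly at the
#' threshold is not called.
#'
#' @param fraction Candidate allele fraction(s), same scale as `threshold`.
#' @param threshold Detection threshold (fraction).
#' @return Logical vector.
#' @export
is_callable <- function(fraction, threshold) {
  fraction > threshold
}
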