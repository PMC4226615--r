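# round-half-up to `digits` decimals (base round() is round-half-even;
# printed tables in the field use half-up)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Parse a variant in mitochondrial m.-notation
#'
#' Supported forms: substitutions `m.<pos><ref>><alt>` (e.g. `m.7989T>C`),
#' insertions `m.<p>_<p+1>ins<seq>` (e.g. `m.5899_5900insC`) and deletions
#' `m.<p>del` / `m.<p>_<q>del`.  Parsing is total and round-trips through
#' [format_mt_variant()].
#'
#' @param text A single m.-notation string.
#' @return An object of class `mt_variant`: list with `position`, `end`,
#'   `kind` (`"substitution"`, `"insertion"` or `"deletion"`), `ref`, `alt`
#'   and the canonical `text`.
#' @examples
#' parse_mt_variant("m.7989T>C")
#' parse_mt_variant("m.5899_5900insC")
#' @export
parse_mt_variant <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text,
                  regexec("^m\\.([0-9]+)([ACGT])>([ACGT])$", text))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2])
    return(new_mt_variant(pos, pos, "substitution", m[3], m[4]))
  }
  m <- regmatches(text,
                  regexec("^m\\.([0-9]+)_([0-9]+)ins([ACGT]+)$", text))[[1]]
  if (length(m)) {
    p1 <- as.integer(m[2]); p2 <- as.integer(m[3])
    if (p2 != p1 + 1L) {
      stop("malformed insertion '", text,
           "': flanking positions must be adjacent")
    }
    return(new_mt_variant(p1, p2, "insertion", "", m[4]))
  }
  m <- regmatches(text, regexec("^m\\.([0-9]+)(_([0-9]+))?del$", text))[[1]]
  if (length(m)) {
    p1 <- as.integer(m[2])
    p2 <- if (nzchar(m[4])) as.integer(m[4]) else p1
    if (p2 < p1) stop("malformed deletion '", text, "': end before start")
    return(new_mt_variant(p1, p2, "deletion", "", ""))
  }
  stop("malformed m.-notation variant: '", text, "'")
}

new_mt_variant <- function(position, end, kind, ref, alt) {
  v <- structure(list(position = position, end = end, kind = kind,
                      ref = ref, alt = alt),
                 class = "mt_variant")
  v$text <- format_mt_variant(v)
  v
}

#' Canonical m.-notation text of a variant
#'
#' @param variant An `mt_variant` from [parse_mt_variant()].
#' @return Character string.
#' @export
format_mt_variant <- function(variant) {
  stopifnot(inherits(variant, "mt_variant"))
  switch(variant$kind,
    substitution = sprintf("m.%d%s>%s", variant$position, variant$ref,
                           variant$alt),
    insertion = sprintf("m.%d_%dins%s", variant$position, variant$end,
                        variant$alt),
    deletion = if (variant$end > variant$position) {
      sprintf("m.%d_%ddel", variant$position, variant$end)
    } else {
      sprintf("m.%ddel", variant$position)
    },
    stop("unknown variant kind '", variant$kind, "'")
  )
}

#' @export
print.mt_variant <- function(x, ...) {
  cat(sprintf("<mt_variant> %s (%s)\n", x$text, x$kind))
  invisible(x)
}

variant_key <- function(text) {
  vapply(text, function(t) parse_mt_variant(t)$text, character(1),
         USE.NAMES = FALSE)
}

#' Compare a call set against a truth panel
#'
#' A truth variant counts as detected iff an identical call (same position,
#' kind and alleles, after canonicalization of the m.-notation) is present;
#' remaining truth variants are false negatives and calls absent from the
#' truth panel are "extra".  Optionally, insertions falling inside declared
#' polymorphic intervals (e.g. the 302–316 homopolymeric stretch, where
#' different platforms place equivalent C-insertions differently) are
#' matched by net inserted length within the interval instead of exactly.
#'
#' @param truth Character vector of m.-notation truth variants for the
#'   sample.
#' @param calls Character vector of m.-notation calls for the same sample
#'   and dataset.
#' @param sample,dataset Labels echoed into the output row.
#' @param equivalent_regions `NULL`, or a `data.frame` with columns `start`
#'   and `end` (1-based, inclusive) of polymorphic intervals in which
#'   insertions are matched by net inserted length.
#' @return A one-row `data.frame` (class `concordance_row`): `sample`,
#'   `dataset`, `n_truth`, `n_detected`, `n_false_negative`, `n_extra`.
#'   Always `n_detected + n_false_negative == n_truth`.
#' @export
compare_callsets <- function(truth, calls, sample = "sample",
                             dataset = "dataset",
                             equivalent_regions = NULL) {
  truth <- unique(variant_key(truth))
  calls <- unique(variant_key(calls))
  matched_truth <- truth %in% calls
  matched_call <- calls %in% truth

  if (!is.null(equivalent_regions) && nrow(equivalent_regions) > 0) {
    stopifnot(all(c("start", "end") %in% names(equivalent_regions)))
    for (r in seq_len(nrow(equivalent_regions))) {
      lo <- equivalent_regions$start[r]; hi <- equivalent_regions$end[r]
      ins_len <- function(texts, in_scope) {
        vs <- lapply(texts[in_scope], parse_mt_variant)
        keep <- vapply(vs, function(v) {
          v$kind == "insertion" && v$position >= lo && v$end <= hi
        }, logical(1))
        list(idx = which(in_scope)[keep],
             len = sum(vapply(vs[keep], function(v) nchar(v$alt),
                              integer(1))))
      }
      t_in <- ins_len(truth, !matched_truth)
      c_in <- ins_len(calls, !matched_call)
      if (length(t_in$idx) && length(c_in$idx) && t_in$len == c_in$len) {
        matched_truth[t_in$idx] <- TRUE
        matched_call[c_in$idx] <- TRUE
      }
    }
  }

  out <- data.frame(sample = sample, dataset = dataset,
                    n_truth = length(truth),
                    n_detected = sum(matched_truth),
                    n_false_negative = sum(!matched_truth),
                    n_extra = sum(!matched_call),
                    stringsAsFactors = FALSE)
  structure(out, class = c("concordance_row", "data.frame"))
}

#' Pooled detection rate over concordance rows
#'
#' `100 * sum(n_detected) / sum(n_truth)`, in percent.  Full precision is
#' returned; printed tables report one decimal.
#'
#' @param rows A `data.frame` with columns `n_detected` and `n_truth`
#'   (e.g. rbind-ed [compare_callsets()] rows).
#' @return Percentage.
#' @export
detection_rate <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1,
            all(c("n_detected", "n_truth") %in% names(rows)))
  total_truth <- sum(rows$n_truth)
  if (total_truth == 0) stop("zero truth variants; detection rate undefined")
  100 * sum(rows$n_detected) / total_truth
}

#' Mean and sample standard deviation of heteroplasmy fractions
#'
#' Arithmetic mean and n-1 standard deviation of per-method minor-allele
#' fractions (percent), as printed in cross-platform heteroplasmy tables.
#' Values are returned at full precision; `digits` controls the half-up
#' rounding applied to the `rounded` element (one decimal by default, the
#' table convention).
#'
#' @param fractions Numeric vector of allele fractions in percent (>= 2
#'   values for a defined sd).
#' @param digits Decimals for the rounded presentation values.
#' @return List with `mean`, `sd` (NA when fewer than 2 values) and
#'   `rounded` (named vector `mean`, `sd` rounded half-up).
#' @examples
#' heteroplasmy_summary(c(12, 12, 23))$rounded  # mean 15.7, sd 6.4
#' @export
heteroplasmy_summary <- function(fractions, digits = 1) {
  stopifnot(is.numeric(fractions), length(fractions) >= 1)
  m <- mean(fractions)
  s <- if (length(fractions) >= 2) sd(fractions) else NA_real_
  list(mean = m, sd = s,
       rounded = c(mean = round_half_up(m, digits),
                   sd = if (is.na(s)) NA_real_ else round_half_up(s, digits)))
}

#' Heteroplasmy summary table from a long variant table
#'
#' @param df A `data.frame` with columns `sample`, `variant`, `platform`
#'   and `fraction` (percent), one row per method measurement.
#' @param digits Decimals for rounding (half-up).
#' @return A `data.frame` with one row per (sample, variant, platform):
#'   the per-method fractions' `mean` and `sd`, rounded.
#' @export
heteroplasmy_table <- function(df, digits = 1) {
  stopifnot(all(c("sample", "variant", "platform", "fraction") %in%
                  names(df)))
  key <- interaction(df$sample, df$variant, df$platform, drop = TRUE)
  rows <- lapply(split(df, key), function(g) {
    hs <- heteroplasmy_summary(g$fraction, digits = digits)
    data.frame(sample = g$sample[1], variant = g$variant[1],
               platform = g$platform[1], n = nrow(g),
               mean = hs$rounded[["mean"]], sd = hs$rounded[["sd"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample, out$variant, out$platform), , drop = FALSE]
}
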