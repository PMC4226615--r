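#' Read a single-record FASTA reference
#'
#' @param path FASTA file with exactly one record.
#' @param circular Circularity flag to attach (default `TRUE`, the mtDNA
#'   convention).
#' @return A [reference_genome()]; sequence is upper-cased.  `N` characters
#'   are tolerated with a warning; any other non-ACGT symbol is an error.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (length(set) > 1L) {
    stop("expected a single-record FASTA; found ", length(set),
         " records: ", paste(names(set), collapse = ", "))
  }
  seq <- toupper(as.character(set[[1]]))
  name <- strsplit(names(set)[1], "\\s+")[[1]][1]
  if (grepl("N", seq, fixed = TRUE)) {
    warning("reference contains N characters; they belong to no base class")
    return(reference_genome(name, seq, circular = circular, allow_n = TRUE))
  }
  reference_genome(name, seq, circular = circular)
}

#' Write a reference as single-record FASTA
#'
#' @param ref A [reference_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "reference_genome"))
  set <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write per-position strand-resolved base counts as pileup TSV
#'
#' The package's pileup dialect: a `#reference=<name> length=<L>` header
#' followed by tab-separated columns `pos`, `strand` (`+`/`-`), `A`, `C`,
#' `G`, `T`.  Two rows per position with any coverage; all-zero positions
#' are omitted (and restored as zeros on read).
#'
#' @param counts A `base_counts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(counts, path) {
  stopifnot(inherits(counts, "base_counts"))
  total <- rowSums(counts$plus) + rowSums(counts$minus)
  keep <- which(total > 0)
  rows <- data.frame(
    pos = rep(keep, each = 2L),
    strand = rep(c("+", "-"), times = length(keep)),
    A = as.vector(rbind(counts$plus[keep, 1], counts$minus[keep, 1])),
    C = as.vector(rbind(counts$plus[keep, 2], counts$minus[keep, 2])),
    G = as.vector(rbind(counts$plus[keep, 3], counts$minus[keep, 3])),
    T = as.vector(rbind(counts$plus[keep, 4], counts$minus[keep, 4]))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#reference=%s\tlength=%d", counts$ref_name,
                     counts$genome_length), con)
  writeLines(paste(c("pos", "strand", "A", "C", "G", "T"),
                   collapse = "\t"), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a pileup TSV into a base-count matrix
#'
#' @param path Pileup TSV written by [write_pileup()] (or conforming to
#'   the same dialect).
#' @return A `base_counts` object.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("^#reference=([^\t]+)\tlength=([0-9]+)$",
                          header))[[1]]
  if (!length(m)) {
    stop("pileup file lacks the '#reference=<name>\tlength=<L>' header: ",
         path)
  }
  ref_name <- m[2]
  L <- as.integer(m[3])
  df <- read.delim(path, comment.char = "#", header = TRUE,
                   stringsAsFactors = FALSE)
  if (!identical(names(df), c("pos", "strand", "A", "C", "G", "T"))) {
    stop("pileup columns must be pos, strand, A, C, G, T")
  }
  if (nrow(df) > 0) {
    if (any(df$pos < 1L | df$pos > L)) {
      stop("pileup position outside the declared length ", L)
    }
    if (any(!df$strand %in% c("+", "-"))) stop("invalid strand symbol")
    if (anyDuplicated(paste(df$pos, df$strand))) {
      stop("duplicate (position, strand) rows in pileup")
    }
    if (any(df$A < 0 | df$C < 0 | df$G < 0 | df$T < 0)) {
      stop("negative counts in pileup")
    }
  }
  plus <- matrix(0L, L, 4L); minus <- matrix(0L, L, 4L)
  for (st in c("+", "-")) {
    sub <- df[df$strand == st, , drop = FALSE]
    m_ <- as.matrix(sub[, c("A", "C", "G", "T")])
    if (st == "+") plus[sub$pos, ] <- m_ else minus[sub$pos, ] <- m_
  }
  new_base_counts(plus, minus, ref_name, L)
}

#' Write simulated reads as a SAM file
#'
#' Minimal single-reference SAM: `@HD`/`@SQ` header plus one record per
#' read (`MAPQ` 60, fully matched CIGAR, fixed base quality).
#'
#' @param reads The `reads` element of [simulate_reads()].
#' @param ref A [reference_genome()].
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ref, path) {
  stopifnot(inherits(ref, "reference_genome"), is.data.frame(reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$name, length(ref))), con)
  qual <- vapply(nchar(reads$seq), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                     reads$qname, reads$flag, ref$name, reads$pos,
                     reads$cigar, reads$seq, qual), con)
  invisible(path)
}

#' Write / read a truth manifest as JSON
#'
#' @param manifest A `truth_manifest` from [simulate_base_counts()].
#' @param path Output path.
#' @return `path` (write) or a list (read).
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "truth_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a variant list TSV
#'
#' Tab-separated with header and columns `sample`, `dataset`, `variant`
#' (m.-notation) and optionally `fraction` (percent).  `#`-prefixed lines
#' are comments.
#'
#' @param path TSV path.
#' @return A `data.frame`; every `variant` is validated by
#'   [parse_mt_variant()].
#' @export
read_variant_tsv <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample", "dataset", "variant")
  if (!all(need %in% names(df))) {
    stop("variant TSV must have columns ", paste(need, collapse = ", "))
  }
  invisible(lapply(df$variant, parse_mt_variant))
  df
}

# TSV writer with '#'-prefixed metadata lines (tool version, seed, config)
# so outputs are traceable and byte-reproducible (no timestamps).
write_tsv_meta <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- tryCatch(as.character(utils::packageVersion("mitocov")),
                      error = function(e) "dev")
  meta <- c(tool = paste0("mitocov ", version), meta)
  writeLines(sprintf("#%s=%s", names(meta), unname(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
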