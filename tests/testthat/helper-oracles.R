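# Brute-force oracles and tiny fixtures, independent of the package's
# vectorized code paths.

bf_pair_content <- function(s, cls) {
  ch <- strsplit(s, "")[[1]]
  b <- strsplit(cls, "")[[1]]
  100 * sum(ch == b[1] | ch == b[2]) / length(ch)
}

bf_relative_coverage <- function(depth) {
  total <- 0
  for (d in depth) total <- total + d
  m <- total / length(depth)
  out <- numeric(length(depth))
  for (i in seq_along(depth)) out[i] <- depth[i] / m
  out
}

bf_sample_sd <- function(x) {
  m <- sum(x) / length(x)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sqrt(ss / (length(x) - 1))
}

# wrapped bin content by direct substring tallying
bf_binned_content <- function(seq, bin_size, cls) {
  L <- nchar(seq)
  n_bins <- ceiling(L / bin_size)
  vapply(seq_len(n_bins), function(b) {
    idx <- ((b - 1) * bin_size + 1):((b - 1) * bin_size + bin_size)
    idx <- ((idx - 1) %% L) + 1
    bf_pair_content(paste(strsplit(seq, "")[[1]][idx], collapse = ""), cls)
  }, numeric(1))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# base_counts with a single nucleotide per strand (the reference base),
# given per-strand depth vectors and a reference
counts_from_depth <- function(plus_depth, minus_depth, ref) {
  L <- length(ref)
  ref_idx <- match(strsplit(ref$sequence, "")[[1]], c("A", "C", "G", "T"))
  plus <- matrix(0L, L, 4L); minus <- matrix(0L, L, 4L)
  plus[cbind(seq_len(L), ref_idx)] <- plus_depth
  minus[cbind(seq_len(L), ref_idx)] <- minus_depth
  base_counts(plus, minus, ref$name)
}

balanced_ref <- function(L, seed = 1, name = "ref") {
  generate_reference(L, data.frame(pair_class = "GC", target = 0.5,
                                   length = L), seed = seed, name = name)
}

# minimal SAM writer for hand-built alignment fixtures
write_tiny_sam <- function(path, ref_name, ref_len, records) {
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len), records)
  writeLines(lines, path)
  path
}

sam_record <- function(qname, flag, rname, pos, cigar, seq) {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, rname, pos, cigar, seq,
          paste(rep("I", nchar(seq)), collapse = ""))
}
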