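table_variants <- c("m.7989T>C", "m.9769T>C", "m.10866T>C", "m.12071T>C",
                    "m.8207C>T", "m.5609T>C", "m.7453G>A", "m.294T>C",
                    "m.16183A>C", "m.309_310insC", "m.315_316insC",
                    "m.5899_5900insC")

test_that("m.-notation parses and round-trips for all study variants", {
  v <- parse_mt_variant("m.7989T>C")
  expect_equal(v$kind, "substitution")
  expect_equal(v$position, 7989L)
  expect_equal(v$ref, "T")
  expect_equal(v$alt, "C")

  ins <- parse_mt_variant("m.5899_5900insC")
  expect_equal(ins$kind, "insertion")
  expect_equal(c(ins$position, ins$end), c(5899L, 5900L))
  expect_equal(ins$alt, "C")

  del <- parse_mt_variant("m.100_105del")
  expect_equal(del$kind, "deletion")
  expect_equal(del$end, 105L)

  for (txt in table_variants) {
    expect_identical(format_mt_variant(parse_mt_variant(txt)), txt)
  }
})

test_that("malformed variant strings are rejected with the offending token", {
  expect_error(parse_mt_variant("m.123A>"), "m\\.123A>")
  expect_error(parse_mt_variant("x.100T>C"), "x\\.100T>C")
  expect_error(parse_mt_variant("m.100_102insA"), "adjacent")
  expect_error(parse_mt_variant("m.10T>U"), "malformed")
})

test_that("callset comparison counts detected, FN and extra correctly", {
  t0 <- c("m.100A>C", "m.200G>T", "m.300T>A")
  row <- compare_callsets(t0, t0, sample = "s", dataset = "d")
  expect_equal(row$n_detected, 3L)
  expect_equal(row$n_false_negative, 0L)
  expect_equal(row$n_extra, 0L)

  row2 <- compare_callsets(t0, c("m.100A>C", "m.200G>T", "m.400C>G"))
  expect_equal(row2$n_detected, 2L)
  expect_equal(row2$n_false_negative, 1L)
  expect_equal(row2$n_extra, 1L)

  # a PGM-like sample: 33 truth, 32 detected, one novel call
  set.seed(50)
  truth33 <- sprintf("m.%dA>G", sample(1000:9000, 33))
  calls <- c(truth33[-1], "m.9999T>C")
  row3 <- compare_callsets(truth33, calls, sample = "1", dataset = "PGM")
  expect_equal(unlist(row3[, c("n_truth", "n_detected", "n_false_negative",
                               "n_extra")], use.names = FALSE),
               c(33L, 32L, 1L, 1L))

  # invariant on random truth/call sets: detected + FN = truth
  for (i in 1:25) {
    pool <- sprintf("m.%dC>T", sample(1:500, 40))
    tr <- sample(pool, 20)
    ca <- sample(pool, 25)
    r <- compare_callsets(tr, ca)
    expect_equal(r$n_detected + r$n_false_negative, r$n_truth)
    expect_equal(r$n_detected, length(intersect(unique(tr), unique(ca))))
    expect_equal(r$n_extra, length(setdiff(unique(ca), unique(tr))))
  }
})

test_that("polymorphic-region equivalence matches by net inserted length", {
  truth <- c("m.309_310insC", "m.315_316insC")
  calls <- c("m.309_310insCC")
  # default exact matching: both truth insertions are false negatives
  exact <- compare_callsets(truth, calls)
  expect_equal(exact$n_false_negative, 2L)
  expect_equal(exact$n_extra, 1L)
  # with the 302-316 interval declared, net length 2 == 2 matches
  region <- data.frame(start = 302, end = 316)
  eq <- compare_callsets(truth, calls, equivalent_regions = region)
  expect_equal(eq$n_false_negative, 0L)
  expect_equal(eq$n_extra, 0L)
  # unequal net length still fails to match
  eq2 <- compare_callsets(truth, c("m.309_310insCCC"),
                          equivalent_regions = region)
  expect_equal(eq2$n_false_negative, 2L)
})

test_that("pooled detection rates reproduce the printed working example", {
  tab2 <- read.delim(system.file("extdata", "table2_concordance.tsv",
                                 package = "mitocov"), comment.char = "#")
  pgm <- tab2[tab2$platform == "PGM", ]
  miseq <- tab2[tab2$platform == "MiSeq", ]
  expect_equal(round(detection_rate(pgm), 1), 96.6)
  expect_equal(round(detection_rate(miseq), 1), 99.5)
  expect_equal(detection_rate(data.frame(n_detected = 5, n_truth = 5)), 100)
  # permutation invariance
  perm <- pgm[sample(nrow(pgm)), ]
  expect_equal(detection_rate(perm), detection_rate(pgm))
  expect_error(detection_rate(data.frame(n_detected = 0, n_truth = 0)),
               "undefined")
})

test_that("heteroplasmy summaries match the printed per-method fractions", {
  # frozen printed rows: values, mean, sd at one decimal
  expect_equal(heteroplasmy_summary(c(12, 12, 23))$rounded,
               c(mean = 15.7, sd = 6.4))
  expect_equal(heteroplasmy_summary(c(17.1, 14.7, 14.1))$rounded,
               c(mean = 15.3, sd = 1.6))
  expect_equal(heteroplasmy_summary(c(8, 8, 8))$rounded,
               c(mean = 8.0, sd = 0.0))
  expect_true(is.na(heteroplasmy_summary(5)$sd))

  # sample sd against a brute-force two-pass oracle on random inputs
  set.seed(51)
  for (i in 1:25) {
    x <- runif(sample(2:8, 1), 0, 60)
    hs <- heteroplasmy_summary(x)
    expect_equal(hs$sd, bf_sample_sd(x), tolerance = 1e-12)
    expect_gte(hs$mean, min(x))
    expect_lte(hs$mean, max(x))
  }
})

test_that("variants above the detection threshold are recovered end-to-end", {
  ref <- balanced_ref(5000, seed = 52)
  chars <- strsplit(ref$sequence, "")[[1]]
  pos <- c(400L, 1500L, 2800L, 4100L)
  f <- c(0.05, 0.12, 0.30, 0.60)
  alt <- vapply(chars[pos], function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  vars <- data.frame(position = pos, ref = chars[pos], alt = alt,
                     fraction = f)
  sim <- simulate_base_counts(
    ref, sim_config(3000, error_rate = 0.002, variants = vars, seed = 53))

  # calibrate on the same run, masking the true variants
  summ <- average_error_rate(position_error(sim$counts, ref, exclude = pos))
  thr <- detection_threshold(summ)
  expect_lte(thr, 0.02)  # a 0.2% baseline maps to at most the 2% policy point

  # oracle caller: any position whose pooled alt fraction clears the
  # threshold becomes a substitution call
  total <- rowSums(sim$counts$plus) + rowSums(sim$counts$minus)
  calls <- character(0)
  for (p in which(total > 0)) {
    ref_i <- match(chars[p], c("A", "C", "G", "T"))
    pooled <- sim$counts$plus[p, ] + sim$counts$minus[p, ]
    for (b in setdiff(1:4, ref_i)) {
      if (is_callable(pooled[b] / total[p], thr)) {
        calls <- c(calls, sprintf("m.%d%s>%s", p, chars[p],
                                  c("A", "C", "G", "T")[b]))
      }
    }
  }
  truth <- sprintf("m.%d%s>%s", pos, chars[pos], alt)
  row <- compare_callsets(truth, calls, sample = "sim", dataset = "oracle")
  expect_equal(row$n_false_negative, 0L)
  expect_equal(row$n_detected, 4L)
})

test_that("heteroplasmy_table summarizes the bundled study table", {
  tab3 <- read.delim(system.file("extdata", "table3_heteroplasmy.tsv",
                                 package = "mitocov"), comment.char = "#")
  out <- heteroplasmy_table(tab3)
  expect_equal(nrow(out), 14L)  # 7 variants x 2 platforms
  g <- function(v, p) out[out$variant == v & out$platform == p, ]
  expect_equal(g("m.12071T>C", "MiSeq")$mean, 15.7)
  expect_equal(g("m.12071T>C", "MiSeq")$sd, 6.4)
  expect_equal(g("m.12071T>C", "PGM")$mean, 12.2)
  expect_equal(g("m.12071T>C", "PGM")$sd, 0.1)
  expect_equal(g("m.7453G>A", "PGM")$mean, 53.3)
  expect_equal(g("m.9769T>C", "MiSeq")$sd, 0.0)
})
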