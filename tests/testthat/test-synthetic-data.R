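test_that("generate_reference hits segment composition targets exactly", {
  # degenerate: a pure-AC genome
  ref <- generate_reference(300, data.frame(pair_class = "AC", target = 1,
                                            length = 300), seed = 1)
  expect_true(grepl("^[AC]+$", ref$sequence))
  expect_equal(pair_content(ref, "AC"), 100)

  # two-segment genome: realized content of each half, by direct counting
  ref2 <- generate_reference(600, data.frame(
    pair_class = "AC", target = c(0.8, 0.4), length = c(300, 300)), seed = 7)
  expect_equal(length(ref2), 600L)
  expect_lt(abs(bf_pair_content(substr(ref2$sequence, 1, 300), "AC") - 80), 2)
  expect_lt(abs(bf_pair_content(substr(ref2$sequence, 301, 600), "AC") - 40),
            2)

  # seed reproducibility
  ref3 <- generate_reference(600, data.frame(
    pair_class = "AC", target = c(0.8, 0.4), length = c(300, 300)), seed = 7)
  expect_identical(ref2$sequence, ref3$sequence)

  # mismatched total length is rejected
  expect_error(
    generate_reference(500, data.frame(pair_class = "AC", target = 0.5,
                                       length = 300), seed = 1),
    "segment lengths sum to 300")
})

test_that("noise-free simulation reproduces the reference at target depth", {
  ref <- balanced_ref(1000, seed = 2)
  sim <- simulate_base_counts(ref, sim_config(100, error_rate = 0, seed = 3))
  pe <- position_error(sim$counts, ref)
  expect_true(all(pe$fraction[!is.na(pe$fraction)] == 0))
  total <- rowSums(sim$counts$plus) + rowSums(sim$counts$minus)
  expect_lt(abs(mean(total) - 100) / 100, 0.05)
  expect_equal(sim$manifest$realized_error_rate, 0)
})

test_that("injected substitution error matches the binomial oracle", {
  ref <- balanced_ref(2000, seed = 4)
  e <- 0.003
  sim <- simulate_base_counts(ref, sim_config(500, error_rate = e, seed = 5))
  pe <- position_error(sim$counts, ref)
  total_bases <- sum(pe$total)
  nonref <- sum(pe$fraction * pe$total, na.rm = TRUE)
  se <- sqrt(e * (1 - e) / total_bases)
  expect_lt(abs(nonref / total_bases - e), 3 * se)
  # manifest records the realized rate
  expect_lt(abs(sim$manifest$realized_error_rate - e), 3 * se)
})

test_that("plus-strand suppression collapses coverage only where injected", {
  # AC-pure segment aligned to positions 1051-1650 in a balanced background
  ref <- generate_reference(3000, data.frame(
    pair_class = c("AC", "AC", "AC"),
    target = c(0.5, 1.0, 0.5),
    length = c(1050, 600, 1350)), seed = 11)
  bias <- bias_model("AC", window = 150, weight_fn = step_weight(0.8, 0.02))
  sim <- simulate_base_counts(ref, sim_config(400, seed = 12), bias = bias)
  rc <- relative_coverage(sim$counts)
  seg <- 1051:1650
  expect_lt(mean(rc$rc_plus[seg]), 0.1)
  expect_gt(mean(rc$rc_minus[seg]), 0.8)
  expect_lt(mean(rc$rc_minus[seg]), 1.2)
})

test_that("unbiased simulation balances the strands", {
  ref <- balanced_ref(12000, seed = 6)
  sim <- simulate_base_counts(ref, sim_config(200, seed = 7))
  d <- depth_from_counts(sim$counts)
  # each strand mean ~ Poisson(100): se of the difference of means
  se <- sqrt(2 * 100 / 12000)
  expect_lt(abs(mean(d$plus_depth) - mean(d$minus_depth)), 3 * se)
})

test_that("depth is conserved through error injection", {
  ref <- balanced_ref(1500, seed = 8)
  clean <- simulate_base_counts(ref, sim_config(300, error_rate = 0,
                                                seed = 9))
  noisy <- simulate_base_counts(ref, sim_config(300, error_rate = 0.02,
                                                seed = 9))
  # same seed, same depth draws: errors relocate counts but never add/drop
  expect_identical(rowSums(clean$counts$plus), rowSums(noisy$counts$plus))
  expect_identical(rowSums(clean$counts$minus), rowSums(noisy$counts$minus))
})

test_that("simulated allele fractions are recovered within binomial error", {
  ref <- balanced_ref(2000, seed = 10)
  chars <- strsplit(ref$sequence, "")[[1]]
  pos <- c(500L, 1200L)
  f <- c(0.3, 0.05)
  alt <- vapply(chars[pos], function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  vars <- data.frame(position = pos, ref = chars[pos], alt = alt,
                     fraction = f)
  sim <- simulate_base_counts(
    ref, sim_config(2500, error_rate = 0.003, variants = vars, seed = 13))
  alt_idx <- match(alt, c("A", "C", "G", "T"))
  for (i in seq_along(pos)) {
    total <- sum(sim$counts$plus[pos[i], ]) + sum(sim$counts$minus[pos[i], ])
    obs <- (sim$counts$plus[pos[i], alt_idx[i]] +
              sim$counts$minus[pos[i], alt_idx[i]]) / total
    expect_lt(abs(obs - f[i]), 3 * sqrt(f[i] * (1 - f[i]) / total))
  }
  # manifest lists every simulated variant exactly once
  expect_equal(sort(sim$manifest$variants$position), sort(pos))
  expect_equal(anyDuplicated(sim$manifest$variants$position), 0L)
})

test_that("the simulator is byte-reproducible under a fixed seed", {
  ref <- balanced_ref(800, seed = 14)
  cfg <- sim_config(150, error_rate = 0.005,
                    variants = data.frame(position = 100L,
                                          ref = substr(ref$sequence, 100, 100),
                                          alt = "A" , fraction = 0.2),
                    seed = 15)
  # ensure a legal alt different from ref
  if (cfg$variants$ref == "A") cfg$variants$alt <- "G"
  a <- simulate_base_counts(ref, cfg)
  b <- simulate_base_counts(ref, cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$manifest, b$manifest)
})

test_that("simulator validates variants against the reference", {
  ref <- balanced_ref(500, seed = 16)
  wrong_ref <- setdiff(c("A", "C", "G", "T"),
                       substr(ref$sequence, 50, 50))[1]
  cfg <- sim_config(100, variants = data.frame(
    position = 50L, ref = wrong_ref, alt = substr(ref$sequence, 50, 50),
    fraction = 0.1), seed = 1)
  expect_error(simulate_base_counts(ref, cfg), "ref base mismatch")
  cfg2 <- sim_config(100, variants = data.frame(
    position = 600L, ref = "A", alt = "C", fraction = 0.1), seed = 1)
  expect_error(simulate_base_counts(ref, cfg2), "outside the genome")
})

test_that("bias_model rejects malformed weight functions", {
  expect_error(bias_model("AC", weight_fn = function(x) 0.5 + 0 * x),
               "weight_fn\\(0\\) must equal 1")
  expect_error(bias_model("AC", weight_fn = function(x) abs(x - 0.5) + 0.5),
               "non-increasing")
  expect_error(bias_model("AC", weight_fn = function(x) 2 - x),
               "into \\[0, 1\\]")
  expect_s3_class(bias_model("CT", weight_fn = step_weight(0.7, 0)),
                  "bias_model")
})
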