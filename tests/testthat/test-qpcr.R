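test_that("efficiency follows the slope equation with its printed anchor", {
  eff <- efficiency_from_slope(-log2(10))       # -3.3219 cycles/log10
  expect_equal(eff$E, 100)
  expect_equal(eff$fold, 2)

  eff90 <- efficiency_from_slope(-3.5875)
  expect_equal(eff90$E, 90, tolerance = 1e-3)
  expect_equal(eff90$fold, 1.9, tolerance = 1e-4)

  # steep-slope limit: efficiency tends to zero
  expect_lt(efficiency_from_slope(-1e6)$E, 1e-3)
  expect_error(efficiency_from_slope(3.3), "negative")
})

test_that("standard curves recover the simulated efficiency exactly", {
  dil <- simulate_dilution_series(efficiency = 1, noise_sd = 0)
  sc <- fit_standard_curve(dil)
  expect_equal(sc$slope, -log2(10), tolerance = 1e-12)
  expect_equal(sc$E, 100, tolerance = 1e-9)
  expect_equal(sc$fold, 2, tolerance = 1e-12)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)

  # round trip at folds 1.8, 1.9, 2.0
  for (f in c(1.8, 1.9, 2.0)) {
    dil <- simulate_dilution_series(efficiency = f - 1, noise_sd = 0)
    expect_equal(fit_standard_curve(dil)$fold, f, tolerance = 1e-12)
  }

  expect_error(fit_standard_curve(
    simulate_dilution_series(concentrations = c(1, 0.1))), ">= 3")
  up <- simulate_dilution_series(efficiency = 1, noise_sd = 0)
  up$ct <- -up$ct
  expect_error(fit_standard_curve(up), "positive slope")
})

test_that("copy-number 2^-ddCt quantification round-trips the simulator", {
  # all four mean Cts equal: rq = 1
  d <- data.frame(sample = rep(c("s1", "s2"), 2),
                  target = rep(c("tgt", "ref"), each = 2), quantity = 1)
  ct <- simulate_ct_table(d, noise_sd = 0)
  rq <- copy_number_rq(ct, "tgt", "ref", "s1", "s2")
  expect_equal(rq$rq, c(1, 1))

  # ddCt = -2 gives rq = 4
  d$quantity <- c(4, 1, 1, 1)
  ct <- simulate_ct_table(d, noise_sd = 0)
  rq <- copy_number_rq(ct, "tgt", "ref", "s1", "s2")
  expect_equal(rq$delta_delta_ct[1], -2)
  expect_equal(rq$rq[1], 4, tolerance = 1e-12)
  expect_equal(rq$rq[rq$sample_id == "s2"], 1)   # calibrator exactly 1

  # true ratio 8, noiseless: rq = 8 to 1e-9 relative
  d$quantity <- c(8, 1, 1, 1)
  ct <- simulate_ct_table(d, noise_sd = 0)
  expect_equal(copy_number_rq(ct, "tgt", "ref", "s1", "s2")$rq[1], 8,
               tolerance = 1e-9)

  expect_error(copy_number_rq(ct, "tgt", "ref", "s1", "missing"), "no Ct")
})

test_that("efficiency-corrected expression uses the lowest-expression calibrator", {
  d <- rbind(
    data.frame(sample = c("leaf", "root", "stalk"), target = "tgt",
               quantity = c(8, 1, 2), efficiency = 1),
    data.frame(sample = c("leaf", "root", "stalk"), target = "GAPDH",
               quantity = 1, efficiency = 1))
  ct <- simulate_ct_table(d, noise_sd = 0)
  rq <- expression_rq(ct, "tgt", "GAPDH", efficiency = 1)
  expect_equal(rq$calibrator_id, rep("root", 3))   # highest normalized Ct
  expect_equal(rq$rq[rq$sample_id == "root"], 1)
  expect_equal(rq$rq[rq$sample_id == "leaf"], 8, tolerance = 1e-9)
  expect_equal(rq$rq[rq$sample_id == "stalk"], 2, tolerance = 1e-9)

  # E = 1, ddCt = -3 -> 8; E = 0.9, ddCt = -2 -> 1.9^2 = 3.61
  d2 <- rbind(
    data.frame(sample = c("a", "b"), target = "tgt",
               quantity = c(1.9^2, 1), efficiency = 0.9),
    data.frame(sample = c("a", "b"), target = "GAPDH", quantity = 1,
               efficiency = 0.9))
  ct2 <- simulate_ct_table(d2, noise_sd = 0)
  rq2 <- expression_rq(ct2, "tgt", "GAPDH", efficiency = 0.9)
  expect_equal(rq2$delta_delta_ct[rq2$sample_id == "a"], -2, tolerance = 1e-9)
  expect_equal(rq2$rq[rq2$sample_id == "a"], 3.61, tolerance = 1e-9)

  # the >=90% efficiency acceptance filter
  expect_error(expression_rq(ct2, "tgt", "GAPDH", efficiency = 0.5),
               "below the acceptance threshold")
  expect_error(expression_rq(ct2, "tgt", "GAPDH", efficiency = 1.5),
               "efficiency")
  expect_error(expression_rq(ct2, "tgt", "missing", efficiency = 1),
               "no Ct")
})

test_that("geNorm M matches brute force and its invariances", {
  # perfectly proportional genes: M = 0
  expr <- rbind(g1 = c(1, 2, 4, 8), g2 = c(3, 6, 12, 24))
  expect_equal(genorm_m(expr)$M, c(0, 0))

  # 3 genes x 4 samples vs brute-force pairwise SDs
  set.seed(501)
  expr <- matrix(2^runif(12, 0, 6), 3, 4,
                 dimnames = list(c("a", "b", "c"), NULL))
  got <- genorm_m(expr)
  brute <- sapply(1:3, function(j) {
    others <- setdiff(1:3, j)
    mean(sapply(others, function(k) sd(log2(expr[j, ] / expr[k, ]))))
  })
  expect_equal(got$M, brute, tolerance = 1e-12)

  # permutation of samples leaves M unchanged; 2-gene case is symmetric
  perm <- expr[, c(3, 1, 4, 2)]
  expect_equal(genorm_m(perm)$M, got$M, tolerance = 1e-12)
  two <- genorm_m(expr[1:2, ])
  expect_equal(two$M[1], two$M[2], tolerance = 1e-12)

  expect_error(genorm_m(expr[1, , drop = FALSE]), ">= 2")
  expect_error(genorm_m(rbind(g1 = c(1, -1), g2 = c(1, 1))), "positive")
})

test_that("one-way ANOVA with LSD matches the textbook formulas", {
  # all identical: degenerate, no separation
  res <- anova_lsd(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  expect_true(all(res$groups$letters == res$groups$letters[1]))

  # clearly separated groups
  res <- anova_lsd(c(1, 1.1, 0.9, 5, 5.2, 4.8), rep(c("a", "b"), each = 3))
  expect_lt(res$p, 0.05)
  expect_false(res$groups$letters[1] == res$groups$letters[2])

  # hand-computed F on the same data
  v <- c(1, 1.1, 0.9, 5, 5.2, 4.8)
  g <- rep(c("a", "b"), each = 3)
  gm <- tapply(v, g, mean)
  ssb <- sum(3 * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  expect_equal(res$F, (ssb / 1) / (ssw / 4), tolerance = 1e-12)

  # random 3x5 design vs textbook F and p
  set.seed(502)
  v <- rnorm(15)
  g <- rep(c("g1", "g2", "g3"), each = 5)
  res <- anova_lsd(v, g)
  k <- 3; N <- 15
  gm <- tapply(v, g, mean)
  ssb <- sum(5 * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  Fref <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(res$F, Fref, tolerance = 1e-10)
  expect_equal(res$p, pf(Fref, k - 1, N - k, lower.tail = FALSE),
               tolerance = 1e-10)

  # degenerate but separated: exact separation, p = 0
  res <- anova_lsd(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_true(res$degenerate)
  expect_equal(res$p, 0)
  expect_false(res$groups$letters[1] == res$groups$letters[2])

  expect_error(anova_lsd(1:4, rep("a", 4)), ">= 2 groups")
  expect_error(anova_lsd(1:3, c("a", "a", "b")), "replicates")
})

test_that("Ct tables round-trip through TSV", {
  d <- data.frame(sample = c("s1", "s2"), target = "t", quantity = c(2, 1))
  ct <- simulate_ct_table(d, noise_sd = 0.2, seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_ct_tsv(ct, path)
  back <- read_ct_tsv(path)
  expect_equal(back$ct, ct$ct, tolerance = 1e-12)
  expect_equal(back$sample, ct$sample)
})
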