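# Spacer-length profiling and its statistics.

test_that("spacer counting finds planted configurations at the right cell", {
  cnt <- count_spacers("TAAT", "TAAT", "TAATGGGGGGGTAAT",
                       spacer_range = 0:10, orientations = "FF")
  expect_equal(unname(cnt["7", "FF"]), 1L)
  expect_equal(sum(cnt, na.rm = TRUE), 1L)
  # head-to-head palindromic configuration 3 bp apart (paired-like layout)
  cnt2 <- count_spacers("TAAT", "TAAT", "TAATGGGATTA",
                        spacer_range = 0:3, orientations = c("FF", "FR", "RF"))
  expect_equal(unname(cnt2["3", "FR"]), 1L)
  expect_equal(unname(cnt2["3", "FF"]), 0L)
  # unobservable cells are NA, not zero
  cnt3 <- count_spacers("TAAT", "TAAT", "TAATGGTAATGG", spacer_range = 0:10,
                        orientations = "FF")
  expect_true(all(is.na(cnt3[as.character(5:10), "FF"])))
  expect_equal(unname(cnt3["2", "FF"]), 1L)
})

test_that("spacer counts equal a brute-force nested scan on random reads", {
  set.seed(53)
  reads <- random_reads(2000, 30)
  cnt <- count_spacers("TAAT", "GACA", reads, spacer_range = 0:12,
                       orientations = c("FF", "FR", "RF"))
  rc <- oracle_revcomp
  for (s in c(0, 3, 7, 12)) {
    want_ff <- sum(vapply(reads, oracle_has_config, logical(1),
                          site1 = "TAAT", site2 = "GACA", s = s))
    want_fr <- sum(vapply(reads, oracle_has_config, logical(1),
                          site1 = "TAAT", site2 = rc("GACA"), s = s))
    want_rf <- sum(vapply(reads, oracle_has_config, logical(1),
                          site1 = rc("TAAT"), site2 = "GACA", s = s))
    expect_equal(unname(cnt[as.character(s), ]),
                 c(want_ff, want_fr, want_rf))
  }
})

test_that("strand symmetry: reverse-complementing every read preserves counts", {
  set.seed(59)
  reads <- random_reads(800, 25)
  a <- count_spacers("TAAT", "TAAT", reads, spacer_range = 0:8)
  b <- count_spacers("TAAT", "TAAT", oracle_revcomp(reads),
                     spacer_range = 0:8)
  # FF configurations are strand-closed; FR and RF swap into each other
  expect_equal(a[, "FF"], b[, "FF"])
  expect_equal(unname(a[, "FR"]), unname(b[, "FR"]))
})

test_that("Grubbs max test: degenerate, textbook and critical-value cases", {
  flat <- grubbs_max_test(rep(5, 10))
  expect_equal(flat$G, 0)
  expect_equal(flat$p, 1)

  g <- grubbs_max_test(c(5, 5, 5, 5, 5, 5, 5, 500))
  expect_lt(g$p, 0.05)
  expect_gt(g$G, 2.13)   # published one-outlier critical value for n = 8
  expect_equal(g$which_max, 8)

  expect_error(grubbs_max_test(c(1, 2)), ">= 3")
  # NA (unobservable) cells are excluded, indices preserved
  gna <- grubbs_max_test(c(1, NA, 2, 50, 3))
  expect_equal(gna$n, 4)
  expect_equal(gna$which_max, 4)
})

test_that("Grubbs p agrees with an independent reference to 1e-8", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- rpois(n, lambda = sample(c(5, 50, 500), 1)) + runif(n, 0, 1e-3)
    got <- grubbs_max_test(x)
    expect_equal(got$p, oracle_grubbs_p(x), tolerance = 1e-8)
  }
})

test_that("Grubbs type-I error sits at alpha under its normal null", {
  set.seed(67)
  m <- matrix(rnorm(21 * 10000, mean = 50, sd = sqrt(50)), nrow = 21)
  rej <- mean(apply(m, 2, function(x) grubbs_max_test(x)$p) < 0.05)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(rej - 0.05), 3 * se)
})

test_that("chi-square independence: identical, shifted and sparse profiles", {
  same <- chi_square_independence(c(100, 100, 100), c(50, 50, 50))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  c0 <- rep(100, 8); c4 <- c(rep(100, 7), 800)
  got <- chi_square_independence(c0, c4)
  want <- oracle_chi2(rbind(c0, c4))
  expect_equal(got$statistic, want$stat, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_lt(got$p, 0.05)
  expect_equal(got$df, 7)

  expect_error(chi_square_independence(rep(0, 5), c(1, 2, 3, 4, 5)), "zero")
  # sparse cells pooled toward the center instead of breaking the test
  sp <- chi_square_independence(c(0, 400, 0, 3, 0), c(1, 420, 0, 2, 1))
  expect_true(is.finite(sp$statistic))
  expect_lt(sp$k, 5)
})

test_that("chi-square agrees with the reference on random dense tables", {
  set.seed(71)
  for (i in 1:100) {
    k <- sample(4:15, 1)
    c0 <- rpois(k, 80) + 1
    c4 <- rpois(k, 120) + 1
    got <- chi_square_independence(c0, c4)
    if (got$k == k) {   # no pooling happened: direct comparison
      want <- oracle_chi2(rbind(c0, c4))
      expect_equal(got$statistic, want$stat, tolerance = 1e-8)
      expect_equal(got$p, want$p, tolerance = 1e-8)
    }
  }
})

test_that("chi-square type-I error sits at alpha under a multinomial null", {
  set.seed(73)
  probs <- rep(1 / 13, 13)
  rej <- mean(replicate(10000, {
    chi_square_independence(as.vector(rmultinom(1, 300, probs)),
                            as.vector(rmultinom(1, 900, probs)))$p < 0.05
  }))
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(rej - 0.05), 3 * se)
})

test_that("spacer specificity is called only when both tests reject", {
  spacers <- as.character(0:12)
  mk <- function(v) matrix(v, ncol = 1, dimnames = list(spacers, "FF"))
  base <- rpois(13, 20)

  # planted outlier at spacer 7, proportions shifted between cycles
  set.seed(79)
  c0 <- mk(rpois(13, 20))
  c4v <- rpois(13, 60); c4v[8] <- 1200
  prof <- call_spacer_specificity(c0, mk(c4v))
  expect_equal(prof$called_spacer, 7)
  expect_lt(prof$grubbs_p, 0.05)
  expect_lt(prof$chi2_p, 0.05)

  # uniform enrichment at all spacers: proportions keep, Grubbs flat
  prof2 <- call_spacer_specificity(mk(base), mk(base * 30))
  expect_true(is.na(prof2$called_spacer))

  # outlier present but proportions unchanged: chi-square blocks the call
  spike <- base; spike[8] <- 500
  prof3 <- call_spacer_specificity(mk(spike), mk(spike * 3))
  expect_gt(prof3$chi2_p, 0.05)
  expect_true(is.na(prof3$called_spacer))
})

test_that("region counting matches read counting semantics", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "GGTAATGGGGGGGTAATGGCCCCCCCCCCGGGGGGGGGG"), fa)
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t19", "chr1\t19\t39"), bed)
  rs <- extract_region_sequences(bed, fa)
  cnt <- count_spacers_in_regions("TAAT", "TAAT", rs, spacer_range = 0:8,
                                  orientations = "FF")
  expect_equal(unname(cnt["7", "FF"]), 1L)   # only the first peak has it
  expect_equal(sum(cnt, na.rm = TRUE), 1L)
  # pure-GC peaks yield all zeros
  writeLines(c(">c", "GGGGCCCCGGGGCCCCGGGG"), fa)
  writeLines("c\t0\t20", bed)
  cnt0 <- count_spacers_in_regions("AATT", "ATTA",
                                   extract_region_sequences(bed, fa),
                                   spacer_range = 0:2)
  expect_equal(sum(cnt0, na.rm = TRUE), 0L)
})
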