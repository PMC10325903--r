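# Core-site extraction and the three dimer-screen criteria.

# exhaustive window-pair search, coded independently
oracle_best_pair <- function(ic, min_spacer = 2) {
  L <- length(ic)
  win <- sapply(0:(L - 4), function(o) mean(ic[(o + 1):(o + 4)]))
  best <- NULL
  for (o1 in 0:(L - 8 - min_spacer)) {
    for (o2 in (o1 + 4 + min_spacer):(L - 4)) {
      s <- win[o1 + 1] + win[o2 + 1]
      if (is.null(best) || s > best$s + 1e-12) best <- list(s = s, o1 = o1, o2 = o2)
    }
  }
  best
}

test_that("core sites land on the highest-IC non-overlapping 4-mers", {
  # GSX2-like layout: TAAT at 0-3 and 11-14 of a 16-mer, uniform elsewhere
  x <- planted_pwm(16, list(`0` = "TAAT", `11` = "TAAT"))
  cs <- extract_core_sites(x)
  expect_equal(cs$site1$offset, 0)
  expect_equal(cs$site2$offset, 11)
  expect_equal(cs$spacer, 7)
  expect_equal(cs$site1$consensus, "TAAT")
  expect_equal(cs$site1$mean_ic, 2)

  # three candidate 4-mers; the flanking pair (2.0 + 2.0) beats any pair
  # involving the weaker middle window
  mat <- planted_pwm(16, list(`0` = "TAAT", `10` = "TAAT"))$mat
  mid <- consensus_to_pwm("TAAT", 0, eps = 0.02)$mat   # mean IC < 2
  mat[6:9, ] <- mid
  x3 <- pwm(mat)
  cs3 <- extract_core_sites(x3)
  expect_equal(c(cs3$site1$offset, cs3$site2$offset), c(0, 10))

  # all-uniform motif: tie-break picks offsets 0 and 6 (leftmost, smallest
  # spacer at the minimum separation)
  flat <- pwm(matrix(0.25, 16, 4))
  csf <- extract_core_sites(flat)
  expect_equal(c(csf$site1$offset, csf$site2$offset), c(0, 6))
  expect_equal(csf$spacer, 2)

  expect_error(extract_core_sites(pwm(matrix(0.25, 9, 4))), "short")
})

test_that("core-site extraction agrees with exhaustive search on random PWMs", {
  set.seed(21)
  for (i in 1:300) {
    L <- sample(16:18, 1)
    mat <- matrix(stats::rgamma(L * 4, shape = 0.5), ncol = 4)
    x <- pwm(mat / rowSums(mat))
    cs <- extract_core_sites(x)
    want <- oracle_best_pair(pwm_ic(x))
    expect_equal(cs$site1$offset, want$o1)
    expect_equal(cs$site2$offset, want$o2)
  }
})

make_gsx2_like_pool <- function(n = 400, L = 20, fraction = 0.3, seed = 1) {
  set.seed(seed)
  reads <- random_reads(n, L)
  k <- round(fraction * n)
  substr(reads[1:k], 3, 6) <- "TAAT"
  substr(reads[1:k], 14, 17) <- "TAAT"
  reads
}

test_that("screen passes a GSX2-like motif and reports its dimer model", {
  x <- planted_pwm(16, list(`0` = "TAAT", `11` = "TAAT"), eps = 0.01)
  pool <- make_gsx2_like_pool(fraction = 0.3)
  sc <- screen_dimer(x, pool)
  expect_true(sc$ic_pass && sc$flank_ratio_pass && sc$abundance_pass)
  expect_s3_class(sc$candidate, "dimer_model")
  expect_equal(sc$candidate$spacer, 7L)
  expect_equal(sc$candidate$consensus1, "TAAT")
  expect_gte(sc$abundance, 0.25)
})

test_that("uniformly high-IC motifs fail the over-amplification criterion", {
  # every column near-fixed: cores strong but indistinguishable from flanks
  x <- consensus_to_pwm("TAATGGCCAGTTAATG", 0)
  pool <- c(strrep("TAATGGCCAGTTAATG", 1), random_reads(9, 16))
  sc <- screen_dimer(x, pool)
  expect_true(sc$ic_pass)
  expect_false(sc$flank_ratio_pass)
  expect_null(sc$candidate)
  expect_match(paste(sc$reasons, collapse = " "), "ratio")
})

test_that("constant positive IC profiles always fail criterion 2", {
  for (eps in c(0.01, 0.1, 0.2)) {
    x <- consensus_to_pwm(strrep("A", 16), 0, eps = eps)
    sc <- screen_dimer(x, random_reads(20, 16))
    expect_false(sc$flank_ratio_pass)   # ratio is exactly 1 < 1.5
  }
})

test_that("rare motifs fail the abundance criterion", {
  x <- planted_pwm(16, list(`0` = "TAAT", `11` = "TAAT"), eps = 0.01)
  pool <- make_gsx2_like_pool(fraction = 0.01)
  sc <- screen_dimer(x, pool)
  expect_true(sc$ic_pass)
  expect_false(sc$abundance_pass)
  expect_null(sc$candidate)
})

test_that("screening is monotone in its thresholds", {
  mat <- planted_pwm(16, list(`0` = "TAAT", `11` = "TAAT"), eps = 0.05)$mat
  flanks <- c(5:11, 16)                       # mildly informative surround
  mat[flanks, ] <- rep(c(0.4, 0.2, 0.2, 0.2), each = length(flanks))
  x <- pwm(mat)
  pool <- make_gsx2_like_pool(fraction = 0.12, seed = 4)
  grid_ic <- c(0.3, 0.6, 1.0, 1.9, 2.1)
  grid_ratio <- c(1, 1.5, 3, 10)
  grid_ab <- c(0.01, 0.05, 0.2, 0.9)
  passed <- function(ic, ra, ab)
    !is.null(screen_dimer(x, pool, ic_min = ic, flank_ratio_min = ra,
                          abundance_min = ab)$candidate)
  base <- passed(0.6, 1.5, 0.05)
  expect_true(base)
  for (ic in grid_ic) for (ra in grid_ratio) for (ab in grid_ab) {
    if (ic <= 0.6 && ra <= 1.5 && ab <= 0.05) {
      expect_true(passed(ic, ra, ab))    # relaxing never un-passes
    }
  }
  # raising any single threshold beyond the observed value converts to fail
  expect_false(passed(2.1, 1.5, 0.05))
  expect_false(passed(0.6, 100, 0.05))
  expect_false(passed(0.6, 1.5, 0.99))
})

test_that("discovery recovers a planted gapped seed and stays silent on null pools", {
  # pools of a few tens of thousands of reads: below that the 0.1% seed
  # support floor admits Poisson flukes (see the methods vignette)
  set.seed(31)
  n <- 20000; L <- 20
  cycle0 <- random_reads(n, L)
  cycle4 <- random_reads(n, L)
  k <- round(0.4 * n)
  substr(cycle4[1:k], 2, 5) <- "TAAT"
  substr(cycle4[1:k], 13, 16) <- "TAAT"    # spacer 7
  motifs <- discover_long_motifs(cycle4, cycle0)
  expect_gt(length(motifs), 0)
  seed <- attr(motifs[[1]], "seed")
  sig <- paste0(seed$site1, "_", seed$spacer, "_", seed$site2)
  expect_true(sig %in% c("TAAT_7_TAAT", "ATTA_7_ATTA"))
  # the planted cores carry high IC, the spacer does not
  ic <- pwm_ic(motifs[[1]])
  cs <- extract_core_sites(motifs[[1]])
  expect_gt(min(cs$site1$mean_ic, cs$site2$mean_ic), 1.5)
  expect_equal(cs$spacer, 7)

  # no selection: cycle 4 == cycle 0 distribution -> no enriched seed
  expect_warning(m0 <- discover_long_motifs(random_reads(n, L), cycle0),
                 "seed")
  expect_length(m0, 0)

  # monomer-only planting: no gapped pair enriched
  mono <- random_reads(n, L)
  substr(mono[1:k], 5, 8) <- "TAAT"
  expect_warning(mm <- discover_long_motifs(mono, cycle0), "seed")
  expect_length(mm, 0)
})
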