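# Dimer/monomer counting, ln fold changes, slopes, enrichment factor.

test_that("dimer-configuration counting matches hand-checkable placements", {
  dm <- dimer_model("TAAT", "TAAT", spacer = 7)
  expect_equal(count_dimer_reads(dm, "TAATGGGGGGGTAAT")$count, 1)
  # 8-bp spacer does not match the 7-bp model
  expect_equal(count_dimer_reads(dm, "TAATGGGGGGGGTAAT")$count, 0)
  # reverse complement of the whole configuration is the same event
  expect_equal(count_dimer_reads(dm, "ATTACCCCCCCATTA")$count, 1)
  # N inside a core breaks the match; N in the spacer is tolerated
  expect_equal(count_dimer_reads(dm, "TANTGGGGGGGTAAT")$count, 0)
  expect_equal(count_dimer_reads(dm, "TAATGGGNGGGTAAT")$count, 1)

  fr <- dimer_model("TAAT", "TAAT", spacer = 3, orientation = "FR")
  expect_equal(count_dimer_reads(fr, "TAATGGGATTA")$count, 1)
  expect_equal(count_dimer_reads(fr, "TAATGGGTAAT")$count, 0)
})

test_that("random-pool dimer fractions match the brute-force oracle", {
  set.seed(41)
  reads <- random_reads(1000, 20)
  dm <- dimer_model("TAAT", "TAAT", spacer = 7)
  got <- count_dimer_reads(dm, reads)
  want <- sum(vapply(reads, oracle_has_config, logical(1),
                     site1 = "TAAT", site2 = "TAAT", s = 7))
  expect_equal(got$count, want)
  # and within 3 binomial SE of the analytic occurrence probability:
  # 12 placements (6 per strand) x 4^-8 each, rare-event union bound
  p <- 12 / 4^8
  expect_lt(abs(got$fraction - p), 3 * sqrt(p * (1 - p) / 1000) + p^2)
})

test_that("monomer counting masks dimer-containing reads", {
  dm <- dimer_model("TAAT", "TAAT", spacer = 7)
  reads <- c("TAATGGGGGGGTAAT", "TAATGGGGGGGGGGG")
  got <- count_monomer_reads("TAAT", dm, reads)
  expect_equal(got$count, 1)          # the dimer read is masked
  expect_equal(got$fraction, 0.5)
  # all reads dimer-positive -> full masking
  expect_equal(count_monomer_reads("TAAT", dm,
                                   rep("TAATGGGGGGGTAAT", 5))$count, 0)
})

test_that("monomer counting equals the two-pass filter on mixed pools", {
  set.seed(43)
  reads <- random_reads(2000, 20)
  k <- 150
  substr(reads[1:k], 1, 4) <- "TAAT"
  substr(reads[1:k], 12, 15) <- "TAAT"
  dm <- dimer_model("TAAT", "TAAT", spacer = 7)
  got <- count_monomer_reads("TAAT", dm, reads)
  dimered <- vapply(reads, oracle_has_config, logical(1),
                    site1 = "TAAT", site2 = "TAAT", s = 7)
  want <- sum(vapply(reads[!dimered], oracle_has_site, logical(1),
                     site = "TAAT"))
  expect_equal(got$count, want)
  # masking conservation: categories partition the site-containing reads
  d <- count_dimer_reads(dm, reads)
  expect_lte(d$count + got$count, length(reads))
})

test_that("ln fold change follows the closed forms", {
  expect_equal(ln_fold_change(0.3, 0.3, 0), 0)
  expect_equal(ln_fold_change(exp(1) * 0.01, 0.01, 0), 1)
  expect_equal(ln_fold_change(0, 0.01, 1e-6), log(1e-6 / 0.010001))
  expect_error(ln_fold_change(0, 0, 0), "positive")
})

test_that("OLS slope fitting is exact on lines and unbiased under noise", {
  expect_equal(fit_enrichment_slope(0:4, 0:4)$slope, 1)
  two <- fit_enrichment_slope(c(0, 4), c(0, 6.04))
  expect_equal(two$slope, 1.51)
  expect_error(fit_enrichment_slope(c(2, 2, 2), c(1, 2, 3)), "identical")
  expect_error(fit_enrichment_slope(1, 1), "points")

  set.seed(47)
  slopes <- replicate(500, {
    y <- 0.7 * (0:4) + rnorm(5, sd = 0.3)
    fit_enrichment_slope(0:4, y)$slope
  })
  se <- 0.3 / sqrt(sum((0:4 - 2)^2)) / sqrt(500)
  expect_lt(abs(mean(slopes) - 0.7), 3 * se)
})

test_that("enrichment factor reproduces the worked example and guards the
           denominator", {
  expect_equal(round(enrichment_factor(1.51, 0.4, 0.4), 2), 3.78)
  expect_equal(enrichment_factor(1, 1, 1), 1)
  expect_equal(enrichment_factor(2, 0.5, 1.5), 2)
  ef <- enrichment_factor(1.5, -0.2, 0.1)
  expect_true(is.na(ef))
  expect_match(attr(ef, "reason"), "monomer slope")
})

test_that("EF is stable under uniform 10% subsampling of every cycle", {
  dm <- dimer_model("TAAT", "TAAT", spacer = 7)
  cyc <- simulate_selex(selex_sim_params(library_size = 50000, omega = 50,
                                         seed = 301))
  ef_full <- as.numeric(enrichment_curve(dm, cyc)$ef)
  rel <- vapply(1:4, function(d) {
    sub <- lapply(seq_along(cyc$cycles), function(i)
      subsample_reads(cyc$cycles[[i]], 5000, seed = d * 10 + i))
    names(sub) <- names(cyc$cycles)
    ef <- as.numeric(enrichment_curve(dm, selex_cycles(sub))$ef)
    abs(ef - ef_full) / ef_full
  }, numeric(1))
  expect_lt(mean(rel), 0.10)
})

test_that("enrichment curves assemble fractions, ln fc and EF per cycle", {
  set.seed(49)
  base <- random_reads(600, 20)
  enrich <- function(frac_dimer, frac_mono) {
    r <- random_reads(600, 20)
    kd <- round(frac_dimer * 600); km <- round(frac_mono * 600)
    if (kd > 0) {
      substr(r[1:kd], 3, 6) <- "TAAT"
      substr(r[1:kd], 14, 17) <- "TAAT"
    }
    if (km > 0) substr(r[(kd + 1):(kd + km)], 8, 11) <- "TAAT"
    r
  }
  cyc <- selex_cycles(list(`0` = base, `1` = enrich(0.05, 0.2),
                           `2` = enrich(0.15, 0.3),
                           `3` = enrich(0.35, 0.4),
                           `4` = enrich(0.6, 0.4)))
  dm <- dimer_model("TAAT", "TAAT", spacer = 7)
  cv <- enrichment_curve(dm, cyc)
  expect_equal(cv$table$ln_fc_dimer[1], 0)   # cycle 0 is the reference
  expect_equal(cv$table$ln_fc_site1[1], 0)
  expect_true(all(cv$table$dimer_fraction >= 0 &
                    cv$table$dimer_fraction <= 1))
  expect_gt(cv$slopes$dimer$slope, 0)
  # EF consistency with its definition
  expect_equal(as.numeric(cv$ef),
               cv$slopes$dimer$slope /
                 mean(c(cv$slopes$site1$slope, cv$slopes$site2$slope)))
  # slope fit is over all five cycles
  expect_equal(cv$table$cycle, 0:4)

  no0 <- selex_cycles(list(`1` = base, `2` = base))
  expect_error(enrichment_curve(dm, no0), "cycle 0")
})
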