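# COSMO-style spacer-length profiling: count two-site configurations at
# every spacer length and orientation, then test spacer specificity with a
# Grubbs max-outlier test (cycle 4) and a chi-square test of independence
# (cycle 0 vs cycle 4).

#' Count two-site configurations at every spacer length and orientation
#'
#' For each spacer `s` and orientation, counts the reads containing at
#' least one (site1, s-bp gap, site2) configuration; matches on either
#' strand of a read are the same event and a read contributes at most once
#' per cell. Cells whose configuration cannot fit the reads
#' (`8 + s >` read length) are `NA` ("unobservable"), not zero -
#' zero-filling would fabricate evidence for outliers in the downstream
#' tests.
#'
#' @param site1,site2 `"core_site"` objects or 4-letter consensus strings.
#' @param reads character vector or `DNAStringSet`.
#' @param spacer_range integer vector of spacer lengths (default 0:20).
#' @param orientations subset of `"FF"`, `"FR"`, `"RF"` (`"RR"` is the
#'   reverse complement of `"FF"` and is folded into it).
#' @param mismatches mismatch budget per configuration.
#' @return integer matrix (spacer x orientation) with `NA` for
#'   unobservable cells; the number of reads is in attribute `n_reads`.
#' @export
count_spacers <- function(site1, site2, reads, spacer_range = 0:20,
                          orientations = c("FF", "FR", "RF"),
                          mismatches = 0) {
  if (!length(reads)) stop("reads is empty", call. = FALSE)
  orientations <- match.arg(orientations, c("FF", "FR", "RF"),
                            several.ok = TRUE)
  dss <- as_dss(reads)
  max_len <- max(Biostrings::width(dss))
  out <- matrix(NA_integer_, nrow = length(spacer_range),
                ncol = length(orientations),
                dimnames = list(spacer = as.character(spacer_range),
                                orientation = orientations))
  for (i in seq_along(spacer_range)) {
    s <- spacer_range[i]
    if (8 + s > max_len) next
    for (o in orientations) {
      pats <- config_patterns(site1, site2, s, o)
      hit <- rep(FALSE, length(dss))
      for (p in pats) hit <- hit | count_occurrences(p, dss, mismatches) > 0
      out[i, o] <- sum(hit)
    }
  }
  attr(out, "n_reads") <- length(dss)
  out
}

#' Count spacer configurations within genomic regions
#'
#' Identical counting semantics to [count_spacers()], applied to the
#' sequences of a region set (e.g. called peaks); a region contributes at
#' most once per (spacer, orientation) cell and configurations never span
#' region boundaries.
#'
#' @param regions a `"region_set"` from [extract_region_sequences()].
#' @inheritParams count_spacers
#' @return as [count_spacers()].
#' @export
count_spacers_in_regions <- function(site1, site2, regions,
                                     spacer_range = 0:20,
                                     orientations = c("FF", "FR", "RF"),
                                     mismatches = 0) {
  stopifnot(inherits(regions, "region_set"))
  if (!length(regions$sequences)) stop("regions is empty", call. = FALSE)
  count_spacers(site1, site2, regions$sequences, spacer_range, orientations,
                mismatches)
}

#' One-sided Grubbs test for a single maximum outlier
#'
#' `G = (max - mean) / sd`; the p-value comes from the t-distribution form
#' of the Grubbs statistic with `n` = number of observable cells. A
#' zero-variance vector returns `G = 0, p = 1`.
#'
#' @param counts numeric vector (>= 3 non-missing values; `NA` cells are
#'   dropped).
#' @return list with `G`, `p`, `n` and `which_max` (index into `counts`).
#' @export
grubbs_max_test <- function(counts) {
  x <- counts[!is.na(counts)]
  n <- length(x)
  if (n < 3) stop("Grubbs test needs >= 3 observable cells", call. = FALSE)
  s <- stats::sd(x)
  which_max <- which(!is.na(counts))[which.max(x)]
  if (s == 0) return(list(G = 0, p = 1, n = n, which_max = which_max))
  G <- (max(x) - mean(x)) / s
  den <- (n - 1)^2 - n * G^2
  p <- if (den <= 0) 0 else {
    t <- sqrt(n * (n - 2) * G^2 / den)
    min(1, n * stats::pt(t, df = n - 2, lower.tail = FALSE))
  }
  list(G = G, p = p, n = n, which_max = which_max)
}

# Pool cells whose expected count under the margins is below `floor` into
# the adjacent cell toward the center of the range, the standard validity
# repair for sparse contingency tables.
pool_sparse_cells <- function(tab, floor = 1) {
  groups <- as.list(seq_len(ncol(tab)))
  repeat {
    k <- length(groups)
    if (k <= 2) break
    m <- sapply(groups, function(g) rowSums(tab[, g, drop = FALSE]))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(tab))
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    worst <- which.min(apply(expected, 2, min))
    if (min(expected[, worst]) >= floor) break
    center <- (k + 1) / 2
    neighbor <- if (worst < center) worst + 1 else worst - 1
    groups[[neighbor]] <- c(groups[[neighbor]], groups[[worst]])
    groups[[worst]] <- NULL
  }
  m <- sapply(groups, function(g) rowSums(tab[, g, drop = FALSE]))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(tab))
  list(table = m, groups = groups)
}

#' Chi-square test of independence between two cycles' spacer profiles
#'
#' Builds the 2 x K contingency table (cycle x spacer), pools cells with
#' expected count below 1 into a neighbor toward the center of the range,
#' and tests independence without continuity correction (K - 1 degrees of
#' freedom after pooling).
#'
#' @param counts_cycle0,counts_cycle4 count vectors over the same spacer
#'   cells (`NA` cells are dropped pairwise).
#' @return list with `statistic`, `p`, `df` and `k` (cells after pooling).
#' @export
chi_square_independence <- function(counts_cycle0, counts_cycle4) {
  if (length(counts_cycle0) != length(counts_cycle4))
    stop("count vectors must cover the same spacer cells", call. = FALSE)
  keep <- !is.na(counts_cycle0) & !is.na(counts_cycle4)
  c0 <- counts_cycle0[keep]; c4 <- counts_cycle4[keep]
  if (sum(c0) == 0 || sum(c4) == 0)
    stop("all counts zero in one cycle; test undefined", call. = FALSE)
  drop <- c0 + c4 == 0
  c0 <- c0[!drop]; c4 <- c4[!drop]
  if (length(c0) < 2) return(list(statistic = 0, p = 1, df = 0, k = length(c0)))
  pooled <- pool_sparse_cells(rbind(c0, c4))
  tt <- suppressWarnings(stats::chisq.test(pooled$table, correct = FALSE))
  list(statistic = unname(tt$statistic), p = unname(tt$p.value),
       df = unname(tt$parameter), k = ncol(pooled$table))
}

#' Call spacer-length specificity from two cycles' spacer counts
#'
#' Runs the Grubbs max-outlier test on the cycle-4 counts and the
#' chi-square independence test on (cycle 0, cycle 4), per orientation.
#' The orientation with the smallest Grubbs p is reported and both
#' p-values are Bonferroni-corrected by the number of orientations
#' tested. A spacer is called - the selection is spacer-specific - only
#' when both corrected p-values fall below `alpha`; the called spacer is
#' the maximal cell of the winning orientation.
#'
#' @param counts0,counts4 spacer x orientation matrices from
#'   [count_spacers()] on the initial library and final cycle.
#' @param alpha significance level for both tests.
#' @return object of class `"spacer_profile"`: per-orientation test table,
#'   winning `orientation`, corrected `grubbs_p` / `chi2_p`, and
#'   `called_spacer` (bp, or `NA` when no call is made).
#' @export
call_spacer_specificity <- function(counts0, counts4, alpha = 0.05) {
  stopifnot(identical(dim(counts0), dim(counts4)))
  orientations <- colnames(counts4)
  spacers <- as.integer(rownames(counts4))
  res <- lapply(orientations, function(o) {
    keep <- !is.na(counts0[, o]) & !is.na(counts4[, o])
    g <- grubbs_max_test(ifelse(keep, counts4[, o], NA))
    chi <- chi_square_independence(counts0[, o], counts4[, o])
    data.frame(orientation = o, grubbs_G = g$G, grubbs_p = g$p,
               chi2 = chi$statistic, chi2_p = chi$p,
               top_spacer = spacers[g$which_max])
  })
  res <- do.call(rbind, res)
  n_or <- length(orientations)
  best <- which.min(res$grubbs_p)
  grubbs_p <- min(1, res$grubbs_p[best] * n_or)
  chi2_p <- min(1, res$chi2_p[best] * n_or)
  called <- if (grubbs_p < alpha && chi2_p < alpha)
    res$top_spacer[best] else NA_integer_
  structure(list(per_orientation = res,
                 orientation = res$orientation[best],
                 grubbs_p = grubbs_p, chi2_p = chi2_p, alpha = alpha,
                 called_spacer = called,
                 counts0 = counts0, counts4 = counts4),
            class = "spacer_profile")
}

#' @export
print.spacer_profile <- function(x, ...) {
  cat("spacer-specificity profile\n")
  print(x$per_orientation, row.names = FALSE, digits = 3)
  cat(sprintf("best orientation %s: Grubbs p = %.3g, chi-square p = %.3g (Bonferroni x%d)\n",
              x$orientation, x$grubbs_p, x$chi2_p,
              nrow(x$per_orientation)))
  if (is.na(x$called_spacer)) cat("no spacer-specific selection called\n")
  else cat(sprintf("called spacer: %d bp\n", x$called_spacer))
  invisible(x)
}
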