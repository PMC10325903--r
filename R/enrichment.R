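# Dimer versus monomer site enrichment across SELEX cycles: per-cycle
# occurrence fractions, ln fold changes, fitted slopes and the enrichment
# factor EF.

#' Count reads containing a dimer-site configuration
#'
#' A read counts when it holds at least one occurrence of site1 and site2 at
#' exactly the model's spacer and orientation; the configuration and its
#' full reverse complement are the same binding event, so matches on either
#' strand count once.
#'
#' @param dimer a [dimer_model()].
#' @param reads character vector or `DNAStringSet`.
#' @param mismatches mismatch budget per configuration (spacer positions are
#'   unconstrained and consume none of it); default 0, i.e. exact consensus
#'   matching at both cores.
#' @return list with `count` and `fraction` (count / number of reads).
#' @export
count_dimer_reads <- function(dimer, reads, mismatches = 0) {
  if (!length(reads)) stop("reads is empty", call. = FALSE)
  hit <- config_hits(dimer, reads, mismatches)
  list(count = sum(hit), fraction = mean(hit))
}

#' Count dimer-free reads containing a monomer 4-mer site
#'
#' Reads containing the dimer configuration are masked before counting, so
#' the monomer enrichment rate is not inflated by the dimer's constituent
#' sites; the count is of reads with no dimer occurrence but at least one
#' match to the 4-mer on either strand.
#'
#' @param site a `"core_site"` or 4-letter consensus string.
#' @param dimer the [dimer_model()] whose occurrences are masked.
#' @inheritParams count_dimer_reads
#' @return list with `count` and `fraction` (over all reads, masked
#'   included).
#' @export
count_monomer_reads <- function(site, dimer, reads, mismatches = 0) {
  if (!length(reads)) stop("reads is empty", call. = FALSE)
  masked <- config_hits(dimer, reads, mismatches)
  hit <- !masked & site_hits(site, reads, mismatches)
  list(count = sum(hit), fraction = mean(hit))
}

#' Natural-log fold change of an occurrence fraction
#'
#' SELEX enrichment is exponential across cycles (selection plus PCR), so
#' fold changes are linearized by the natural logarithm:
#' `ln((fraction_c + pseudo) / (fraction_0 + pseudo))`.
#'
#' @param fraction_c fraction at cycle c.
#' @param fraction_0 fraction in the initial library.
#' @param pseudo pseudocount fraction added to numerator and denominator;
#'   guards cycle-0 zeros.
#' @return dimensionless ln fold change (vectorized over `fraction_c`).
#' @export
ln_fold_change <- function(fraction_c, fraction_0, pseudo = 0) {
  if (fraction_0 + pseudo <= 0)
    stop("fraction_0 + pseudo must be positive", call. = FALSE)
  log((fraction_c + pseudo) / (fraction_0 + pseudo))
}

#' Fit an enrichment slope by ordinary least squares
#'
#' Regresses ln fold change on cycle index with a free intercept (PCR
#' efficiency offsets between cycle 0 and cycle 1 land in the intercept, and
#' dimer and monomer fits share that treatment, keeping the slope
#' comparison fair).
#'
#' @param cycle cycle indices (>= 2 distinct values).
#' @param ln_fc ln fold changes, same length.
#' @return list with `slope` (per cycle), `intercept` and `r_squared`.
#' @export
fit_enrichment_slope <- function(cycle, ln_fc) {
  if (length(cycle) != length(ln_fc) || length(cycle) < 2)
    stop("need >= 2 (cycle, ln_fc) points", call. = FALSE)
  if (length(unique(cycle)) < 2)
    stop("all cycle indices identical; slope undefined", call. = FALSE)
  fit <- stats::lm(ln_fc ~ cycle)
  sst <- sum((ln_fc - mean(ln_fc))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Enrichment factor: dimer slope over mean monomer slope
#'
#' `EF = slope_dimer / ((slope_site1 + slope_site2) / 2)`. An EF above 2
#' marks the dimer configuration as enriching faster than expected from
#' finding its two monomer sites, the signature of cooperative binding.
#' When the mean monomer slope is not positive the ratio has no enrichment
#' interpretation and `NA` is returned (flagged via the `"reason"`
#' attribute), never a spuriously "cooperative" negative value.
#'
#' @param slope_dimer,slope_site1,slope_site2 fitted per-cycle slopes.
#' @return the EF, or flagged `NA`.
#' @export
enrichment_factor <- function(slope_dimer, slope_site1, slope_site2) {
  denom <- (slope_site1 + slope_site2) / 2
  if (!is.finite(denom) || denom <= 0) {
    return(structure(NA_real_, reason = "mean monomer slope not positive"))
  }
  slope_dimer / denom
}

#' Per-cycle enrichment curve for a dimer model
#'
#' Computes, for every cycle in the set, the fraction of reads containing
#' the dimer configuration and the fractions of dimer-free reads containing
#' each core 4-mer; ln fold changes against cycle 0; OLS slopes; and the
#' enrichment factor. Fractions (not raw counts) normalize unequal pool
#' sizes across cycles.
#'
#' @param dimer a [dimer_model()].
#' @param cycles a [selex_cycles()] object containing cycle 0 and at least
#'   one later cycle.
#' @param pseudo pseudocount fraction; default `NULL` uses half a read of
#'   the respective cycle's pool (0.5 / pool size), since cycle-0 dimer
#'   counts of long configurations are often 0 at desk scale.
#' @param mismatches mismatch budget per configuration.
#' @return an object of class `"enrichment_curve"`: a per-cycle table plus
#'   `slopes` (each with slope and R-squared), `ef` and the model.
#' @export
enrichment_curve <- function(dimer, cycles, pseudo = NULL, mismatches = 0) {
  stopifnot(inherits(cycles, "selex_cycles"))
  idx <- as.integer(names(cycles$cycles))
  if (!0 %in% idx)
    stop("initial library required: enrichment slopes need cycle 0",
         call. = FALSE)
  if (length(idx) < 2)
    stop("need at least 2 cycles for a slope fit", call. = FALSE)
  rows <- lapply(names(cycles$cycles), function(k) {
    reads <- as_dss(cycles$cycles[[k]])
    d <- count_dimer_reads(dimer, reads, mismatches)
    m1 <- count_monomer_reads(dimer$consensus1, dimer, reads, mismatches)
    m2 <- count_monomer_reads(dimer$consensus2, dimer, reads, mismatches)
    data.frame(cycle = as.integer(k), n_reads = length(reads),
               dimer_count = d$count, dimer_fraction = d$fraction,
               site1_count = m1$count, site1_fraction = m1$fraction,
               site2_count = m2$count, site2_fraction = m2$fraction)
  })
  tab <- do.call(rbind, rows)
  ps <- if (is.null(pseudo)) 0.5 / tab$n_reads else rep(pseudo, nrow(tab))
  i0 <- which(tab$cycle == 0)
  lfc <- function(fr) log((fr + ps) / (fr[i0] + ps[i0]))
  tab$ln_fc_dimer <- lfc(tab$dimer_fraction)
  tab$ln_fc_site1 <- lfc(tab$site1_fraction)
  tab$ln_fc_site2 <- lfc(tab$site2_fraction)
  slopes <- list(dimer = fit_enrichment_slope(tab$cycle, tab$ln_fc_dimer),
                 site1 = fit_enrichment_slope(tab$cycle, tab$ln_fc_site1),
                 site2 = fit_enrichment_slope(tab$cycle, tab$ln_fc_site2))
  ef <- enrichment_factor(slopes$dimer$slope, slopes$site1$slope,
                          slopes$site2$slope)
  structure(list(table = tab, slopes = slopes, ef = ef, dimer = dimer,
                 pseudo = ps), class = "enrichment_curve")
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("enrichment curve for %s-%dN-%s (%s), cycles %s\n",
              x$dimer$consensus1, x$dimer$spacer, x$dimer$consensus2,
              x$dimer$orientation, paste(x$table$cycle, collapse = ",")))
  print(x$table[, c("cycle", "dimer_fraction", "site1_fraction",
                    "ln_fc_dimer", "ln_fc_site1")], row.names = FALSE,
        digits = 3)
  cat(sprintf("slopes: dimer %.3f (R2 %.2f), monomer %.3f / %.3f\n",
              x$slopes$dimer$slope, x$slopes$dimer$r_squared,
              x$slopes$site1$slope, x$slopes$site2$slope))
  cat(sprintf("enrichment factor EF = %s\n",
              if (is.na(x$ef)) "undefined (mean monomer slope <= 0)"
              else sprintf("%.2f", x$ef)))
  invisible(x)
}
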