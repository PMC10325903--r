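# Dimer-site screening: pick the two highest-information 4-mer core sites
# within a long motif and apply the three selection criteria.

new_core_site <- function(x, offset) {
  sub <- pwm(x$mat[(offset + 1):(offset + 4), , drop = FALSE],
             name = sprintf("%s_core%d", x$name, offset))
  structure(list(pwm4 = sub,
                 offset = offset,
                 consensus = pwm_consensus(sub),
                 mean_ic = mean(pwm_ic(sub))),
            class = "core_site")
}

#' @export
print.core_site <- function(x, ...) {
  cat(sprintf("core site %s @ offset %d (mean IC %.2f bits)\n",
              x$consensus, x$offset, x$mean_ic))
  invisible(x)
}

as_site_consensus <- function(site) {
  if (inherits(site, "core_site")) site$consensus
  else if (is.character(site) && length(site) == 1) toupper(site)
  else stop("site must be a core_site or a consensus string", call. = FALSE)
}

#' Extract the two core 4-mer sites of a long motif
#'
#' Finds the pair of non-overlapping 4-column windows, separated by at least
#' `min_spacer` bp, that maximizes the sum of the two windows' mean
#' information contents. Ties are broken by the leftmost site-1 offset, then
#' by the smallest spacer.
#'
#' @param x a [pwm()] of length >= 10 (two 4-mers plus the minimum spacer).
#' @param min_spacer minimum gap in bp between the two 4-mers (homeodomain
#'   default 2).
#' @return list with elements `site1` and `site2` (class `"core_site"`;
#'   site1 is the leftmost) and `spacer` (bp between site1 end and site2
#'   start).
#' @export
extract_core_sites <- function(x, min_spacer = 2) {
  L <- nrow(x$mat)
  if (L < 8 + min_spacer)
    stop(sprintf("motif too short (%d bp) for two 4-mers %d bp apart",
                 L, min_spacer), call. = FALSE)
  ic <- pwm_ic(x)
  win <- sapply(0:(L - 4), function(o) mean(ic[(o + 1):(o + 4)]))
  best <- NULL
  for (o1 in 0:(L - 8 - min_spacer)) {
    for (o2 in (o1 + 4 + min_spacer):(L - 4)) {
      s <- win[o1 + 1] + win[o2 + 1]
      # strict > keeps the earliest (o1, then smallest spacer) on ties,
      # because o1 ascends in the outer loop and o2 in the inner
      if (is.null(best) || s > best$s + 1e-12) best <- list(s = s, o1 = o1, o2 = o2)
    }
  }
  list(site1 = new_core_site(x, best$o1),
       site2 = new_core_site(x, best$o2),
       spacer = best$o2 - (best$o1 + 4))
}

#' Define a dimer-site model
#'
#' The unit handed to all downstream counting: two 4-mer core sites, a
#' spacer length and a relative orientation. `"FF"` is head-to-tail (both
#' sites on the same strand), `"FR"` head-to-head (site2 reverse
#' complemented), `"RF"` the mirror case; a tail-to-tail `"RR"` arrangement
#' is the reverse complement of an `"FF"` one and is folded into it.
#'
#' @param site1,site2 `"core_site"` objects or 4-letter consensus strings.
#' @param spacer gap in bp between site1 end and site2 start (>= 0; the
#'   homeodomain screen only produces spacers >= 2).
#' @param orientation `"FF"`, `"FR"` or `"RF"`.
#' @param source_motif optional [pwm()] the sites were extracted from.
#' @param abundance_cycle4 optional fraction of cycle-4 reads containing the
#'   source motif.
#' @return an object of class `"dimer_model"`.
#' @export
dimer_model <- function(site1, site2, spacer, orientation = "FF",
                        source_motif = NULL, abundance_cycle4 = NA_real_) {
  orientation <- match.arg(orientation, c("FF", "FR", "RF"))
  if (!is_count(spacer) || spacer < 0)
    stop("spacer must be a non-negative integer", call. = FALSE)
  s1 <- as_site_consensus(site1)
  s2 <- as_site_consensus(site2)
  if (nchar(s1) != 4 || nchar(s2) != 4)
    stop("core sites must be 4-mers", call. = FALSE)
  structure(list(
    site1 = if (inherits(site1, "core_site")) site1 else NULL,
    site2 = if (inherits(site2, "core_site")) site2 else NULL,
    consensus1 = s1, consensus2 = s2,
    spacer = as.integer(spacer), orientation = orientation,
    source_motif = source_motif,
    abundance_cycle4 = abundance_cycle4), class = "dimer_model")
}

#' @export
print.dimer_model <- function(x, ...) {
  cat(sprintf("dimer model: %s-%dN-%s (%s)%s\n", x$consensus1, x$spacer,
              x$consensus2, x$orientation,
              if (is.na(x$abundance_cycle4)) "" else
                sprintf(", cycle-4 abundance %.1f%%", 100 * x$abundance_cycle4)))
  invisible(x)
}

# The configuration pattern(s) to search for: the configuration and its full
# reverse complement are the same binding event, so both are scanned on the
# forward strand of the reads (deduplicated when palindromic).
config_patterns <- function(site1, site2, spacer, orientation = "FF") {
  s1 <- as_site_consensus(site1)
  s2 <- as_site_consensus(site2)
  p <- switch(orientation,
              FF = paste0(s1, strrep("N", spacer), s2),
              FR = paste0(s1, strrep("N", spacer), revcomp(s2)),
              RF = paste0(revcomp(s1), strrep("N", spacer), s2))
  unique(c(p, revcomp(p)))
}

# Logical vector: which reads contain >= 1 occurrence of the configuration.
config_hits <- function(dimer, reads, mismatches = 0) {
  dss <- as_dss(reads)
  pats <- config_patterns(dimer$consensus1, dimer$consensus2, dimer$spacer,
                          dimer$orientation)
  hit <- rep(FALSE, length(dss))
  for (p in pats) hit <- hit | count_occurrences(p, dss, mismatches) > 0
  hit
}

# Which reads contain >= 1 match to a 4-mer consensus on either strand.
site_hits <- function(site, reads, mismatches = 0) {
  dss <- as_dss(reads)
  s <- as_site_consensus(site)
  pats <- unique(c(s, revcomp(s)))
  hit <- rep(FALSE, length(dss))
  for (p in pats) hit <- hit | count_occurrences(p, dss, mismatches) > 0
  hit
}

#' Screen a long motif for a dimer site
#'
#' Applies the three dimer-site criteria to a candidate long motif:
#' \enumerate{
#'   \item both core 4-mers' mean information content exceeds `ic_min`;
#'   \item each core's mean IC is at least `flank_ratio_min` times the mean
#'     IC of the surrounding motif columns, which rejects motifs born of
#'     PCR over-amplification (uniformly high IC across the whole PWM);
#'   \item at least `abundance_min` of the cycle-4 reads contain a
#'     full-length match to the motif on either strand.
#' }
#' Failures are results, not errors: the returned object carries a flag per
#' criterion and the reasons for rejection.
#'
#' @param x the candidate long motif, a [pwm()] (16-18 bp typically). With
#'   a match-score threshold (e.g. from a Homer file) criterion 3 scans the
#'   full PWM; without one, a read matches when both cores match their
#'   consensus at the extracted spacer, whatever the spacer and flank
#'   content.
#' @param cycle4_reads reads of the final selection cycle.
#' @param ic_min minimum mean core IC in bits.
#' @param flank_ratio_min minimum core-to-surround IC ratio.
#' @param abundance_min minimum fraction of cycle-4 reads with a motif match.
#' @param surround which columns count as the surround for criterion 2:
#'   everything outside the two core windows (`"pooled"`, the default), only
#'   the flanks, or only the spacer.
#' @param min_spacer minimum core separation passed to
#'   [extract_core_sites()].
#' @return an object of class `"dimer_screen"`; its `candidate` element is a
#'   [dimer_model()] when all three criteria pass, otherwise `NULL`.
#' @export
screen_dimer <- function(x, cycle4_reads, ic_min = 0.6, flank_ratio_min = 1.5,
                         abundance_min = 0.05,
                         surround = c("pooled", "flanks_only", "spacer_only"),
                         min_spacer = 2) {
  surround <- match.arg(surround)
  if (!length(cycle4_reads)) stop("cycle4_reads is empty", call. = FALSE)
  cores <- extract_core_sites(x, min_spacer = min_spacer)
  s1 <- cores$site1; s2 <- cores$site2
  ic <- pwm_ic(x)
  core_cols <- c(s1$offset + 1:4, s2$offset + 1:4)
  spacer_cols <- if (s2$offset > s1$offset + 4)
    (s1$offset + 5):s2$offset else integer(0)
  sur_cols <- switch(surround,
    pooled = setdiff(seq_along(ic), core_cols),
    flanks_only = setdiff(seq_along(ic), c(core_cols, spacer_cols)),
    spacer_only = spacer_cols)
  sur_ic <- if (length(sur_cols)) mean(ic[sur_cols]) else 0

  ic_pass <- s1$mean_ic > ic_min && s2$mean_ic > ic_min
  flank_pass <- s1$mean_ic >= flank_ratio_min * sur_ic &&
    s2$mean_ic >= flank_ratio_min * sur_ic

  # Criterion 3: fraction of cycle-4 reads containing the motif. With a
  # supplied match-score threshold (Homer header) the full PWM is scanned
  # on both strands; without one, a read counts when it contains the
  # extracted core configuration (site1, spacer, site2 consensus, either
  # strand). A single scalar threshold cannot separate core-exact from
  # core-broken matches once the flank score spread exceeds the core
  # mismatch gap, so configuration counting is the exact semantics here.
  if (!is.null(x$threshold)) {
    ab <- count_pwm_hits(x, cycle4_reads)
  } else {
    hit <- config_hits(dimer_model(s1, s2, cores$spacer), cycle4_reads)
    ab <- list(count = sum(hit), fraction = mean(hit))
  }
  abundance_pass <- ab$fraction >= abundance_min

  reasons <- c(if (!ic_pass) "core IC below threshold",
               if (!flank_pass) "core-to-surround IC ratio below threshold",
               if (!abundance_pass) "motif abundance below threshold")
  candidate <- NULL
  if (ic_pass && flank_pass && abundance_pass) {
    candidate <- dimer_model(s1, s2, cores$spacer, orientation = "FF",
                             source_motif = x,
                             abundance_cycle4 = ab$fraction)
  }
  structure(list(candidate = candidate, ic_pass = ic_pass,
                 flank_ratio_pass = flank_pass,
                 abundance_pass = abundance_pass,
                 reasons = reasons,
                 core_ic = c(site1 = s1$mean_ic, site2 = s2$mean_ic),
                 surround_ic = sur_ic, abundance = ab$fraction,
                 sites = cores,
                 thresholds = c(ic_min = ic_min,
                                flank_ratio_min = flank_ratio_min,
                                abundance_min = abundance_min)),
            class = "dimer_screen")
}

#' @export
print.dimer_screen <- function(x, ...) {
  cat("dimer screen:",
      if (is.null(x$candidate)) "REJECTED" else "PASSED", "\n")
  cat(sprintf("  core IC: %.2f / %.2f bits (min %.2f)  [%s]\n",
              x$core_ic[1], x$core_ic[2], x$thresholds["ic_min"],
              if (x$ic_pass) "pass" else "fail"))
  cat(sprintf("  surround IC: %.2f bits, ratio min %.1f  [%s]\n",
              x$surround_ic, x$thresholds["flank_ratio_min"],
              if (x$flank_ratio_pass) "pass" else "fail"))
  cat(sprintf("  cycle-4 abundance: %.1f%% (min %.0f%%)  [%s]\n",
              100 * x$abundance, 100 * x$thresholds["abundance_min"],
              if (x$abundance_pass) "pass" else "fail"))
  if (!is.null(x$candidate)) print(x$candidate)
  invisible(x)
}
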