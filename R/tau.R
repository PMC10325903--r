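# Tau cooperativity from EMSA band proportions.
#
# Each lane of a shift assay resolves three bands: free probe [D], probe
# bound by one protein [PD], and probe bound by a dimer [P2D], quantified
# as proportions summing to 1. Tau is the fold by which binding of the
# first protein facilitates binding of the second (the coefficient
# relating the two dissociation constants Kd2 = Kd1 / tau); it is computed
# directly from the band proportions, the Kd's themselves are never
# estimated.

#' Build an EMSA lane table
#'
#' Validates a lane table (proportions of probe in the dimer, monomer and
#' free bands) or converts raw band intensities to proportions.
#'
#' @param x data.frame with columns `p2d`, `pd`, `d` (plus any annotation
#'   columns such as `probe_id`, `replicate`, `protein_conc`).
#' @param normalize if `TRUE`, the three band columns are taken as raw
#'   intensities and divided by their lane sum.
#' @return the validated data.frame, class `"emsa_lanes"` prepended.
#' @export
emsa_lanes <- function(x, normalize = FALSE) {
  need <- c("p2d", "pd", "d")
  if (!all(need %in% names(x)))
    stop("lane table needs columns p2d, pd, d", call. = FALSE)
  if (any(x$p2d < 0 | x$pd < 0 | x$d < 0))
    stop("band values must be non-negative", call. = FALSE)
  tot <- x$p2d + x$pd + x$d
  if (normalize) {
    if (any(tot <= 0)) stop("lane with zero total intensity", call. = FALSE)
    x[need] <- x[need] / tot
  } else if (any(abs(tot - 1) > 1e-6)) {
    stop("band proportions must sum to 1 per lane (use normalize = TRUE for raw intensities)",
         call. = FALSE)
  }
  class(x) <- unique(c("emsa_lanes", class(x)))
  x
}

#' Read an EMSA lane table from a delimited file
#'
#' @param path CSV/TSV with columns `p2d`, `pd`, `d` and optional
#'   annotations; the delimiter is sniffed from the header line.
#' @param normalize treat the band columns as raw intensities?
#' @return an [emsa_lanes()] table.
#' @export
read_emsa_lanes <- function(path, normalize = FALSE) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  emsa_lanes(utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE),
             normalize = normalize)
}

#' Tau cooperativity factor of one or more lanes
#'
#' `tau = 4 * p2d * d / pd^2`. Tau of 1 marks independent (non-cooperative)
#' binding of the two sites; values above 1 mark cooperative binding.
#' Lanes with no monomer band (`pd = 0`) have undefined tau and return
#' `NA`.
#'
#' @param p2d proportion of probe bound as a dimer, or an [emsa_lanes()]
#'   table (then `pd` and `d` are taken from it).
#' @param pd proportion bound as a monomer.
#' @param d proportion unbound.
#' @return numeric tau, vectorized over lanes.
#' @export
compute_tau <- function(p2d, pd = NULL, d = NULL) {
  if (is.data.frame(p2d)) {
    lanes <- p2d
    p2d <- lanes$p2d; pd <- lanes$pd; d <- lanes$d
  }
  ifelse(pd > 0, 4 * p2d * d / pd^2, NA_real_)
}

#' Summarize tau over replicate lanes
#'
#' Lanes whose monomer-band proportion falls below `pd_floor` are excluded
#' (tau diverges as the monomer band vanishes) and reported.
#'
#' @param lanes an [emsa_lanes()] table.
#' @param pd_floor minimum monomer-band proportion for a lane to enter the
#'   summary.
#' @return list with `mean_tau`, `sd_tau` (sample SD), `n`, `per_lane_tau`
#'   and `n_excluded`.
#' @export
summarize_tau <- function(lanes, pd_floor = 0.01) {
  tau <- compute_tau(lanes)
  valid <- !is.na(tau) & lanes$pd >= pd_floor
  if (!any(valid)) stop("no valid lanes (monomer band below floor everywhere)",
                        call. = FALSE)
  list(mean_tau = mean(tau[valid]),
       sd_tau = if (sum(valid) > 1) stats::sd(tau[valid]) else 0,
       n = sum(valid),
       per_lane_tau = tau[valid],
       n_excluded = sum(!valid))
}

#' Compare two groups of tau values
#'
#' Two-sided unpaired Student t-test (equal variance by default; Welch
#' available via `var_equal = FALSE`). Two zero-variance groups with equal
#' means compare as p = 1.
#'
#' @param group_a,group_b numeric tau vectors (each n >= 2).
#' @param var_equal equal-variance Student test (default) or Welch.
#' @return list with `p`, `t`, `df` and the group means.
#' @export
compare_tau <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 values", call. = FALSE)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    eq <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(list(p = if (eq) 1 else 0, t = if (eq) 0 else Inf,
                df = length(group_a) + length(group_b) - 2,
                mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(p = unname(tt$p.value), t = unname(tt$statistic),
       df = unname(tt$parameter), mean_a = mean(group_a),
       mean_b = mean(group_b))
}

#' Simulate EMSA lanes from a two-step equilibrium binding model
#'
#' Band proportions follow the sequential model with `Kd2 = Kd1 / omega`:
#' unnormalized weights `D = 1`, `PD = 2 [P] / Kd1`,
#' `P2D = omega ([P] / Kd1)^2`, normalized per lane. Without noise,
#' `compute_tau()` on the resulting lanes returns exactly `omega` at any
#' protein concentration. Gaussian noise of sd `noise_sd` is added to the
#' proportions, which are then clipped to \[0, 1\] and renormalized.
#'
#' @param kd1 dissociation constant of the first binding event (nM).
#' @param omega cooperativity factor (> 0; 1 = independent binding).
#' @param protein_concs protein concentrations (nM) to lay out lanes for.
#' @param n_replicates lanes per concentration.
#' @param noise_sd Gaussian noise sd on the proportions.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return an [emsa_lanes()] table with columns `probe_id`, `replicate`,
#'   `protein_conc`, `p2d`, `pd`, `d`.
#' @export
simulate_emsa_lanes <- function(kd1, omega, protein_concs,
                                n_replicates = 3, noise_sd = 0, seed = NULL) {
  if (kd1 <= 0 || omega <= 0) stop("kd1 and omega must be positive",
                                   call. = FALSE)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      protein_conc = protein_concs)
  q <- grid$protein_conc / kd1
  w <- cbind(p2d = omega * q^2, pd = 2 * q, d = 1)
  pr <- w / rowSums(w)
  if (noise_sd > 0) {
    pr <- with_seed(seed, {
      noisy <- pr + matrix(stats::rnorm(length(pr), sd = noise_sd),
                           nrow = nrow(pr))
      noisy[noisy < 0] <- 0
      noisy[noisy > 1] <- 1
      bad <- rowSums(noisy) <= 0
      noisy[bad, ] <- pr[bad, ]
      noisy / rowSums(noisy)
    })
  }
  emsa_lanes(data.frame(probe_id = sprintf("sim_kd%g_omega%g", kd1, omega),
                        replicate = grid$replicate,
                        protein_conc = grid$protein_conc,
                        p2d = pr[, "p2d"], pd = pr[, "pd"], d = pr[, "d"]))
}
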