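# Synthetic HT-SELEX: random fixed-length libraries undergoing
# binding-weighted selection with tunable monomer affinity, dimer
# cooperativity and a planted spacer preference, plus PCR-style
# amplification between rounds. Ground truth is known, so every pipeline
# stage is testable without downloads.

#' Parameters of a synthetic SELEX experiment
#'
#' Defaults reproduce the desk-scale study conditions used throughout:
#' a 50,000-read random 20-mer library, four selection cycles, a planted
#' head-to-tail TAAT-7bp-TAAT configuration, monomer binding weight 5 and
#' 20% retention per round. `omega` defaults to 1, i.e. independent
#' binding of the two sites; cooperative data are simulated by raising it.
#'
#' Each read's selection weight is `w = 1 + monomer_weight * m +
#' monomer_weight * omega * d`, where `d` counts occurrences of the
#' planted configuration and `m` counts 4-mer site matches outside those
#' configurations (site1 and site2 matches pooled; for a homodimer the
#' identical match sets are counted once). The planted configuration is
#' thus one binding event whose weight is `omega`-fold that of a single
#' site: at `omega = 1` it enriches at exactly a monomer site's rate, which
#' is the independence baseline the enrichment factor is calibrated
#' against.
#'
#' @param library_size reads per pool.
#' @param read_length bp (20-40 in the HT-SELEX designs emulated here).
#' @param n_cycles selection rounds.
#' @param site_consensus1,site_consensus2 the two 4-mer core sites.
#' @param planted_spacer bp between the sites in the favored configuration.
#' @param orientation `"FF"`, `"FR"` or `"RF"`.
#' @param monomer_weight relative binding weight of a single site match.
#' @param omega dimer cooperativity multiplier (>= 0; 1 = independent).
#' @param selection_stringency fraction of the pool retained per round.
#' @param amplification_noise resample the retained reads multinomially
#'   back to `library_size` (PCR analog)? If `FALSE`, retained reads are
#'   replicated deterministically.
#' @param seed RNG seed for the whole simulation.
#' @return a `"selex_sim_params"` list.
#' @export
selex_sim_params <- function(library_size = 50000, read_length = 20,
                             n_cycles = 4,
                             site_consensus1 = "TAAT",
                             site_consensus2 = "TAAT",
                             planted_spacer = 7, orientation = "FF",
                             monomer_weight = 5, omega = 1,
                             selection_stringency = 0.2,
                             amplification_noise = TRUE, seed = 1) {
  orientation <- match.arg(orientation, c("FF", "FR", "RF"))
  stopifnot(library_size >= 1, n_cycles >= 1, omega >= 0,
            selection_stringency > 0, selection_stringency <= 1,
            monomer_weight >= 0,
            read_length >= 8 + planted_spacer)
  structure(list(library_size = as.integer(library_size),
                 read_length = as.integer(read_length),
                 n_cycles = as.integer(n_cycles),
                 site_consensus1 = toupper(site_consensus1),
                 site_consensus2 = toupper(site_consensus2),
                 planted_spacer = as.integer(planted_spacer),
                 orientation = orientation,
                 monomer_weight = monomer_weight, omega = omega,
                 selection_stringency = selection_stringency,
                 amplification_noise = amplification_noise,
                 seed = seed),
            class = "selex_sim_params")
}

#' Generate a random initial SELEX library
#'
#' @param params a [selex_sim_params()].
#' @return character vector of `library_size` iid uniform-base reads of
#'   `read_length` bp, reproducible under the params seed.
#' @export
generate_initial_library <- function(params) {
  with_seed(params$seed, {
    m <- matrix(sample(BASES, params$library_size * params$read_length,
                       replace = TRUE),
                nrow = params$library_size)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  })
}

# selection weight of each read (see selex_sim_params docs)
read_weights <- function(pool, params) {
  dss <- as_dss(pool)
  s1 <- params$site_consensus1; s2 <- params$site_consensus2
  site_pats <- unique(c(s1, revcomp(s1), s2, revcomp(s2)))
  m <- rep(0L, length(dss))
  for (p in site_pats) m <- m + count_occurrences(p, dss)
  cfg <- config_patterns(s1, s2, params$planted_spacer, params$orientation)
  d <- rep(0L, length(dss))
  for (p in cfg) d <- d + count_occurrences(p, dss)
  m <- pmax(m - 2L * d, 0L)    # sites inside planted configurations masked
  1 + params$monomer_weight * m + params$monomer_weight * params$omega * d
}

#' Run one round of selection and amplification
#'
#' Retains `ceiling(selection_stringency * pool size)` reads, sampled
#' without replacement with probability proportional to their binding
#' weight (exponential-key weighted reservoir scheme), then amplifies the
#' retained reads back to `library_size` - multinomially when
#' `amplification_noise` is set, by deterministic replication otherwise.
#'
#' Randomness is drawn from the current RNG state so rounds chain inside
#' [simulate_selex()]; seed there, not here.
#'
#' @param pool character vector of reads.
#' @param params a [selex_sim_params()].
#' @return the next cycle's pool (length `library_size`).
#' @export
simulate_selection_round <- function(pool, params) {
  if (!length(pool)) stop("pool is empty", call. = FALSE)
  w <- read_weights(pool, params)
  if (all(w <= 0)) stop("all selection weights are zero; degenerate parameters",
                        call. = FALSE)
  k <- ceiling(params$selection_stringency * length(pool))
  # Efraimidis-Spirakis keys: top-k of w-weighted exponentials is a
  # weighted draw without replacement
  keep <- order(stats::rexp(length(pool)) / w)[seq_len(k)]
  retained <- pool[keep]
  if (params$amplification_noise) {
    retained[sample.int(k, params$library_size, replace = TRUE)]
  } else {
    rep_len(retained, params$library_size)
  }
}

#' Simulate a full HT-SELEX experiment
#'
#' Chains [generate_initial_library()] and `n_cycles` rounds of
#' [simulate_selection_round()], storing every cycle's pool.
#'
#' @param params a [selex_sim_params()].
#' @return a [selex_cycles()] object (cycles `0 .. n_cycles`) with the
#'   ground-truth parameters attached as attribute `"truth"`.
#' @export
simulate_selex <- function(params) {
  pools <- vector("list", params$n_cycles + 1)
  pools[[1]] <- generate_initial_library(params)
  with_seed(params$seed + 1L, {
    for (cc in seq_len(params$n_cycles)) {
      pools[[cc + 1]] <- simulate_selection_round(pools[[cc]], params)
    }
  })
  names(pools) <- as.character(0:params$n_cycles)
  out <- selex_cycles(pools,
                      source = sprintf("synthetic SELEX (omega=%g, spacer=%d, %s)",
                                       params$omega, params$planted_spacer,
                                       params$orientation))
  attr(out, "truth") <- params
  out
}
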