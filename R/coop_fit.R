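# The end-to-end cooperativity prediction: screen candidate long motifs,
# fit enrichment curves, profile spacer specificity, and combine the
# evidence into a cooperative / non-cooperative call per dimer model.

#' Combine screening, enrichment and spacing evidence into a cooperativity
#' call
#'
#' A TF is called cooperative on a dimer model when all gates hold: the
#' model passed the dimer screen, the enrichment factor exceeds `ef_min`
#' (default 2: the dimer site enriches more than twice as fast as its
#' monomer sites), and both spacer-specificity tests reject at `alpha`.
#' The decision is a pure conjunction; every contributing value is kept in
#' the call for audit.
#'
#' @param screen a `"dimer_screen"` result.
#' @param curve the [enrichment_curve()] fitted for the screened model.
#' @param profile the [call_spacer_specificity()] profile for the same
#'   model's core sites.
#' @param ef_min enrichment-factor gate.
#' @param alpha significance level for the spacer tests.
#' @param tf_name label carried into reports.
#' @return an object of class `"coop_call"`.
#' @export
classify_cooperativity <- function(screen, curve, profile, ef_min = 2,
                                   alpha = 0.05, tf_name = "TF") {
  stopifnot(inherits(screen, "dimer_screen"))
  dimer_detected <- !is.null(screen$candidate)
  if (!dimer_detected) {
    return(structure(list(tf_name = tf_name, dimer_detected = FALSE,
                          ef = NA_real_, ef_pass = FALSE,
                          grubbs_p = NA_real_, chi2_p = NA_real_,
                          spacer_called = NA_integer_, cooperative = FALSE,
                          reasons = screen$reasons),
                     class = "coop_call"))
  }
  stopifnot(inherits(curve, "enrichment_curve"),
            inherits(profile, "spacer_profile"))
  same_model <- identical(curve$dimer$consensus1, screen$candidate$consensus1) &&
    identical(curve$dimer$consensus2, screen$candidate$consensus2) &&
    identical(curve$dimer$spacer, screen$candidate$spacer)
  if (!same_model)
    stop("enrichment curve was fitted for a different dimer model than the screen",
         call. = FALSE)
  ef <- curve$ef
  ef_pass <- !is.na(ef) && ef > ef_min
  cooperative <- ef_pass && profile$grubbs_p < alpha && profile$chi2_p < alpha
  structure(list(tf_name = tf_name, dimer_detected = TRUE,
                 dimer = screen$candidate, ef = as.numeric(ef),
                 ef_pass = ef_pass,
                 grubbs_p = profile$grubbs_p, chi2_p = profile$chi2_p,
                 spacer_called = profile$called_spacer,
                 orientation = profile$orientation,
                 cooperative = cooperative,
                 reasons = character(0)),
            class = "coop_call")
}

#' @export
print.coop_call <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$tf_name,
              if (x$cooperative) "COOPERATIVE" else "not cooperative"))
  if (!x$dimer_detected) {
    cat("  no dimer site detected:", paste(x$reasons, collapse = "; "), "\n")
  } else {
    cat(sprintf("  dimer %s-%dN-%s | EF %.2f (>2: %s) | Grubbs p %.3g | chi2 p %.3g | spacer %s\n",
                x$dimer$consensus1, x$dimer$spacer, x$dimer$consensus2,
                x$ef, if (x$ef_pass) "yes" else "no", x$grubbs_p, x$chi2_p,
                ifelse(is.na(x$spacer_called), "none",
                       paste0(x$spacer_called, " bp"))))
  }
  invisible(x)
}

#' Predict cooperative homodimer binding from an HT-SELEX cycle set
#'
#' The full pipeline: candidate long motifs (supplied Homer/JASPAR-style
#' PWMs or discovered de novo from the final cycle) are screened for dimer
#' sites; for each screened model the dimer and masked-monomer enrichment
#' slopes are fitted across cycles and the spacer-length profile of the
#' two core 4-mers is tested for specificity; the evidence is combined
#' into one call per model. A TF is cooperative when any of its models is.
#'
#' @param cycles a [selex_cycles()] set; cycle 0 and at least one later
#'   cycle are required.
#' @param motifs list of [pwm()] long motifs (e.g. from
#'   [read_homer_motif()]); `NULL` runs [discover_long_motifs()].
#' @param tf_name label for reports.
#' @param subsample pools larger than this are subsampled to it (per cycle,
#'   independently, under `seed`); `Inf` disables.
#' @param seed seed for subsampling and any other randomness.
#' @param ic_min,flank_ratio_min,abundance_min dimer-screen thresholds
#'   (see [screen_dimer()]).
#' @param ef_min,alpha decision gates (see [classify_cooperativity()]).
#' @param spacer_range,orientations spacer profiling grid (see
#'   [count_spacers()]).
#' @param mismatches mismatch budget for all consensus-configuration
#'   counting.
#' @param lengths,top_k discovery parameters (see
#'   [discover_long_motifs()]).
#' @param surround surround definition for screen criterion 2.
#' @return an object of class `"coop_fit"` with `print()`, `summary()`,
#'   `coef()` and `plot()` methods.
#' @examples
#' params <- selex_sim_params(library_size = 2000, omega = 50, seed = 7)
#' cyc <- simulate_selex(params)
#' fit <- coop_predict(cyc, motifs = NULL, tf_name = "simTF", seed = 7)
#' fit
#' @export
coop_predict <- function(cycles, motifs = NULL, tf_name = "TF",
                         subsample = 50000, seed = 1,
                         ic_min = 0.6, flank_ratio_min = 1.5,
                         abundance_min = 0.05, ef_min = 2, alpha = 0.05,
                         spacer_range = 0:20,
                         orientations = c("FF", "FR", "RF"),
                         mismatches = 0, lengths = c(16, 18), top_k = 3,
                         surround = "pooled") {
  stopifnot(inherits(cycles, "selex_cycles"))
  idx <- as.integer(names(cycles$cycles))
  if (!0 %in% idx) stop("initial library required (cycle 0)", call. = FALSE)
  if (length(idx) < 2) stop("need cycle 0 and at least one later cycle",
                            call. = FALSE)
  if (is.finite(subsample)) {
    sub <- lapply(seq_along(cycles$cycles), function(i)
      subsample_reads(cycles$cycles[[i]], subsample, seed = seed + idx[i]))
    names(sub) <- names(cycles$cycles)
    cycles <- selex_cycles(sub, source = cycles$source, subsample_seed = seed)
  }
  last <- as.character(max(idx))
  pool4 <- cycles$cycles[[last]]
  pool0 <- cycles$cycles[["0"]]
  discovered <- is.null(motifs)
  if (discovered) {
    motifs <- with_seed(seed, discover_long_motifs(pool4, pool0,
                                                   lengths = lengths,
                                                   top_k = top_k))
  }
  if (inherits(motifs, "pwm")) motifs <- list(motifs)

  config <- list(tf_name = tf_name, subsample = subsample, seed = seed,
                 ic_min = ic_min, flank_ratio_min = flank_ratio_min,
                 abundance_min = abundance_min, ef_min = ef_min,
                 alpha = alpha, spacer_range = spacer_range,
                 orientations = orientations, mismatches = mismatches,
                 motif_source = if (discovered) "internal discovery"
                 else "supplied motifs",
                 version = as.character(utils::packageVersion("coopselex")))

  models <- lapply(motifs, function(mx) {
    screen <- screen_dimer(mx, pool4, ic_min = ic_min,
                           flank_ratio_min = flank_ratio_min,
                           abundance_min = abundance_min, surround = surround)
    if (is.null(screen$candidate)) {
      return(list(motif = mx, screen = screen,
                  call = classify_cooperativity(screen, NULL, NULL,
                                                ef_min = ef_min,
                                                alpha = alpha,
                                                tf_name = tf_name)))
    }
    dm <- screen$candidate
    curve <- enrichment_curve(dm, cycles, mismatches = mismatches)
    c0 <- count_spacers(dm$consensus1, dm$consensus2, pool0,
                        spacer_range = spacer_range,
                        orientations = orientations, mismatches = mismatches)
    c4 <- count_spacers(dm$consensus1, dm$consensus2, pool4,
                        spacer_range = spacer_range,
                        orientations = orientations, mismatches = mismatches)
    profile <- call_spacer_specificity(c0, c4, alpha = alpha)
    list(motif = mx, screen = screen, curve = curve, profile = profile,
         call = classify_cooperativity(screen, curve, profile,
                                       ef_min = ef_min, alpha = alpha,
                                       tf_name = tf_name))
  })
  structure(list(tf_name = tf_name, models = models, config = config,
                 cycles_summary = data.frame(
                   cycle = idx,
                   n_reads = vapply(cycles$cycles, length, integer(1))),
                 cooperative = any(vapply(models, function(m)
                   isTRUE(m$call$cooperative), logical(1)))),
            class = "coop_fit")
}

#' @export
print.coop_fit <- function(x, ...) {
  cat(sprintf("Cooperativity prediction for %s: %s\n", x$tf_name,
              if (x$cooperative) "COOPERATIVE"
              else if (!length(x$models)) "no dimer detected"
              else "not cooperative"))
  cat(sprintf("  %d candidate long motif(s), cycles %s\n", length(x$models),
              paste(x$cycles_summary$cycle, collapse = ",")))
  for (m in x$models) print(m$call)
  invisible(x)
}

#' @export
summary.coop_fit <- function(object, ...) {
  df <- do.call(rbind, lapply(object$models, function(m) {
    cl <- m$call
    data.frame(tf = cl$tf_name,
               motif = m$motif$name,
               dimer_detected = cl$dimer_detected,
               site1 = if (cl$dimer_detected) cl$dimer$consensus1 else NA,
               site2 = if (cl$dimer_detected) cl$dimer$consensus2 else NA,
               spacer = if (cl$dimer_detected) cl$dimer$spacer else NA,
               orientation = if (cl$dimer_detected) cl$dimer$orientation else NA,
               abundance = if (cl$dimer_detected) cl$dimer$abundance_cycle4 else NA,
               ef = cl$ef, grubbs_p = cl$grubbs_p, chi2_p = cl$chi2_p,
               called_spacer = cl$spacer_called,
               cooperative = cl$cooperative,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame()
  structure(list(table = df, tf_name = object$tf_name,
                 cooperative = object$cooperative), class = "summary.coop_fit")
}

#' @export
print.summary.coop_fit <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$tf_name,
              if (x$cooperative) "COOPERATIVE" else "not cooperative"))
  if (nrow(x$table)) print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
#' @describeIn coop_predict slopes and enrichment factor of the first
#'   screened model (named vector), `NULL` when no dimer was detected.
coef.coop_fit <- function(object, ...) {
  for (m in object$models) {
    if (!is.null(m$curve)) {
      return(c(slope_dimer = m$curve$slopes$dimer$slope,
               slope_site1 = m$curve$slopes$site1$slope,
               slope_site2 = m$curve$slopes$site2$slope,
               ef = as.numeric(m$curve$ef)))
    }
  }
  NULL
}

#' @export
plot.coop_fit <- function(x, which_model = 1, ...) {
  m <- x$models[[which_model]]
  if (is.null(m$curve)) {
    warning("model has no enrichment curve (dimer screen failed)")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  tab <- m$curve$table
  ylim <- range(tab$ln_fc_dimer, tab$ln_fc_site1, tab$ln_fc_site2)
  graphics::plot(tab$cycle, tab$ln_fc_dimer, type = "b", pch = 19,
                 xlab = "SELEX cycle", ylab = "ln fold change", ylim = ylim,
                 main = sprintf("%s enrichment (EF %.2f)", x$tf_name,
                                m$curve$ef))
  graphics::lines(tab$cycle, tab$ln_fc_site1, type = "b", pch = 1, lty = 2)
  graphics::lines(tab$cycle, tab$ln_fc_site2, type = "b", pch = 2, lty = 3)
  graphics::abline(m$curve$slopes$dimer$intercept,
                   m$curve$slopes$dimer$slope, col = "grey")
  graphics::legend("topleft", legend = c("dimer", "site1", "site2"),
                   pch = c(19, 1, 2), lty = 1:3, bty = "n")
  if (!is.null(m$profile)) {
    cnt <- m$profile$counts4[, m$profile$orientation]
    spacers <- as.integer(rownames(m$profile$counts4))
    called <- m$profile$called_spacer
    cols <- if (is.na(called)) rep("grey", length(spacers)) else
      ifelse(spacers == called, "firebrick", "grey")
    graphics::barplot(cnt, names.arg = spacers, col = cols,
                      xlab = "spacer (bp)", ylab = "cycle-4 reads",
                      main = sprintf("spacer profile (%s)",
                                     m$profile$orientation))
  }
  invisible(x)
}

#' Write a cooperativity report to disk
#'
#' Emits `report.json` (full audit: config, per-model screen values,
#' per-cycle fractions, slopes, test p-values, call) and `report.tsv` (one
#' row per dimer model, the summary table). Output is byte-identical for
#' identical input and seed.
#'
#' @param fit a [coop_predict()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_coop_report <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(fit)$table
  utils::write.table(s, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  payload <- list(
    tf_name = fit$tf_name,
    cooperative = fit$cooperative,
    config = fit$config,
    cycles = fit$cycles_summary,
    models = lapply(fit$models, function(m) {
      list(motif = m$motif$name,
           screen = list(ic_pass = m$screen$ic_pass,
                         flank_ratio_pass = m$screen$flank_ratio_pass,
                         abundance_pass = m$screen$abundance_pass,
                         core_ic = m$screen$core_ic,
                         surround_ic = m$screen$surround_ic,
                         abundance = m$screen$abundance),
           curve = if (!is.null(m$curve)) list(
             table = m$curve$table,
             slopes = lapply(m$curve$slopes, function(s)
               s[c("slope", "r_squared")]),
             ef = as.numeric(m$curve$ef)),
           spacing = if (!is.null(m$profile)) list(
             per_orientation = m$profile$per_orientation,
             grubbs_p = m$profile$grubbs_p, chi2_p = m$profile$chi2_p,
             called_spacer = m$profile$called_spacer),
           call = unclass(m$call)[c("dimer_detected", "ef", "ef_pass",
                                    "grubbs_p", "chi2_p", "spacer_called",
                                    "cooperative")])
    }))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(dir)
}
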