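# Lightweight de novo discovery of long (16-18 bp) gapped dimer motifs.
#
# This is a seeded, greedy stand-in for a full de novo motif search: gapped
# 4mer-pair seeds (4mer, spacer, 4mer) are ranked by their cycle-4 versus
# cycle-0 read-frequency ratio, and a PWM is built for each top seed from
# the cycle-4 reads aligned on the seed span. Externally produced Homer
# motifs can be supplied to the pipeline instead for faithful reruns.

# Tabulate gapped 4mer-pair seeds: how many reads contain each
# (4mer, spacer, 4mer) at least once, plus the per-position 4-mer
# frequencies needed to judge whether a pair co-occurs more often than its
# parts predict. Seeds are integer-encoded (spacer * 4^8 + code1 * 4^4 +
# code2) for speed; reads with N at a seed position contribute no seed
# there.
seed_read_counts <- function(reads, spacer_min = 2, spacer_max = 12) {
  codes <- encode_reads(as.character(as_dss(reads)))
  n <- nrow(codes); L <- ncol(codes)
  code4 <- function(i) {   # 4-mer codes starting at column i, 0..255
    codes[, i] * 64L + codes[, i + 1] * 16L + codes[, i + 2] * 4L + codes[, i + 3]
  }
  k4 <- lapply(1:(L - 3), code4)
  pos_freq <- vapply(k4, function(v) tabulate(v + 1L, nbins = 256) / n,
                     numeric(256))
  keys <- list(); m <- 0
  for (s in spacer_min:spacer_max) {
    span <- 8 + s
    if (span > L) next
    for (i in 1:(L - span + 1)) {
      a <- k4[[i]]; b <- k4[[i + 4 + s]]
      ok <- which(!is.na(a) & !is.na(b))
      if (!length(ok)) next
      sid <- (s * 65536 + a[ok] * 256 + b[ok])
      m <- m + 1
      # key = seed id * n + read index - 1 so duplicates within a read collapse
      keys[[m]] <- sid * n + (ok - 1)
    }
  }
  if (!m) return(list(seeds = data.frame(), pos_freq = pos_freq, n = n))
  u <- unique(unlist(keys, use.names = FALSE))
  sid <- u %/% n
  counts <- table(sid)
  ids <- as.numeric(names(counts))
  seeds <- data.frame(spacer = ids %/% 65536,
                      code1 = (ids %% 65536) %/% 256,
                      code2 = ids %% 256,
                      reads = as.integer(counts))
  # reads expected for each seed if its two 4-mers occurred independently
  # at their per-position cycle frequencies
  seeds$expected <- vapply(seq_len(nrow(seeds)), function(r) {
    s <- seeds$spacer[r]
    i <- seq_len(L - 8 - s + 1)
    sum(pos_freq[seeds$code1[r] + 1, i] *
          pos_freq[seeds$code2[r] + 1, i + 4 + s]) * n
  }, numeric(1))
  list(seeds = seeds, pos_freq = pos_freq, n = n)
}

decode4 <- function(code) {
  d <- c(code %/% 64, (code %% 64) %/% 16, (code %% 16) %/% 4, code %% 4)
  paste(BASES[d + 1], collapse = "")
}

# Build a length-L PWM from reads aligned on the first occurrence of the
# seed (forward strand; reverse-strand occurrences are included after
# reverse complementing the read), centered on the seed span.
seed_pwm <- function(reads, seed1, seed2, spacer, motif_length) {
  span <- 8 + spacer
  pat <- paste0(seed1, strrep("N", spacer), seed2)
  rcp <- revcomp(pat)
  dss <- as_dss(reads)
  pos_f <- Biostrings::vmatchPattern(Biostrings::DNAString(pat), dss, fixed = .fixed)
  first_f <- sapply(Biostrings::startIndex(pos_f), function(v) if (length(v)) v[1] else NA_integer_)
  use <- character(0); at <- integer(0)
  hit_f <- !is.na(first_f)
  use <- as.character(dss[hit_f]); at <- first_f[hit_f]
  if (rcp != pat) {
    pos_r <- Biostrings::vmatchPattern(Biostrings::DNAString(rcp), dss, fixed = .fixed)
    first_r <- sapply(Biostrings::startIndex(pos_r), function(v) if (length(v)) v[1] else NA_integer_)
    hit_r <- !is.na(first_r) & !hit_f
    if (any(hit_r)) {
      rcseq <- revcomp(as.character(dss[hit_r]))
      L <- nchar(rcseq[1])
      use <- c(use, rcseq)
      at <- c(at, L - (first_r[hit_r] + span - 1) + 1)
    }
  }
  if (!length(use)) return(NULL)
  lead <- (motif_length - span) %/% 2
  starts <- at - lead
  counts <- matrix(0.25, nrow = motif_length, ncol = 4,
                   dimnames = list(NULL, BASES))   # quarter pseudocounts
  codes <- encode_reads(use)
  L <- ncol(codes)
  for (j in seq_len(motif_length)) {
    col <- starts + j - 1
    ok <- col >= 1 & col <= L
    if (!any(ok)) next
    v <- codes[cbind(which(ok), col[ok])]
    v <- v[!is.na(v)]
    if (length(v)) counts[j, ] <- counts[j, ] + tabulate(v + 1L, nbins = 4)
  }
  # no scalar match threshold: downstream screening counts reads by core
  # configuration, the exact semantics for a seed-anchored motif
  pwm(counts, name = sprintf("%s_%dN_%s_L%d", seed1, spacer, seed2,
                             motif_length))
}

#' Discover enriched long dimer motifs de novo
#'
#' Enumerates gapped 4mer-pair seeds (4-mer, spacer of `spacer_min` to
#' `spacer_max` bp, 4-mer) in the final-cycle pool, ranks them by the ratio
#' of cycle-4 to cycle-0 read frequency, and builds one PWM per top seed by
#' aligning the cycle-4 reads that contain it. Seeds below `support_min`
#' cycle-4 frequency are ignored; an empty result (with a warning) means no
#' enriched gapped seed exists, e.g. when the pool only enriched a monomer
#' site or did not undergo selection.
#'
#' @param cycle4_reads final-cycle reads (uniform length).
#' @param cycle0_reads initial-library reads.
#' @param lengths candidate motif lengths; one PWM per (seed, length) is
#'   scored and the better-covered length kept.
#' @param top_k number of seed motifs to return (seeds sharing 8 of their
#'   9+ defining bases with a better seed are collapsed).
#' @param spacer_min,spacer_max seed spacer range in bp.
#' @param support_min minimum cycle-4 read frequency of a seed.
#' @param enrichment_min minimum cycle-4 / cycle-0 frequency ratio.
#' @param lift_min minimum pairing lift: observed cycle-4 seed reads over
#'   the count expected if the two 4-mers occurred independently at their
#'   per-position cycle-4 frequencies. A pool that only enriched a monomer
#'   site produces gapped pairs at exactly their independent co-occurrence
#'   rate (lift about 1), so this is what separates true dimer
#'   configurations from monomer shadows.
#' @return list of [pwm()] objects ordered by decreasing seed enrichment
#'   (possibly empty).
#' @export
discover_long_motifs <- function(cycle4_reads, cycle0_reads,
                                 lengths = c(16, 18), top_k = 3,
                                 spacer_min = 2, spacer_max = 12,
                                 support_min = 0.001, enrichment_min = 5,
                                 lift_min = 2) {
  if (!length(cycle4_reads) || !length(cycle0_reads))
    stop("both read pools must be nonempty", call. = FALSE)
  n4 <- length(cycle4_reads); n0 <- length(cycle0_reads)
  sc4 <- seed_read_counts(cycle4_reads, spacer_min, spacer_max)
  t4 <- sc4$seeds
  if (!nrow(t4)) {
    warning("no gapped seed found in cycle-4 reads")
    return(list())
  }
  t4 <- t4[t4$reads >= support_min * n4, , drop = FALSE]
  if (!nrow(t4)) {
    warning(sprintf("no gapped seed present in >= %.2g%% of cycle-4 reads",
                    100 * support_min))
    return(list())
  }
  t4$lift <- t4$reads / (t4$expected + 0.5)
  # Bonferroni-corrected Poisson tail over the whole seed enumeration:
  # a pairing must be significantly more frequent than its marginals
  # predict, not just nominally lifted
  n_tests <- 65536 * length(spacer_min:spacer_max)
  t4$pair_p <- stats::ppois(t4$reads - 1, t4$expected + 0.5,
                            lower.tail = FALSE)
  t0 <- seed_read_counts(cycle0_reads, spacer_min, spacer_max)$seeds
  key <- function(d) d$spacer * 65536 + d$code1 * 256 + d$code2
  f0 <- t0$reads[match(key(t4), key(t0))] / n0
  f0[is.na(f0)] <- 0
  t4$f4 <- t4$reads / n4
  # half-read pseudocount on the cycle-0 frequency keeps unseen seeds finite
  t4$enrichment <- t4$f4 / (f0 + 0.5 / n0)
  # significance of the cycle-4 count given the cycle-0 frequency (Poisson
  # log tail): the ranking criterion, robust against seeds whose cycle-0
  # count happens to be 0, which would dominate a plain frequency ratio
  t4$enrich_logp <- stats::ppois(t4$reads - 1, (f0 + 0.5 / n0) * n4,
                                 lower.tail = FALSE, log.p = TRUE)
  t4 <- t4[t4$enrichment >= enrichment_min & t4$lift >= lift_min &
             t4$pair_p < 0.05 / n_tests, , drop = FALSE]
  if (!nrow(t4)) {
    warning("no gapped seed enriched over the initial library")
    return(list())
  }
  t4 <- t4[order(t4$enrich_logp, -t4$f4), , drop = FALSE]

  out <- list(); taken <- character(0)
  for (r in seq_len(nrow(t4))) {
    if (length(out) >= top_k) break
    s1 <- decode4(t4$code1[r]); s2 <- decode4(t4$code2[r]); sp <- t4$spacer[r]
    sig <- paste0(s1, sp, s2)
    # a configuration equals its full reverse complement
    rcsig <- paste0(revcomp(s2), sp, revcomp(s1))
    # collapse seeds that are 1-bp shifts / 1-mismatch variants of a kept one
    if (any(vapply(taken, function(t)
      seed_similar(sig, t) || seed_similar(rcsig, t), logical(1)))) next
    fit <- NULL
    for (Lm in sort(lengths)) {
      if (8 + sp > Lm || Lm > nchar(as.character(cycle4_reads[1]))) next
      fit <- seed_pwm(cycle4_reads, s1, s2, sp, Lm)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    attr(fit, "seed") <- list(site1 = s1, site2 = s2, spacer = sp,
                              enrichment = t4$enrichment[r], f4 = t4$f4[r])
    out[[length(out) + 1]] <- fit
    taken <- c(taken, sig)
  }
  out
}

# Crude redundancy filter: seeds are the same binding arrangement when the
# spacer differs by <= 2 (a 1-bp shift of each 4-mer changes it by 2) and
# each 4-mer is a 1-mismatch or 1-bp-shift variant of its counterpart.
seed_similar <- function(a, b) {
  pa <- regmatches(a, regexec("^([ACGT]{4})([0-9]+)([ACGT]{4})$", a))[[1]]
  pb <- regmatches(b, regexec("^([ACGT]{4})([0-9]+)([ACGT]{4})$", b))[[1]]
  if (abs(as.integer(pa[3]) - as.integer(pb[3])) > 2) return(FALSE)
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  shift <- function(x, y) substr(x, 2, 4) == substr(y, 1, 3) ||
    substr(y, 2, 4) == substr(x, 1, 3)
  (ham(pa[2], pb[2]) <= 1 || shift(pa[2], pb[2])) &&
    (ham(pa[4], pb[4]) <= 1 || shift(pa[4], pb[4]))
}
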