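# Independent oracles used by the tests. These deliberately avoid the
# package's code paths: plain string/loop implementations.

oracle_revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

ALL_4MERS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, stringsAsFactors = FALSE)
  apply(g[, 4:1], 1, paste, collapse = "")
})

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all sequences within m mismatches of an IUPAC consensus (degenerate codes
# expanded before measuring distance)
oracle_hamming_ball <- function(consensus, m) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  sets <- iupac[strsplit(consensus, "")[[1]]]
  exact <- apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste,
                 collapse = "")
  ALL_4MERS[vapply(ALL_4MERS, function(s)
    min(vapply(exact, hamming, numeric(1), a = s)) <= m, logical(1))]
}

# does `read` contain site1 + gap + site2 (exact strings) at spacer s,
# on the forward strand? plain substring walk.
oracle_has_config_fwd <- function(read, site1, site2, s) {
  L <- nchar(read)
  span <- 8 + s
  if (span > L) return(FALSE)
  for (i in 1:(L - span + 1)) {
    if (substr(read, i, i + 3) == site1 &&
        substr(read, i + 4 + s, i + 7 + s) == site2) return(TRUE)
  }
  FALSE
}

# either-strand configuration presence: the configuration or its full
# reverse complement on the forward strand
oracle_has_config <- function(read, site1, site2, s) {
  oracle_has_config_fwd(read, site1, site2, s) ||
    oracle_has_config_fwd(read, oracle_revcomp(site2), oracle_revcomp(site1), s)
}

oracle_has_site <- function(read, site) {
  grepl(site, read, fixed = TRUE) ||
    grepl(oracle_revcomp(site), read, fixed = TRUE)
}

# Grubbs one-sided max-outlier p, coded independently via the critical-value
# inversion: p = n * P(T_{n-2} > t(G))
oracle_grubbs_p <- function(x) {
  n <- length(x)
  G <- (max(x) - mean(x)) / sd(x)
  num <- n * (n - 2) * G^2
  den <- (n - 1)^2 - n * G^2
  if (den <= 0) return(0)
  min(1, n * (1 - pt(sqrt(num / den), df = n - 2)))
}

# textbook chi-square of a 2 x K table, no correction
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(stat = stat, p = 1 - pchisq(stat, df))
}

random_reads <- function(n, L) {
  do.call(paste0, as.data.frame(matrix(sample(c("A", "C", "G", "T"), n * L,
                                              replace = TRUE), n),
                                stringsAsFactors = FALSE))
}

# point-mass long motif: fixed consensus bases at given 0-based offsets,
# uniform elsewhere
planted_pwm <- function(length, sites, eps = 0) {
  mat <- matrix(0.25, nrow = length, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (nm in names(sites)) {
    off <- as.integer(nm)
    letters <- strsplit(sites[[nm]], "")[[1]]
    for (j in seq_along(letters)) {
      p <- rep(eps, 4)
      p[match(letters[j], c("A", "C", "G", "T"))] <- 1 - 3 * eps
      mat[off + j, ] <- p
    }
  }
  coopselex::pwm(mat, name = "planted")
}
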