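# Position weight matrices: construction, information content, scanning.

#' Construct a position weight matrix
#'
#' A PWM is stored as an L x 4 matrix of base probabilities in A,C,G,T column
#' order. Rows are renormalized to sum to 1; rows summing outside
#' \[0.9, 1.1\] before normalization are rejected as corrupt.
#'
#' @param mat numeric matrix with 4 columns (A,C,G,T) and one row per motif
#'   position, holding base probabilities (or counts, which are normalized).
#' @param name motif name.
#' @param threshold optional log-odds match-score threshold (natural log,
#'   uniform background). Scanning reports hits scoring at or above it.
#' @return an object of class `"pwm"`.
#' @seealso [consensus_to_pwm()], [scan_sequence()], [pwm_ic()]
#' @export
pwm <- function(mat, name = "motif", threshold = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("a PWM needs 4 columns (A,C,G,T)", call. = FALSE)
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("PWM probabilities must be finite and non-negative", call. = FALSE)
  rs <- rowSums(mat)
  if (any(rs < 0.9) || any(rs > 1.1)) {
    # counts rather than probabilities? normalize if every row is clearly counts
    if (all(rs > 0)) mat <- mat / rs else
      stop("PWM row sums outside [0.9, 1.1]", call. = FALSE)
  } else {
    mat <- mat / rs
  }
  dimnames(mat) <- list(NULL, BASES)
  structure(list(mat = mat, name = name, threshold = threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions, consensus %s\n",
              x$name, nrow(x$mat), pwm_consensus(x)))
  cat(sprintf("  per-column IC (bits): %s\n",
              paste(sprintf("%.2f", pwm_ic(x)), collapse = " ")))
  if (!is.null(x$threshold))
    cat(sprintf("  match-score threshold (nat log-odds): %.3f\n", x$threshold))
  invisible(x)
}

#' @export
length.pwm <- function(x) nrow(x$mat)

#' Consensus sequence of a PWM (argmax base per column, ties to the
#' alphabetically first base)
#' @param x a [pwm()].
#' @return character string.
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$mat, 1, which.max)], collapse = "")
}

#' Information content of a single PWM column
#'
#' IC = 2 + sum(p * log2 p) bits, with 0 * log(0) taken as 0: 0 bits for a
#' uniform column, 2 bits for a fixed base.
#'
#' @param p probability 4-vector (A,C,G,T), summing to 1 within 1e-6.
#' @return bits, in \[0, 2\].
#' @export
column_ic <- function(p) {
  if (length(p) != 4) stop("p must have length 4", call. = FALSE)
  if (any(p < 0)) stop("negative probability", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1", call. = FALSE)
  terms <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + sum(terms)
  min(max(ic, 0), 2)
}

#' Per-column information content of a PWM
#' @param x a [pwm()].
#' @return numeric vector of bits, one per motif position.
#' @export
pwm_ic <- function(x) {
  apply(x$mat, 1, column_ic)
}

#' Mean information content over a window of PWM columns
#'
#' @param x a [pwm()].
#' @param start 0-based start position of the window.
#' @param width window width in positions (> 0).
#' @return mean per-column IC in bits.
#' @export
mean_window_ic <- function(x, start, width) {
  if (width < 1) stop("empty window", call. = FALSE)
  if (start < 0 || start + width > nrow(x$mat))
    stop("window outside motif", call. = FALSE)
  mean(pwm_ic(x)[(start + 1):(start + width)])
}

#' Reverse complement a PWM
#' @param x a [pwm()].
#' @return a [pwm()] representing the motif on the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  m <- x$mat[rev(seq_len(nrow(x$mat))), c("T", "G", "C", "A"), drop = FALSE]
  pwm(m, name = paste0(x$name, "_rc"), threshold = x$threshold)
}

#' Build a PWM from an IUPAC consensus with a mismatch allowance
#'
#' Mirrors the semantics of Homer's seq2profile tool: the returned PWM's
#' match set (sequences scoring at or above its threshold) is exactly the
#' set of sequences within `mismatches` Hamming distance of the consensus,
#' with degenerate IUPAC codes expanded. Consensus bases get probability
#' close to 1 (`1 - 3 * eps` for a non-degenerate position) and off-consensus
#' bases get `eps`; the threshold is placed midway between the worst allowed
#' and the best disallowed sequence score, which is well-conditioned for
#' `eps = 0.001` and any mismatch count a 4-mer admits.
#'
#' @param consensus IUPAC string.
#' @param mismatches allowed Hamming mismatches (>= 0). Fully degenerate (N)
#'   positions can never mismatch.
#' @param eps probability assigned to disallowed bases.
#' @param name motif name; defaults to the consensus.
#' @return a [pwm()] with its `threshold` set.
#' @export
consensus_to_pwm <- function(consensus, mismatches = 0, eps = 0.001,
                             name = consensus) {
  if (!is_count(mismatches) || mismatches < 0)
    stop("mismatches must be a non-negative integer", call. = FALSE)
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  bad <- !letters %in% names(IUPAC)
  if (any(bad))
    stop(sprintf("invalid IUPAC letter '%s' in consensus", letters[bad][1]),
         call. = FALSE)
  L <- length(letters)
  mat <- matrix(eps, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
  for (j in seq_len(L)) {
    allowed <- IUPAC[[letters[j]]]
    k <- length(allowed)
    mat[j, allowed] <- (1 - (4 - k) * eps) / k
  }
  x <- pwm(mat, name = name)
  ll <- log(x$mat / 0.25)
  amax <- apply(ll, 1, max)
  # per-position cost of a mismatch; N columns admit none
  gap <- amax - log(eps / 0.25)
  gap <- gap[sapply(letters, function(l) length(IUPAC[[l]]) < 4)]
  total <- sum(amax)
  m <- min(mismatches, length(gap))
  if (m == length(gap)) {
    x$threshold <- -Inf            # every sequence is a match
  } else {
    worst_allowed <- total - sum(sort(gap, decreasing = TRUE)[seq_len(m)])
    best_disallowed <- total - sum(sort(gap)[seq_len(m + 1)])
    x$threshold <- (worst_allowed + best_disallowed) / 2
  }
  x
}

# natural-log odds matrix against uniform background; column j of the result
# is the score of base j (A,C,G,T); N scores -Inf (never matches).
logodds <- function(x) log(x$mat / 0.25)

# Score every offset of every (uniform-length, encoded) read against a PWM.
# Returns an n x n_offsets matrix of scores; NA bases (N) give -Inf.
score_matrix <- function(codes, x) {
  ll <- logodds(x)
  W <- nrow(ll)
  L <- ncol(codes)
  n_off <- L - W + 1
  if (n_off < 1) return(matrix(numeric(0), nrow = nrow(codes), ncol = 0))
  out <- matrix(0, nrow = nrow(codes), ncol = n_off)
  for (o in seq_len(n_off)) {
    s <- numeric(nrow(codes))
    for (j in seq_len(W)) {
      v <- ll[j, ][codes[, o + j - 1] + 1L]
      v[is.na(v)] <- -Inf
      s <- s + v
    }
    out[, o] <- s
  }
  out
}

#' Scan a DNA sequence with a PWM
#'
#' Reports every offset whose natural-log odds score (uniform background)
#' reaches the PWM's threshold. Reverse-strand hits are reported at the
#' forward-strand coordinate of the match's leftmost base. Positions
#' containing N never match. Overlapping hits are all reported.
#'
#' @param x a [pwm()] with a `threshold`.
#' @param seq DNA string (A,C,G,T,N).
#' @param both_strands scan the reverse complement as well?
#' @return data.frame with columns `pos` (0-based leftmost base of the
#'   match on the forward strand), `strand` (`"+"`/`"-"`) and `score`.
#'   A sequence shorter than the motif yields zero rows.
#' @export
scan_sequence <- function(x, seq, both_strands = TRUE) {
  if (is.null(x$threshold))
    stop("PWM has no match-score threshold; set one or use consensus_to_pwm()",
         call. = FALSE)
  seq <- toupper(seq)
  check_alphabet(seq)
  empty <- data.frame(pos = integer(0), strand = character(0),
                      score = numeric(0))
  W <- nrow(x$mat)
  L <- nchar(seq)
  if (L < W) return(empty)
  codes <- encode_reads(seq)
  hits_one <- function(p, strand) {
    sc <- drop(score_matrix(codes, p))
    keep <- which(sc >= p$threshold)
    if (!length(keep)) return(empty)
    data.frame(pos = keep - 1L, strand = strand, score = sc[keep])
  }
  out <- hits_one(x, "+")
  if (both_strands) {
    rc <- hits_one(pwm_revcomp(x), "-")
    out <- rbind(out, rc)
  }
  out[order(out$pos, out$strand), , drop = FALSE]
}

# Fraction / count of reads (uniform length) with >= 1 PWM match on either
# strand at the PWM's threshold. Used for the 5% abundance criterion.
count_pwm_hits <- function(x, reads, both_strands = TRUE) {
  reads <- as.character(as_dss(reads))
  codes <- encode_reads(reads)
  hit <- rowSums(score_matrix(codes, x) >= x$threshold) > 0
  if (both_strands) {
    rc <- pwm_revcomp(x)
    hit <- hit | rowSums(score_matrix(codes, rc) >= rc$threshold) > 0
  }
  list(count = sum(hit), fraction = mean(hit))
}
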