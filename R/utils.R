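# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> allowed base sets
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Pattern matching policy used everywhere: IUPAC codes in the pattern are
# degenerate (N spans a spacer), letters in the subject are literal, so an N
# in a read never satisfies an A/C/G/T motif position.
.fixed <- c(pattern = FALSE, subject = TRUE)

as_dss <- function(reads) {
  if (methods::is(reads, "DNAStringSet")) reads else Biostrings::DNAStringSet(reads)
}

count_occurrences <- function(pattern, subject, max.mismatch = 0) {
  Biostrings::vcountPattern(Biostrings::DNAString(pattern), as_dss(subject),
                            max.mismatch = max.mismatch, fixed = .fixed)
}

check_alphabet <- function(reads, what = "sequence") {
  bad <- grep("[^ACGTN]", reads)
  if (length(bad)) {
    stop(sprintf("%s %d contains characters outside {A,C,G,T,N}", what, bad[1]),
         call. = FALSE)
  }
  invisible(reads)
}

# Encode sequences as an integer matrix (A=0 C=1 G=2 T=3, N/other = NA).
# Requires uniform length; the workhorse behind pool-wide PWM scoring and
# seed tabulation.
encode_reads <- function(reads) {
  n <- length(reads)
  L <- nchar(reads[1])
  if (any(nchar(reads) != L)) stop("reads must have uniform length", call. = FALSE)
  codes <- match(unlist(strsplit(reads, "", fixed = TRUE)), BASES) - 1L
  matrix(codes, nrow = n, ncol = L, byrow = TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)
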