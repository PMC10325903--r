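# Reading and writing the external formats: read pools, Homer .motif files,
# JASPAR PFMs, BED regions plus genome FASTA.

#' Read one HT-SELEX cycle's read pool
#'
#' Sequences are uppercased; quality strings of FASTQ records are discarded.
#' Sequences containing characters outside A,C,G,T,N are rejected with the
#' offending record index.
#'
#' @param path FASTA or FASTQ file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return character vector of sequences, input order preserved.
#' @export
read_cycle_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  reads <- tryCatch(
    as.character(Biostrings::readBStringSet(path, format = format)),
    error = function(e) stop(sprintf("parse error in %s file '%s': %s",
                                     format, path, conditionMessage(e)),
                             call. = FALSE))
  if (!length(reads)) stop(sprintf("empty %s file: %s", format, path),
                           call. = FALSE)
  reads <- toupper(unname(reads))
  check_alphabet(reads, what = "record")
  reads
}

#' Bundle per-cycle read pools into a cycle set
#'
#' @param cycles named list mapping cycle index (`"0"`, `"1"`, ...) to a
#'   character vector of reads. Cycle 0 is the unselected initial library;
#'   it must be present before enrichment slopes can be fitted.
#' @param source provenance string recorded in reports.
#' @param subsample_seed seed used if the pools were subsampled, or `NULL`.
#' @return an object of class `"selex_cycles"`.
#' @export
selex_cycles <- function(cycles, source = "unspecified", subsample_seed = NULL) {
  idx <- suppressWarnings(as.integer(names(cycles)))
  if (any(is.na(idx)) || any(idx < 0))
    stop("cycle names must be non-negative integers", call. = FALSE)
  if (is.unsorted(idx, strictly = TRUE))
    stop("cycle indices must be strictly increasing", call. = FALSE)
  cycles <- lapply(cycles, function(r) {
    r <- toupper(as.character(r))
    check_alphabet(r, what = "read")
    r
  })
  names(cycles) <- as.character(idx)
  structure(list(cycles = cycles,
                 read_length = nchar(cycles[[1]][1]),
                 source = source,
                 subsample_seed = subsample_seed),
            class = "selex_cycles")
}

#' @export
print.selex_cycles <- function(x, ...) {
  cat(sprintf("HT-SELEX cycle set (%s): cycles %s\n", x$source,
              paste(names(x$cycles), collapse = ", ")))
  for (k in names(x$cycles))
    cat(sprintf("  cycle %s: %d reads of %d bp\n", k, length(x$cycles[[k]]),
                nchar(x$cycles[[k]][1])))
  invisible(x)
}

#' Randomly subsample a read pool
#'
#' Draws `n` reads uniformly without replacement with R's Mersenne-Twister
#' generator under the given seed, so the draw is reproducible. If `n`
#' meets or exceeds the pool size, the whole pool is returned unchanged.
#'
#' @param reads character vector.
#' @param n reads to keep (>= 1).
#' @param seed integer seed.
#' @return character vector of `min(n, length(reads))` reads.
#' @export
subsample_reads <- function(reads, n, seed = 1) {
  if (!is_count(n) || n <= 0) stop("n must be a positive integer", call. = FALSE)
  if (n >= length(reads)) return(reads)
  with_seed(seed, reads[sort(sample.int(length(reads), n))])
}

#' Read a Homer-format motif file
#'
#' Homer `.motif`: a header line `>consensus<TAB>name<TAB>threshold` followed
#' by one row per position with 4 tab-separated probabilities in A,C,G,T
#' order. Probabilities are renormalized on load (Homer files carry rounded
#' values); rows summing outside \[0.9, 1.1\] beforehand are an error. The
#' header log-odds threshold is retained as the PWM's match-score threshold.
#'
#' @param path motif file; may hold several motifs.
#' @return list of [pwm()] objects.
#' @export
read_homer_motif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], ">"))
    stop("not a Homer motif file (no '>' header)", call. = FALSE)
  starts <- grep("^>", lines)
  ends <- c(starts[-1] - 1, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[i]]), "\t")[[1]]
    name <- if (length(hdr) >= 2) hdr[2] else hdr[1]
    threshold <- if (length(hdr) >= 3) as.numeric(hdr[3]) else NULL
    rows <- lines[(starts[i] + 1):ends[i]]
    parsed <- lapply(seq_along(rows), function(j) {
      f <- suppressWarnings(as.numeric(strsplit(rows[j], "[\t ]+")[[1]]))
      if (length(f) != 4 || any(is.na(f)))
        stop(sprintf("motif '%s' row %d: expected 4 probabilities", name, j),
             call. = FALSE)
      if (sum(f) < 0.9 || sum(f) > 1.1)
        stop(sprintf("motif '%s' row %d: probabilities sum to %.3f", name, j,
                     sum(f)), call. = FALSE)
      f
    })
    out[[i]] <- pwm(do.call(rbind, parsed), name = name, threshold = threshold)
  }
  out
}

#' Write a PWM in Homer motif format
#'
#' @param x a [pwm()].
#' @param path output file.
#' @param append append to an existing file?
#' @return `path`, invisibly.
#' @export
write_homer_motif <- function(x, path, append = FALSE) {
  thr <- if (is.null(x$threshold)) 0 else x$threshold
  hdr <- sprintf(">%s\t%s\t%.6g", pwm_consensus(x), x$name, thr)
  rows <- apply(x$mat, 1, function(p) paste(sprintf("%.6f", p), collapse = "\t"))
  cat(c(hdr, rows), file = path, sep = "\n", append = append)
  invisible(path)
}

#' Write a PWM as a JASPAR position frequency matrix
#'
#' Four rows labelled A/C/G/T with bracketed counts,
#' `count = round(probability * counts_scale)`.
#'
#' @param x a [pwm()].
#' @param path output file.
#' @param counts_scale total count each column is scaled to.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(x, path, counts_scale = 100) {
  counts <- round(x$mat * counts_scale)
  lines <- c(sprintf(">%s", x$name),
             sapply(seq_along(BASES), function(b) {
               sprintf("%s  [ %s ]", BASES[b],
                       paste(format(counts[, b], width = 6), collapse = " "))
             }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JASPAR position frequency matrix
#'
#' @param path PFM file as produced by [write_jaspar_pfm()] (also accepts
#'   the bare 4-row layout without base labels or brackets).
#' @return a [pwm()]; counts are normalized to probabilities.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "jaspar_motif"
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4) stop("JASPAR PFM needs 4 base rows", call. = FALSE)
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(is.na(v))) stop("malformed JASPAR PFM row", call. = FALSE)
    v
  })
  if (length(unique(lengths(rows))) != 1)
    stop("JASPAR PFM rows have unequal lengths", call. = FALSE)
  counts <- do.call(cbind, rows)   # L x 4, columns already A,C,G,T order
  pwm(counts, name = name)
}

#' Extract region sequences from a BED file and genome FASTA
#'
#' BED intervals are 0-based half-open, the convention of the BED standard;
#' extracted sequences are uppercased and may contain N.
#'
#' @param bed_path 3+ column BED file (chrom, start, end).
#' @param fasta_path genome FASTA; sequence names must cover every BED
#'   chromosome.
#' @return an object of class `"region_set"`: a list with `intervals`
#'   (data.frame chrom/start/end) and `sequences` (character vector of the
#'   same length).
#' @export
extract_region_sequences <- function(bed_path, fasta_path) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  bed <- bed[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  if (any(bed$start >= bed$end))
    stop("BED intervals must satisfy start < end (0-based half-open)",
         call. = FALSE)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(bed$chrom), names(genome))
  if (length(missing))
    stop(sprintf("chromosome(s) absent from FASTA: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  lens <- Biostrings::width(genome)[match(bed$chrom, names(genome))]
  oob <- bed$start < 0 | bed$end > lens
  if (any(oob))
    stop(sprintf("interval %d (%s:%d-%d) out of chromosome bounds",
                 which(oob)[1], bed$chrom[which(oob)[1]],
                 bed$start[which(oob)[1]], bed$end[which(oob)[1]]),
         call. = FALSE)
  seqs <- toupper(as.character(Biostrings::subseq(
    genome[bed$chrom], start = bed$start + 1, end = bed$end)))
  structure(list(intervals = bed, sequences = unname(seqs)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("RegionSet: %d intervals, widths %d-%d bp\n",
              nrow(x$intervals), min(nchar(x$sequences)),
              max(nchar(x$sequences))))
  invisible(x)
}
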