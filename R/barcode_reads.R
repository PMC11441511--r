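#' Default barcode flank sequences
#'
#' The 20-bp random barcode sits between these vector-derived anchors in the
#' amplicon: `GAGCCTCGTCTCCCACCG` (5') and `GTTTTGAGACGCATGCTGCA` (3').
#' @return Named character vector with elements `flank5` and `flank3`.
#' @export
barcode_flanks <- function() {
  c(flank5 = "GAGCCTCGTCTCCCACCG", flank3 = "GTTTTGAGACGCATGCTGCA")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# hamming distance of two equal-length strings
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Merge a read pair into a consensus single read
#'
#' Reverse-complements mate 2 and scans 3'-overlap lengths, keeping the
#' longest overlap of at least `min_overlap` bases whose mismatch fraction
#' is at most `max_mismatch_frac`. At disagreeing overlap positions the
#' base with the higher Phred score wins (its quality is kept); at agreeing
#' positions the higher of the two qualities is kept.
#'
#' @param seq1,seq2 Mate sequences (mate 2 in sequencing orientation).
#' @param qual1,qual2 Integer Phred scores, one per base.
#' @param min_overlap Minimum acceptable overlap, bases (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return `list(seq =, qual =)` for the consensus, or `NULL` when no
#'   overlap qualifies.
#' @export
merge_read_pair <- function(seq1, qual1, seq2, qual2,
                            min_overlap = 10, max_mismatch_frac = 0.1) {
  if (nchar(seq1) == 0L || nchar(seq2) == 0L)
    stop("mates must be non-empty")
  if (nchar(seq1) != length(qual1) || nchar(seq2) != length(qual2))
    stop("sequence and quality lengths differ")
  s2 <- revcomp(seq2)
  q2 <- rev(qual2)
  r1 <- charToRaw(seq1); r2 <- charToRaw(s2)
  n1 <- length(r1); n2 <- length(r2)

  if (min(n1, n2) < min_overlap) return(NULL)
  best <- 0L
  for (L in seq.int(min(n1, n2), min_overlap, by = -1L)) {  # longest first
    mm <- sum(r1[(n1 - L + 1L):n1] != r2[1:L])
    if (mm / L <= max_mismatch_frac) { best <- L; break }
  }
  if (best == 0L) return(NULL)

  L <- best
  i1 <- (n1 - L + 1L):n1
  ov1 <- r1[i1]; ov2 <- r2[1:L]
  qo1 <- qual1[i1]; qo2 <- q2[1:L]
  agree <- ov1 == ov2
  take1 <- agree | qo1 >= qo2
  cons <- rawToChar(ov1, multiple = TRUE)
  cons[!take1] <- rawToChar(ov2[!take1], multiple = TRUE)
  consq <- ifelse(agree, pmax(qo1, qo2), ifelse(take1, qo1, qo2))
  list(seq = paste0(substr(seq1, 1L, n1 - L),
                    paste(cons, collapse = ""),
                    substr(s2, L + 1L, n2)),
       qual = c(qual1[seq_len(n1 - L)], consq,
                q2[seq(L + 1L, length.out = n2 - L)]))
}

#' Mean-quality read filter
#'
#' Keeps a read iff its mean Phred score is at least `min_mean`
#' (default 30). An optional per-base floor drops reads with any base below
#' `min_base`.
#'
#' @param qual Integer Phred scores of one read, or a list of such vectors.
#' @param min_mean Minimum mean Phred (default 30).
#' @param min_base Optional minimum per-base Phred.
#' @return Logical, one per read.
#' @export
quality_filter <- function(qual, min_mean = 30, min_base = NULL) {
  if (!is.list(qual)) qual <- list(qual)
  vapply(qual, function(q) {
    mean(q) >= min_mean && (is.null(min_base) || all(q >= min_base))
  }, logical(1))
}

# leftmost position where `pattern` matches `seq` with <= max_mm
# substitutions AND the downstream layout verifies via `check(pos)`
scan_fuzzy <- function(seq, pattern, max_mm, check) {
  rs <- charToRaw(seq); rp <- charToRaw(pattern)
  np <- length(rp)
  limit <- length(rs) - np + 1L
  if (limit < 1L) return(NA_integer_)
  for (pos in seq_len(limit)) {
    if (sum(rs[pos:(pos + np - 1L)] != rp) <= max_mm && check(pos))
      return(pos)
  }
  NA_integer_
}

#' Extract the barcode from a consensus read
#'
#' Anchors on `flank5` allowing `floor(tolerance * nchar(flank5))`
#' substitutions (no indels), takes the next `barcode_len` bases, and
#' verifies `flank3` immediately downstream within
#' `floor(tolerance * nchar(flank3))` substitutions. The leftmost position
#' at which the full layout qualifies wins. Barcodes containing `N` are
#' rejected.
#'
#' @param seq Consensus read sequence(s); vectorized.
#' @param flank5,flank3 Anchor sequences (defaults: [barcode_flanks()]).
#' @param tolerance Substitution tolerance as a fraction of flank length
#'   (default 0.1).
#' @param barcode_len Barcode length, bases (default 20).
#' @return Character vector of barcodes, `NA` where extraction failed.
#' @examples
#' fl <- barcode_flanks()
#' read <- paste0("AA", fl["flank5"], strrep("ACGT", 5), fl["flank3"], "CC")
#' extract_barcode(read)
#' @export
extract_barcode <- function(seq, flank5 = barcode_flanks()[["flank5"]],
                            flank3 = barcode_flanks()[["flank3"]],
                            tolerance = 0.1, barcode_len = 20L) {
  stopifnot(nchar(flank5) > 0, nchar(flank3) > 0, barcode_len > 0)
  max5 <- floor(tolerance * nchar(flank5))
  max3 <- floor(tolerance * nchar(flank3))
  n5 <- nchar(flank5); n3 <- nchar(flank3)

  one <- function(s) {
    ns <- nchar(s)
    check <- function(pos) {
      bc_start <- pos + n5
      f3_start <- bc_start + barcode_len
      if (f3_start + n3 - 1L > ns) return(FALSE)
      bc <- substr(s, bc_start, bc_start + barcode_len - 1L)
      if (grepl("N", bc, fixed = TRUE)) return(FALSE)
      hamming(substr(s, f3_start, f3_start + n3 - 1L), flank3) <= max3
    }
    # fast path: exact leftmost flank5 hit that verifies
    pos <- regexpr(flank5, s, fixed = TRUE)
    if (pos > 0L && check(pos)) {
      bc_start <- pos + n5
      return(substr(s, bc_start, bc_start + barcode_len - 1L))
    }
    pos <- scan_fuzzy(s, flank5, max5, check)
    if (is.na(pos)) return(NA_character_)
    bc_start <- pos + n5
    substr(s, bc_start, bc_start + barcode_len - 1L)
  }
  vapply(seq, one, character(1), USE.NAMES = FALSE)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (plain or gzip).
#' @return List with `id` (character), `seq` (character) and `qual` (list of
#'   integer Phred vectors).
#' @export
read_fastq <- function(path) {
  # the quality container drops metadata columns with a warning; harmless
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  qual <- as(Biostrings::quality(x), "IntegerList")
  list(id = names(x),
       seq = unname(suppressWarnings(as.character(x))),
       qual = unname(as.list(qual)))
}

#' Write a FASTQ file
#'
#' @param path Output path.
#' @param id Read identifiers.
#' @param seq Sequences.
#' @param qual List of integer Phred vectors (or a single integer recycled
#'   per base).
#' @export
write_fastq <- function(path, id, seq, qual) {
  if (!is.list(qual)) qual <- lapply(nchar(seq), function(n) rep(qual, n))
  qchar <- vapply(qual, function(q) intToUtf8(q + 33L), character(1))
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qchar))
  invisible(path)
}

#' Process one sample's paired FASTQ into barcode counts
#'
#' Merges pairs, applies the mean-Phred filter, extracts barcodes and
#' tabulates them. Failure counts at each stage are attached as the
#' `stats` attribute.
#'
#' @param fastq1,fastq2 Paths to the mate FASTQ files.
#' @param min_overlap,max_mismatch_frac Merge parameters
#'   (see [merge_read_pair()]).
#' @param min_mean_phred Quality threshold (default 30).
#' @param flank5,flank3,tolerance,barcode_len Extraction parameters
#'   (see [extract_barcode()]).
#' @return Named integer vector of read counts per raw (unclustered)
#'   barcode, sorted by decreasing count.
#' @export
count_sample_barcodes <- function(fastq1, fastq2,
                                  min_overlap = 10, max_mismatch_frac = 0.1,
                                  min_mean_phred = 30,
                                  flank5 = barcode_flanks()[["flank5"]],
                                  flank3 = barcode_flanks()[["flank3"]],
                                  tolerance = 0.1, barcode_len = 20L) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (length(r1$seq) != length(r2$seq))
    stop("mate files differ in read count")
  n <- length(r1$seq)
  merged_seq <- character(n)
  merged_qual <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    m <- merge_read_pair(r1$seq[i], r1$qual[[i]], r2$seq[i], r2$qual[[i]],
                         min_overlap = min_overlap,
                         max_mismatch_frac = max_mismatch_frac)
    if (!is.null(m)) {
      ok[i] <- TRUE
      merged_seq[i] <- m$seq
      merged_qual[[i]] <- m$qual
    }
  }
  keep <- ok
  keep[ok] <- quality_filter(merged_qual[ok], min_mean = min_mean_phred)
  bc <- extract_barcode(merged_seq[keep], flank5 = flank5, flank3 = flank3,
                        tolerance = tolerance, barcode_len = barcode_len)
  counts <- table(bc[!is.na(bc)])
  out <- sort(stats::setNames(as.integer(counts), names(counts)),
              decreasing = TRUE)
  attr(out, "stats") <- c(n_pairs = n, n_merged = sum(ok),
                          n_quality = sum(keep),
                          n_extracted = sum(!is.na(bc)))
  out
}
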