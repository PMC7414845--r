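#' Ancient-DNA authenticity summaries
#'
#' Read-level summaries used to authenticate ancient sequence data: the
#' fragment-length distribution (ancient molecules are short), terminal
#' misincorporation profiles (postmortem cytosine deamination produces
#' elevated C->T rates at 5' ends and, on the complementary strand, G->A at
#' 3' ends, decaying inward), and reference coverage. Mapping itself is out
#' of scope: these functions summarize a given alignment.
#'
#' @name adna_damage
NULL

#' Fragment length statistics
#'
#' @param reads a [read_set].
#' @return list with `n`, `mean`, `median`, `sd` (NA for a single read).
#' @export
fragment_length_stats <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  lens <- nchar(reads$reads$sequence)
  if (length(lens) == 0L) .pc_stop("empty read set")
  list(n = length(lens), mean = mean(lens), median = stats::median(lens),
       sd = if (length(lens) > 1L) stats::sd(lens) else NA_real_)
}

# reference windows in read orientation
.read_space_ref <- function(reads) {
  lens <- nchar(reads$reads$sequence)
  win <- substring(reads$reference, reads$reads$start + 1,
                   reads$reads$start + lens)
  neg <- reads$reads$strand == "-"
  if (any(neg)) win[neg] <- .revcomp(win[neg])
  win
}

#' Terminal misincorporation (damage) profile
#'
#' For each position `i = 1..K` from the 5' end, the C->T rate is the number
#' of reads carrying T where the read-oriented reference has C, divided by
#' the number of reads whose read-oriented reference has C at that position
#' (the "opportunities"). The G->A profile is computed symmetrically from
#' the 3' end. Reverse-strand reads are handled by complementing the
#' reference window, so damage is always measured in the molecule's own
#' 5'->3' frame. Rates are `NA` where there are no opportunities.
#'
#' @param reads a [read_set].
#' @param K number of terminal positions profiled (default 25).
#' @return object of class `damage_profile`: data frame with columns
#'   `position`, `ct5_rate`, `ct5_n`, `ga3_rate`, `ga3_n`.
#' @export
damage_profile <- function(reads, K = 25) {
  stopifnot(inherits(reads, "read_set"))
  seqs <- reads$reads$sequence
  if (length(seqs) == 0L) .pc_stop("empty read set")
  refw <- .read_space_ref(reads)
  lens <- nchar(seqs)
  ct <- ctn <- ga <- gan <- numeric(K)
  for (k in seq_len(K)) {
    ok <- lens >= k
    r5 <- substring(refw[ok], k, k)
    s5 <- substring(seqs[ok], k, k)
    opp <- r5 == "C"
    ctn[k] <- sum(opp)
    ct[k] <- if (ctn[k] > 0) sum(opp & s5 == "T") / ctn[k] else NA_real_
    p3 <- lens[ok] - k + 1L
    r3 <- substring(refw[ok], p3, p3)
    s3 <- substring(seqs[ok], p3, p3)
    opp <- r3 == "G"
    gan[k] <- sum(opp)
    ga[k] <- if (gan[k] > 0) sum(opp & s3 == "A") / gan[k] else NA_real_
  }
  structure(data.frame(position = seq_len(K), ct5_rate = ct, ct5_n = ctn,
                       ga3_rate = ga, ga3_n = gan),
            class = c("damage_profile", "data.frame"))
}

#' Per-position read depth on the reference
#'
#' @param reads a [read_set].
#' @return integer vector of depth, one per reference position.
#' @export
read_depth <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  L <- nchar(reads$reference)
  lens <- nchar(reads$reads$sequence)
  delta <- numeric(L + 1L)
  tb <- tabulate(reads$reads$start + 1L, nbins = L + 1L)
  te <- tabulate(reads$reads$start + lens + 1L, nbins = L + 1L)
  cumsum(tb - te)[seq_len(L)]
}

#' Coverage summary
#'
#' Fraction of reference positions covered at least once, and mean depth
#' over all reference positions (zero-depth positions included).
#'
#' @param depth integer/numeric vector of per-position depth, or a
#'   [read_set] (depth then computed with [read_depth]).
#' @return list with `fraction_covered`, `mean_depth`, `length`.
#' @export
coverage_summary <- function(depth) {
  if (inherits(depth, "read_set")) depth <- read_depth(depth)
  if (length(depth) == 0L) .pc_stop("empty depth vector")
  list(fraction_covered = mean(depth >= 1), mean_depth = mean(depth),
       length = length(depth))
}

#' Write / read an aligned read set as TSV
#'
#' Columns: `read_id`, `ref_start_0based`, `strand`, `sequence` (read
#' orientation). The reference travels separately as FASTA.
#'
#' @param reads a [read_set].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  d <- reads$reads
  names(d) <- c("read_id", "ref_start_0based", "strand", "sequence")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @param reference reference sequence (character) or path to a FASTA file.
#' @param min_len length filter recorded in the set's metadata.
#' @export
read_reads_tsv <- function(path, reference, min_len = 0L) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(d)[names(d) == "ref_start_0based"] <- "start"
  if (file.exists(reference)) reference <- read_fasta(reference)
  read_set(d, reference, min_len = min_len)
}

#' Read / write a single-sequence FASTA file
#'
#' @param path FASTA path.
#' @return `read_fasta`: the first sequence as a character scalar.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) < 1L) .pc_stop("no sequences in %s", path)
  as.character(x[[1]])
}

#' @rdname read_fasta
#' @param seq sequence (character scalar).
#' @param name FASTA record name.
#' @export
write_fasta <- function(seq, path, name = "ref") {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write / read an aligned read set as SAM
#'
#' A minimal SAM representation of the alignment: unpaired reads, CIGAR
#' all-match, no qualities. SEQ is stored in reference orientation (flag 16
#' marks reverse-strand reads), per the SAM convention; reading converts
#' back to read orientation. Ingestion goes through Rsamtools.
#'
#' @param reads a [read_set].
#' @param path SAM path.
#' @param ref_name reference sequence name used in the header.
#' @export
write_sam <- function(reads, path, ref_name = "ref") {
  stopifnot(inherits(reads, "read_set"))
  d <- reads$reads
  lens <- nchar(d$sequence)
  seq_out <- d$sequence
  neg <- d$strand == "-"
  if (any(neg)) seq_out[neg] <- .revcomp(d$sequence[neg])
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", ref_name, nchar(reads$reference)),
             sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                     d$read_id, ifelse(neg, 16L, 0L), ref_name,
                     d$start + 1L, lens, seq_out))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sam
#' @param reference reference sequence (character) or FASTA path.
#' @param min_len length filter recorded in the set's metadata.
#' @export
read_reads_sam <- function(path, reference, min_len = 0L) {
  if (file.exists(reference)) reference <- read_fasta(reference)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "seq", "strand")))[[1]]
  neg <- as.character(b$strand) == "-"
  seqs <- as.character(b$seq)
  if (any(neg)) seqs[neg] <- .revcomp(seqs[neg])
  read_set(data.frame(read_id = b$qname, start = b$pos - 1L,
                      strand = ifelse(neg, "-", "+"), sequence = seqs,
                      stringsAsFactors = FALSE),
           reference, min_len = min_len)
}
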