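#' Configuration for the ancient-read simulator
#'
#' Emulates the read-level signature of authentic ancient DNA: short
#' fragments with a right-skewed (lognormal) length distribution, and
#' cytosine deamination read as C->T substitutions at the 5' end and
#' G->A at the 3' end, with per-position rates decaying exponentially
#' away from each terminus.
#'
#' @param ref_length reference length (bp) when a reference is simulated.
#' @param n_reads number of fragments to draw (before length filtering).
#' @param mean_len,sd_len mean and sd of fragment length (bp); the lognormal
#'   is moment-matched to these. The default sd is small enough relative to
#'   `min_len` that truncation leaves the mean essentially unchanged.
#' @param ct5_rate terminal 5' C->T substitution probability (position 1).
#' @param ga3_rate terminal 3' G->A substitution probability (position 1
#'   from the 3' end).
#' @param decay_lambda per-position exponential decay of the deamination
#'   probability moving inward from a terminus.
#' @param min_len fragments shorter than this are discarded (default 30).
#' @param seed integer seed.
#' @return list of class `read_sim_config`.
#' @export
read_sim_config <- function(ref_length = 16727, n_reads = 10000,
                            mean_len = 57.6, sd_len = 12,
                            ct5_rate = 0.38, ga3_rate = 0.48,
                            decay_lambda = 0.3, min_len = 30, seed = 1) {
  .check_range(ct5_rate, "ct5_rate", 0, 1)
  .check_range(ga3_rate, "ga3_rate", 0, 1)
  .check_range(decay_lambda, "decay_lambda", 0)
  .check_range(mean_len, "mean_len", min_len, lo_open = TRUE)
  .check_range(sd_len, "sd_len", 0, lo_open = TRUE)
  if (n_reads < 1) .pc_stop("`n_reads` must be >= 1")
  structure(list(ref_length = ref_length, n_reads = n_reads,
                 mean_len = mean_len, sd_len = sd_len,
                 ct5_rate = ct5_rate, ga3_rate = ga3_rate,
                 decay_lambda = decay_lambda, min_len = min_len,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' An aligned ancient-read set
#'
#' @param reads data frame with columns `read_id`, `start` (0-based
#'   leftmost reference position), `strand` (`"+"`/`"-"`), `sequence`
#'   (in read orientation, i.e. as sequenced, 5' to 3').
#' @param reference single reference sequence (character scalar).
#' @param min_len the length filter that was applied.
#' @return object of class `read_set`.
#' @export
read_set <- function(reads, reference, min_len = 0L) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "start", "strand", "sequence") %in% names(reads)))
  lens <- nchar(reads$sequence)
  if (any(reads$start < 0) || any(reads$start + lens > nchar(reference)))
    .pc_stop("reads map outside the reference bounds")
  if (any(!reads$strand %in% c("+", "-")))
    .pc_stop("`strand` must be '+' or '-'")
  structure(list(reads = reads, reference = toupper(reference),
                 min_len = min_len),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads on a %d bp reference (min_len %d)\n",
              nrow(x$reads), nchar(x$reference), x$min_len))
  invisible(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a random nucleotide reference
#'
#' @param length sequence length (bp).
#' @param seed integer seed.
#' @param gc GC content.
#' @return character scalar.
#' @export
gen_reference <- function(length, seed = 1, gc = 0.42) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Simulate an aligned ancient-read set with deamination damage
#'
#' Fragment lengths are lognormal (moment-matched to `mean_len`/`sd_len`),
#' fragments below `min_len` are discarded, start positions are uniform over
#' placements that fit the reference, and strands are drawn with equal
#' probability. Damage is applied in read orientation: a reference C at
#' 0-based position i from the 5' end is read as T with probability
#' `ct5_rate * exp(-decay_lambda * i)`, and a reference G at position j from
#' the 3' end as A with probability `ga3_rate * exp(-decay_lambda * j)`.
#'
#' @param cfg a [read_sim_config].
#' @param reference optional reference sequence; simulated from
#'   `cfg$ref_length` when omitted.
#' @return a [read_set] with attribute `truth` (the config).
#' @export
gen_ancient_reads <- function(cfg = read_sim_config(), reference = NULL) {
  stopifnot(inherits(cfg, "read_sim_config"))
  set.seed(cfg$seed)
  if (is.null(reference))
    reference <- gen_reference(cfg$ref_length, seed = cfg$seed + 1L)
  reference <- toupper(reference)
  L <- nchar(reference)
  s2 <- log(1 + (cfg$sd_len / cfg$mean_len)^2)
  lens <- round(stats::rlnorm(cfg$n_reads, log(cfg$mean_len) - s2 / 2, sqrt(s2)))
  keep <- lens >= cfg$min_len & lens <= L
  lens <- lens[keep]
  n <- length(lens)
  if (n == 0L) .pc_stop("all simulated fragments shorter than min_len")
  starts <- as.integer(floor(stats::runif(n) * (L - lens + 1)))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  win <- substring(reference, starts + 1, starts + lens)
  seqs <- win
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- .revcomp(win[neg])
  # vectorized per-base damage
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  pos5 <- sequence(lens) - 1L
  pos3 <- rep(lens, lens) - 1L - pos5
  isC <- chars == "C"
  hit <- isC & stats::runif(length(chars)) <
    cfg$ct5_rate * exp(-cfg$decay_lambda * pos5)
  chars[hit] <- "T"
  isG <- chars == "G"
  hit <- isG & stats::runif(length(chars)) <
    cfg$ga3_rate * exp(-cfg$decay_lambda * pos3)
  chars[hit] <- "A"
  big <- paste(chars, collapse = "")
  ends <- cumsum(lens)
  seqs <- substring(big, ends - lens + 1, ends)
  rs <- read_set(data.frame(read_id = sprintf("sim_%06d", seq_len(n)),
                            start = starts, strand = strand,
                            sequence = seqs, stringsAsFactors = FALSE),
                 reference, min_len = cfg$min_len)
  attr(rs, "truth") <- cfg
  rs
}
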