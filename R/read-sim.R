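#' Simulation configuration
#'
#' Bundles and validates the paired-end library parameters used by
#' [simulate_read_pairs()]. Fragment lengths follow a normal law truncated
#' below at `2 * read_len` so both mates always fit inside the fragment.
#'
#' @param coverage Mean fold coverage of the mutated genome.
#' @param read_len Read length in bases (both mates).
#' @param insert_mean,insert_sd Mean and standard deviation of the fragment
#'   (outer insert) length in bases.
#' @param error_rate Per-base substitution probability, in `[0, 0.05)`.
#'   Substitutions only; the simulator introduces no indel errors.
#' @param seed Integer seed controlling all randomness of the simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(coverage = 50, read_len = 100L, insert_mean = 300,
                       insert_sd = 30, error_rate = 0.002, seed = 1L) {
  if (coverage <= 0) stopf("coverage must be positive")
  if (insert_mean <= 2 * read_len)
    stopf("insert_mean must exceed 2 * read_len")
  if (error_rate < 0 || error_rate >= 0.05)
    stopf("error_rate must lie in [0, 0.05)")
  if (insert_sd < 0) stopf("insert_sd must be >= 0")
  structure(list(coverage = coverage, read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate paired-end reads from a (mutated) genome
#'
#' Draws `round(coverage * total_length / (2 * read_len))` fragments.
#' Fragments are assigned to replicons with probability proportional to
#' replicon length, start uniformly, and have normal(insert_mean, insert_sd)
#' lengths truncated at `[2 * read_len, Inf)`. Mate 1 is the fragment's 5'
#' end on the forward strand; mate 2 is the reverse complement of its 3'
#' end. Sequencing errors are i.i.d. substitutions at `error_rate`.
#'
#' @param genome The genome reads are drawn from (typically the mutated
#'   genome returned by [plant_events()]).
#' @param cfg A [sim_config()].
#' @return A `data.frame` with one row per pair: `pair_id`, `replicon`,
#'   `frag_start` (0-based, on `genome`), `frag_len`, `seq1`, `seq2`.
#' @export
simulate_read_pairs <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rl <- cfg$read_len
  lens <- Biostrings::width(genome)
  if (any(lens < 10 * cfg$insert_mean))
    stopf("every replicon must be at least 10 * insert_mean long")
  total <- sum(lens)
  n <- round(cfg$coverage * total / (2 * rl))
  set.seed(cfg$seed)
  repl_idx <- sample.int(length(lens), n, replace = TRUE, prob = lens)
  frag_len <- round(stats::rnorm(n, cfg$insert_mean, cfg$insert_sd))
  while (any(short <- frag_len < 2L * rl))  # truncation by resampling
    frag_len[short] <- round(stats::rnorm(sum(short), cfg$insert_mean, cfg$insert_sd))
  frag_start <- floor(stats::runif(n) * (lens[repl_idx] - frag_len + 1))
  frag_start <- as.integer(pmax(frag_start, 0L))

  seqs <- as.character(genome)
  seq1 <- character(n)
  seq2 <- character(n)
  for (i in seq_along(seqs)) {
    sel <- repl_idx == i
    if (!any(sel)) next
    fs <- frag_start[sel]
    fl <- frag_len[sel]
    seq1[sel] <- substring(seqs[i], fs + 1L, fs + rl)
    seq2[sel] <- substring(seqs[i], fs + fl - rl + 1L, fs + fl)
  }
  seq2 <- rc_chr(seq2)
  if (cfg$error_rate > 0) {
    seq1 <- add_substitutions(seq1, cfg$error_rate)
    seq2 <- add_substitutions(seq2, cfg$error_rate)
  }
  data.frame(pair_id = sprintf("sim%08d", seq_len(n)),
             replicon = names(genome)[repl_idx],
             frag_start = frag_start, frag_len = as.integer(frag_len),
             seq1 = seq1, seq2 = seq2, stringsAsFactors = FALSE)
}

# i.i.d. substitution errors: draw the genome-wide error count, place errors
# uniformly, and rewrite each hit base to one of the three alternatives.
add_substitutions <- function(reads, rate) {
  rl <- nchar(reads[1])
  n_bases <- length(reads) * rl
  m <- stats::rbinom(1L, n_bases, rate)
  if (m == 0L) return(reads)
  pos <- sample.int(n_bases, m)
  read_i <- (pos - 1L) %/% rl + 1L
  off <- (pos - 1L) %% rl + 1L
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  pick <- sample.int(3L, m, replace = TRUE)
  for (j in seq_len(m)) {
    cur <- substr(reads[read_i[j]], off[j], off[j])
    substr(reads[read_i[j]], off[j], off[j]) <-
      substr(alt[[cur]], pick[j], pick[j])
  }
  reads
}

#' Write simulated pairs to a FASTQ file pair
#'
#' @param pairs Output of [simulate_read_pairs()].
#' @param prefix Path prefix; writes `<prefix>_1.fastq` and `<prefix>_2.fastq`
#'   with `/1` and `/2` read-name suffixes and constant quality `I`.
#' @return Invisibly, the two file paths.
#' @export
write_fastq <- function(pairs, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    sq <- pairs[[paste0("seq", m)]]
    qual <- strrep("I", nchar(sq))
    con <- file(paths[m], "w")
    writeLines(paste0("@", pairs$pair_id, "/", m, "\n", sq, "\n+\n", qual), con)
    close(con)
  }
  invisible(paths)
}
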