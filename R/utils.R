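# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere inside the package; files (SAM, TSV reports, GFF3) use the
# 1-based conventions of their formats.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @importFrom Biostrings DNAStringSet reverseComplement
rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA with a given expected GC content, returned as one string.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Reference width of a CIGAR string (sum of M/D/N/=/X op lengths).
# Vectorised over unique values since alignment streams repeat few CIGARs.
cigar_ref_width <- function(cigar) {
  u <- unique(cigar)
  w <- vapply(u, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
  unname(w[match(cigar, u)])
}

total_genome_length <- function(genome) sum(Biostrings::width(genome))
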