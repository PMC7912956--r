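#' Generate a random multi-replicon reference genome
#'
#' Draws i.i.d. nucleotides with a target GC content for each replicon.
#' Bacterial genomes such as *Cupriavidus metallidurans* CH34 carry several
#' replicons (chromosome, chromid, megaplasmids); downstream functions treat
#' each as an independent coordinate system.
#'
#' @param lengths Integer vector of replicon lengths in bases.
#' @param gc Expected GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param names Replicon names; defaults to `repl_1`, `repl_2`, ...
#' @return A named [Biostrings::DNAStringSet], one entry per replicon.
#' @examples
#' g <- generate_genome(c(10000, 5000), gc = 0.6, seed = 1)
#' Biostrings::width(g)
#' @export
generate_genome <- function(lengths, gc = 0.5, seed = 1L, names = NULL) {
  lengths <- as.integer(lengths)
  if (length(lengths) < 1L || any(is.na(lengths)) || any(lengths <= 0L))
    stopf("replicon lengths must be positive integers")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    stopf("gc must lie strictly between 0 and 1")
  if (is.null(names)) names <- paste0("repl_", seq_along(lengths))
  if (anyDuplicated(names) || any(!nzchar(names)))
    stopf("replicon names must be unique and non-empty")
  set.seed(as.integer(seed))
  seqs <- vapply(lengths, random_dna, character(1), gc = gc)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names
  out
}

#' Generate a catalog of insertion-sequence (IS) elements
#'
#' Each element is a random sequence whose first `ir_len` bases are the
#' reverse complement of its last `ir_len` bases (terminal inverted repeats,
#' the structural hallmark of an IS element). Elements are rejection-sampled
#' until all pairwise sequence identities fall below `max_identity`, so that
#' reads from one element cannot be attributed to another.
#'
#' @param names Unique element names, e.g. `c("IS1088", "ISRme5", "ISRme15")`.
#' @param lengths Element lengths in bases (bacterial IS elements are
#'   typically 700-3000 bp).
#' @param ir_len Terminal inverted-repeat length in bases.
#' @param tsd_len Target-site duplication created on insertion, in bases.
#' @param seed Integer seed.
#' @param max_identity Maximum tolerated pairwise positional identity.
#' @return A [Biostrings::DNAStringSet] with `ir_len` and `tsd_len` metadata
#'   columns.
#' @export
generate_is_catalog <- function(names, lengths, ir_len = 25L, tsd_len = 8L,
                                seed = 1L, max_identity = 0.6) {
  lengths <- as.integer(lengths)
  if (anyDuplicated(names)) stopf("IS element names must be unique")
  if (length(names) != length(lengths))
    stopf("names and lengths must have equal length")
  if (any(lengths < 700L) || any(lengths > 3000L))
    stopf("IS element lengths must lie in [700, 3000] bases")
  if (2L * ir_len > min(lengths))
    stopf("2 * ir_len exceeds the shortest element length")
  if (tsd_len < 0L) stopf("tsd_len must be >= 0")
  set.seed(as.integer(seed))
  make_one <- function(len) {
    core <- random_dna(len - ir_len, gc = 0.5)
    ir <- substr(core, 1L, ir_len)
    paste0(core, rc_chr(ir))
  }
  for (attempt in seq_len(100L)) {
    seqs <- vapply(lengths, make_one, character(1))
    if (max_pairwise_identity(seqs) < max_identity) break
    if (attempt == 100L) stopf("could not sample elements below %.0f%% identity",
                               100 * max_identity)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    ir_len = rep(as.integer(ir_len), length(out)),
    tsd_len = rep(as.integer(tsd_len), length(out)))
  out
}

# Positional identity over the shared prefix, the discriminability proxy the
# element sampler enforces. Random sequences sit near 0.25 so rejection is rare.
max_pairwise_identity <- function(seqs) {
  if (length(seqs) < 2L) return(0)
  best <- 0
  for (i in seq_len(length(seqs) - 1L)) for (j in seq(i + 1L, length(seqs))) {
    n <- min(nchar(seqs[i]), nchar(seqs[j]))
    a <- strsplit(substr(seqs[i], 1, n), "")[[1]]
    b <- strsplit(substr(seqs[j], 1, n), "")[[1]]
    best <- max(best, mean(a == b))
  }
  best
}

#' Build a truth-event table
#'
#' Convenience constructor for the event table consumed by [plant_events()].
#' Insertions are zero-length breakpoints (`start == end`) naming a catalog
#' element and a strand; deletions are half-open intervals `[start, end)`.
#'
#' @param kind `"insertion"` or `"deletion"` per event.
#' @param replicon Replicon name per event.
#' @param start,end 0-based half-open coordinates on the original reference.
#'   For insertions `end` must equal `start`.
#' @param element Catalog element name (insertions) or `NA` (deletions).
#' @param strand `"+"` or `"-"` for insertions, `NA` otherwise.
#' @return A `data.frame` with one row per event.
#' @export
truth_events <- function(kind, replicon, start, end = start, element = NA,
                         strand = NA) {
  n <- length(start)
  df <- data.frame(kind = rep_len(as.character(kind), n),
                   replicon = rep_len(as.character(replicon), n),
                   start = as.integer(start),
                   end = rep_len(as.integer(end), n),
                   element = rep_len(as.character(element), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  bad <- df$kind == "insertion" & df$start != df$end
  if (any(bad)) stopf("insertion events must have start == end")
  if (any(df$kind == "deletion" & df$end <= df$start))
    stopf("deletion events must have end > start")
  if (!all(df$kind %in% c("insertion", "deletion")))
    stopf("event kind must be 'insertion' or 'deletion'")
  df[order(df$replicon, df$start), , drop = FALSE]
}

#' Plant insertion and deletion events into a genome
#'
#' Applies a sorted, non-overlapping set of truth events to the reference.
#' An insertion at position `p` of element `E` with target-site duplication
#' length `t` produces `original[0, p + t) + E + original[p, ...)`: the `t`
#' bases at `[p, p + t)` are duplicated on both sides of the element, as a
#' transposase does on integration. A deletion excises `[start, end)`.
#' Elements planted on the `-` strand are inserted reverse-complemented.
#'
#' @param genome A [Biostrings::DNAStringSet] reference.
#' @param events Event table from [truth_events()].
#' @param catalog IS catalog from [generate_is_catalog()].
#' @return A list with `genome` (the mutated [Biostrings::DNAStringSet]) and
#'   `truth` (the event table with added columns: `size`, the net length
#'   change source; `mut_start`/`mut_end`, the event's footprint in mutated
#'   coordinates).
#' @export
plant_events <- function(genome, events, catalog) {
  if (nrow(events) == 0L) {
    events$size <- integer(0); events$mut_start <- integer(0)
    events$mut_end <- integer(0)
    return(list(genome = genome, truth = events))
  }
  if (!all(events$replicon %in% names(genome)))
    stopf("events name unknown replicons: %s",
          paste(setdiff(events$replicon, names(genome)), collapse = ", "))
  ins <- events$kind == "insertion"
  if (any(ins & !(events$element %in% names(catalog))))
    stopf("unknown catalog element: %s",
          paste(setdiff(events$element[ins], names(catalog)), collapse = ", "))
  tsd <- S4Vectors::mcols(catalog)$tsd_len
  names(tsd) <- names(catalog)

  events$size <- ifelse(ins,
                        Biostrings::width(catalog)[match(events$element, names(catalog))] +
                          tsd[events$element],
                        events$end - events$start)
  events$mut_start <- NA_integer_
  events$mut_end <- NA_integer_

  out_seqs <- as.character(genome)
  for (rep_name in unique(events$replicon)) {
    ev <- events[events$replicon == rep_name, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    L <- Biostrings::width(genome)[match(rep_name, names(genome))]
    if (any(ev$end > L)) stopf("event exceeds bounds of replicon %s", rep_name)
    # non-overlap: each event must start at or after the previous one ends
    if (nrow(ev) > 1L && any(ev$start[-1L] < ev$end[-nrow(ev)]))
      stopf("overlapping events on replicon %s", rep_name)
    orig <- as.character(genome[[rep_name]])
    pieces <- character(0)
    cursor <- 0L  # next original base to emit
    mut_len <- 0L
    for (k in seq_len(nrow(ev))) {
      if (ev$kind[k] == "insertion") {
        p <- ev$start[k]
        t <- unname(tsd[ev$element[k]])
        if (p + t > L) stopf("insertion TSD exceeds replicon %s", rep_name)
        el <- as.character(catalog[[ev$element[k]]])
        if (!is.na(ev$strand[k]) && ev$strand[k] == "-") el <- rc_chr(el)
        lead <- substr(orig, cursor + 1L, p + t)  # up to and incl. first TSD copy
        pieces <- c(pieces, lead, el)
        mut_len <- mut_len + nchar(lead)
        idx <- which(events$replicon == rep_name & events$start == ev$start[k] &
                       events$kind == "insertion")
        events$mut_start[idx] <- mut_len
        events$mut_end[idx] <- mut_len + nchar(el)
        mut_len <- mut_len + nchar(el)
        cursor <- p  # re-emit [p, p+t) after the element: second TSD copy
      } else {
        lead <- substr(orig, cursor + 1L, ev$start[k])
        pieces <- c(pieces, lead)
        mut_len <- mut_len + nchar(lead)
        idx <- which(events$replicon == rep_name & events$start == ev$start[k] &
                       events$kind == "deletion")
        events$mut_start[idx] <- mut_len
        events$mut_end[idx] <- mut_len
        cursor <- ev$end[k]
      }
    }
    pieces <- c(pieces, substr(orig, cursor + 1L, L))
    out_seqs[rep_name] <- paste(pieces, collapse = "")
  }
  mutated <- Biostrings::DNAStringSet(out_seqs)
  names(mutated) <- names(genome)
  list(genome = mutated, truth = events)
}

# Piecewise map from mutated coordinates back to the original reference and
# the element catalog, one table per replicon. Columns: mut_start/mut_end
# (half-open, mutated frame), target (replicon or element name), target_start
# (0-based in the target), type ("ref"/"element"), strand of the mapping.
segment_map <- function(genome, truth, catalog) {
  tsd <- S4Vectors::mcols(catalog)$tsd_len
  names(tsd) <- names(catalog)
  maps <- list()
  for (rep_name in names(genome)) {
    L <- Biostrings::width(genome)[match(rep_name, names(genome))]
    ev <- truth[truth$replicon == rep_name, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    seg <- data.frame(mut_start = integer(0), mut_end = integer(0),
                      target = character(0), target_start = integer(0),
                      type = character(0), strand = character(0),
                      stringsAsFactors = FALSE)
    cursor_orig <- 0L
    cursor_mut <- 0L
    add <- function(seg, len, target, target_start, type, strand) {
      if (len <= 0L) return(seg)
      rbind(seg, data.frame(mut_start = cursor_mut, mut_end = cursor_mut + len,
                            target = target, target_start = target_start,
                            type = type, strand = strand,
                            stringsAsFactors = FALSE))
    }
    for (k in seq_len(nrow(ev))) {
      if (ev$kind[k] == "insertion") {
        p <- ev$start[k]
        t <- unname(tsd[ev$element[k]])
        el_len <- Biostrings::width(catalog)[match(ev$element[k], names(catalog))]
        len <- p + t - cursor_orig
        seg <- add(seg, len, rep_name, cursor_orig, "ref", "+")
        cursor_mut <- cursor_mut + len
        st <- if (!is.na(ev$strand[k])) ev$strand[k] else "+"
        seg <- add(seg, el_len, ev$element[k], 0L, "element", st)
        cursor_mut <- cursor_mut + el_len
        cursor_orig <- p
      } else {
        len <- ev$start[k] - cursor_orig
        seg <- add(seg, len, rep_name, cursor_orig, "ref", "+")
        cursor_mut <- cursor_mut + len
        cursor_orig <- ev$end[k]
      }
    }
    seg <- add(seg, L - cursor_orig, rep_name, cursor_orig, "ref", "+")
    maps[[rep_name]] <- seg
  }
  maps
}
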