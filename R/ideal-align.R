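#' Project simulated read pairs onto the original reference as ideal alignments
#'
#' Maps every simulated mate back onto the *original* reference by coordinate
#' lift-over through the truth events, writing a valid SAM file. This stands
#' in for an external aligner so the detection stages can be exercised with
#' exactly known evidence:
#'
#' * a mate lying entirely in unchanged sequence maps at its lifted position;
#' * a mate lying entirely inside an inserted element maps to that element's
#'   catalog sequence (catalog entries appear as extra `@SQ` references);
#' * a mate straddling any junction is emitted unmapped by default (the
#'   "unpaired read" signal that drives insertion detection); with
#'   `clip_mode = "softclip"` it is instead mapped on its longer side when
#'   that anchor reaches `min_anchor` bases;
#' * mates bridging a deletion map at lifted positions, so the pair's
#'   apparent insert size exceeds the fragment length by the deletion size.
#'
#' @param pairs Output of [simulate_read_pairs()] (coordinates on the
#'   mutated genome).
#' @param original The original reference [Biostrings::DNAStringSet].
#' @param catalog The IS catalog used when planting events.
#' @param truth Truth table from [plant_events()].
#' @param sam_path Output SAM path.
#' @param min_anchor Minimum mapped bases required to place a junction-
#'   straddling mate in `"softclip"` mode.
#' @param clip_mode `"unmapped"` (default) or `"softclip"`.
#' @return Invisibly, `sam_path`.
#' @export
project_ideal_alignments <- function(pairs, original, catalog, truth, sam_path,
                                     min_anchor = 20L,
                                     clip_mode = c("unmapped", "softclip")) {
  clip_mode <- match.arg(clip_mode)
  rl <- nchar(pairs$seq1[1])
  maps <- segment_map(original, truth, catalog)
  n <- nrow(pairs)

  mate_tbl <- function(starts, strands) {
    # one mate per pair: mutated-frame [start, start + rl), sequenced strand
    out <- data.frame(rname = rep(NA_character_, n), pos = NA_integer_,
                      strand = strands, mapped = FALSE,
                      cigar = rep("*", n), clip_left = 0L,
                      stringsAsFactors = FALSE)
    for (rep_name in unique(pairs$replicon)) {
      seg <- maps[[rep_name]]
      sel <- which(pairs$replicon == rep_name)
      s <- starts[sel]
      e <- s + rl
      idx <- findInterval(s, seg$mut_start)
      contained <- e <= seg$mut_end[idx]
      place <- function(rows, segrow, s0, width, clip_left) {
        # map `width` bases beginning at mutated coord s0 through segment segrow
        off <- s0 - seg$mut_start[segrow]
        el <- seg$type[segrow] == "element"
        minus_el <- el & seg$strand[segrow] == "-"
        pos <- ifelse(minus_el,
                      nchar_target(seg$target[segrow], original, catalog) -
                        (off + width),
                      seg$target_start[segrow] + off)
        out$rname[rows] <<- seg$target[segrow]
        out$pos[rows] <<- as.integer(pos)
        out$mapped[rows] <<- TRUE
        out$strand[rows] <<- ifelse(minus_el,
                                    ifelse(out$strand[rows] == "+", "-", "+"),
                                    out$strand[rows])
        out$cigar[rows] <<- cigar_clip(width, rl, clip_left)
        out$clip_left[rows] <<- as.integer(clip_left)
      }
      ok <- which(contained)
      if (length(ok)) place(sel[ok], idx[ok], s[ok], rl, 0L)
      if (clip_mode == "softclip") {
        bad <- which(!contained)
        if (length(bad)) {
          idx2 <- findInterval(e[bad] - 1L, seg$mut_start)
          left_anchor <- seg$mut_end[idx[bad]] - s[bad]
          right_anchor <- e[bad] - seg$mut_start[idx2]
          use_left <- left_anchor >= right_anchor
          anchor <- ifelse(use_left, left_anchor, right_anchor)
          keep <- anchor >= min_anchor
          kl <- which(keep & use_left)
          kr <- which(keep & !use_left)
          if (length(kl)) place(sel[bad][kl], idx[bad][kl], s[bad][kl],
                                left_anchor[kl], 0L)
          if (length(kr)) place(sel[bad][kr], idx2[kr],
                                seg$mut_start[idx2[kr]], right_anchor[kr],
                                rl - right_anchor[kr])
        }
      }
    }
    out
  }
  m1 <- mate_tbl(pairs$frag_start, rep("+", n))
  m2 <- mate_tbl(pairs$frag_start + pairs$frag_len - rl, rep("-", n))

  write_sam(pairs, m1, m2, rl, original, catalog, sam_path)
  invisible(sam_path)
}

nchar_target <- function(target, original, catalog) {
  w <- c(stats::setNames(Biostrings::width(original), names(original)),
         stats::setNames(Biostrings::width(catalog), names(catalog)))
  unname(w[target])
}

cigar_clip <- function(width, rl, clip_left) {
  ifelse(width == rl, paste0(rl, "M"),
         ifelse(clip_left > 0L,
                paste0(clip_left, "S", width, "M"),
                paste0(width, "M", rl - width, "S")))
}

# Assemble and write the two-mates-per-pair SAM stream. SEQ is stored in
# forward-reference orientation for mapped reverse-strand mates, per the
# SAM convention (0x10 set => SEQ is the reverse complement of the read as
# sequenced).
write_sam <- function(pairs, m1, m2, rl, original, catalog, sam_path) {
  qual <- strrep("I", rl)
  flag_of <- function(me, other, first) {
    fl <- 1L + if (first) 64L else 128L
    fl <- fl + ifelse(me$mapped, 0L, 4L) + ifelse(other$mapped, 0L, 8L)
    fl <- fl + ifelse(me$mapped & me$strand == "-", 16L, 0L)
    fl <- fl + ifelse(other$mapped & other$strand == "-", 32L, 0L)
    proper <- me$mapped & other$mapped & me$rname == other$rname &
      me$strand != other$strand &
      ifelse(me$strand == "+", me$pos <= other$pos, other$pos <= me$pos)
    fl + ifelse(!is.na(proper) & proper, 2L, 0L)
  }
  fields <- function(me, other, seq_as_sequenced, first) {
    seq_out <- ifelse(me$mapped & me$strand == "-",
                      rc_chr(seq_as_sequenced), seq_as_sequenced)
    rname <- ifelse(me$mapped, me$rname, ifelse(other$mapped, other$rname, "*"))
    pos1 <- ifelse(me$mapped, me$pos + 1L, ifelse(other$mapped, other$pos + 1L, 0L))
    rnext <- ifelse(other$mapped,
                    ifelse(me$mapped & me$rname == other$rname, "=", other$rname),
                    ifelse(me$mapped, "=", "*"))
    pnext <- ifelse(other$mapped, other$pos + 1L, pos1)
    same <- me$mapped & other$mapped & !is.na(me$rname) & !is.na(other$rname) &
      me$rname == other$rname
    lo <- pmin(me$pos, other$pos)
    hi <- pmax(me$pos + cigar_ref_width(me$cigar),
               other$pos + cigar_ref_width(other$cigar))
    tlen <- ifelse(same & !is.na(lo), ifelse(me$pos <= lo, hi - lo, -(hi - lo)), 0L)
    tlen[is.na(tlen)] <- 0L
    paste(pairs$pair_id, flag_of(me, other, first), rname, pos1,
          ifelse(me$mapped, 60L, 0L), me$cigar, rnext, pnext, tlen,
          seq_out, qual, sep = "\t")
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(original), Biostrings::width(original)),
           sprintf("@SQ\tSN:%s\tLN:%d", names(catalog), Biostrings::width(catalog)),
           "@PG\tID:mobsv\tPN:mobsv")
  l1 <- fields(m1, m2, pairs$seq1, TRUE)
  l2 <- fields(m2, m1, pairs$seq2, FALSE)
  writeLines(c(hdr, as.vector(rbind(l1, l2))), sam_path)
}
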