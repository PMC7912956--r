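#' Poisson upper-tail probability
#'
#' `P(K >= k)` for `K ~ Poisson(lam)`, the significance measure used to
#' decide whether a window's count of anchored mates is an unexpected
#' excess over the genomic background. Computed through the survival
#' function, which is numerically stable far into the tail.
#'
#' @param k Observed count (non-negative integer, vectorised).
#' @param lam Expected count under the background model.
#' @return `P(K >= k)`.
#' @examples
#' poisson_upper_tail(0, 3)        # 1
#' poisson_upper_tail(1, log(2))   # 0.5
#' @export
poisson_upper_tail <- function(k, lam) {
  if (any(k < 0) || any(lam < 0)) stopf("k and lam must be non-negative")
  stats::ppois(k - 1, lam, lower.tail = FALSE)
}

# One row per anchored mate: the genomic mate of an IS_ANCHORED or
# MATE_UNMAPPED pair. A forward anchored mate supports a breakpoint to its
# right ("left" flank of the insertion); a reverse one, to its left.
anchored_mates <- function(pairs, classes) {
  sel_a <- classes == "IS_ANCHORED"
  sel_u <- classes == "MATE_UNMAPPED"
  take <- function(sel, anchored_is_r1, target) {
    idx <- which(sel & anchored_is_r1)
    jdx <- which(sel & !anchored_is_r1)
    rbind(
      data.frame(replicon = pairs$r1_ref[idx], pos = pairs$r1_start[idx],
                 strand = pairs$r1_strand[idx],
                 target = target[idx], stringsAsFactors = FALSE),
      data.frame(replicon = pairs$r2_ref[jdx], pos = pairs$r2_start[jdx],
                 strand = pairs$r2_strand[jdx],
                 target = target[jdx], stringsAsFactors = FALSE))
  }
  a <- take(sel_a, !pairs$r1_on_catalog,
            ifelse(pairs$r1_on_catalog, pairs$r1_ref, pairs$r2_ref))
  u <- take(sel_u, pairs$r1_mapped, rep(NA_character_, nrow(pairs)))
  out <- rbind(a, u)
  out$side <- ifelse(out$strand == "+", "left", "right")
  out[order(out$replicon, out$pos), , drop = FALSE]
}

#' Scan the genome for windows with an unexpected excess of anchored mates
#'
#' Anchored-mate positions (from `IS_ANCHORED` and `MATE_UNMAPPED` pairs)
#' are binned into sliding windows per replicon and flank side. Each
#' window's support is tested against a Poisson background whose rate is
#' the replicon-wide anchored-mate density times the window size, floored
#' at `lam_min`; windows significant after Bonferroni correction over all
#' windows scanned are merged per side when they overlap.
#'
#' @param pairs Pair records from [read_alignments()].
#' @param classes Factor from [classify_pairs()].
#' @param ref_lengths Named replicon lengths (defaults to the
#'   `ref_lengths` attribute of `pairs`).
#' @param window,step Window size and stride in bases.
#' @param alpha Family-wise error level before Bonferroni division.
#' @param lam_min Floor for the background rate per window, so that empty
#'   replicons cannot produce zero-rate artefacts.
#' @return A `data.frame` of clusters: `replicon`, `start`, `end` (0-based
#'   half-open union window), `side` (`"left"`/`"right"` flank), `support`,
#'   `p_value`, and `mate_targets` (list-column of named counts over IS
#'   catalog targets within the best window).
#' @export
scan_anchor_windows <- function(pairs, classes, ref_lengths = NULL,
                                window = 200L, step = 50L, alpha = 0.01,
                                lam_min = 0.05) {
  ref_lengths <- ref_lengths %||% attr(pairs, "ref_lengths")
  if (is.null(ref_lengths)) stopf("ref_lengths must be supplied")
  am <- anchored_mates(pairs, classes)
  empty <- data.frame(replicon = character(0), start = integer(0),
                      end = integer(0), side = character(0),
                      support = integer(0), p_value = numeric(0))
  empty$mate_targets <- list()
  if (nrow(am) == 0L) return(empty)

  n_windows <- sum(vapply(ref_lengths, function(L)
    length(seq.int(0L, max(0L, L - window), by = step)), numeric(1))) * 2
  thresh <- alpha / n_windows
  out <- list()
  for (rep_name in intersect(names(ref_lengths), unique(am$replicon))) {
    L <- ref_lengths[[rep_name]]
    rate <- sum(am$replicon == rep_name) / L
    lam <- max(lam_min, window * rate)
    ws <- seq.int(0L, max(0L, L - window), by = step)
    wr <- IRanges::IRanges(start = ws + 1L, width = window)
    for (side in c("left", "right")) {
      a <- am[am$replicon == rep_name & am$side == side, , drop = FALSE]
      if (nrow(a) == 0L) next
      cnt <- IRanges::countOverlaps(wr, IRanges::IRanges(a$pos + 1L, width = 1L))
      p <- poisson_upper_tail(cnt, lam)
      sig <- which(p <= thresh & cnt > 0L)
      if (length(sig) == 0L) next
      merged <- IRanges::reduce(wr[sig])
      hit <- IRanges::findOverlaps(wr[sig], merged)
      for (m in seq_along(merged)) {
        members <- sig[S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == m]]
        best <- members[which.max(cnt[members])]
        in_best <- a$pos >= ws[best] & a$pos < ws[best] + window
        tg <- a$target[in_best]
        tg <- tg[!is.na(tg)]
        out[[length(out) + 1L]] <- data.frame(
          replicon = rep_name,
          start = IRanges::start(merged)[m] - 1L,
          end = IRanges::end(merged)[m],
          side = side, support = max(cnt[members]),
          p_value = min(p[members]), stringsAsFactors = FALSE)
        out[[length(out)]]$mate_targets <-
          list(if (length(tg)) table(tg) else integer(0))
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$replicon, res$start), , drop = FALSE]
}

#' Pair flanking anchor clusters into insertion calls
#'
#' A left-flank cluster is paired with the nearest right-flank cluster
#' starting within `max_gap` bases downstream; the breakpoint is the
#' interval between the innermost window edges (a single base when the
#' windows overlap). The inserted element is the majority vote over the
#' pooled mate-target histograms, `"ambiguous"` on a tie or when no mate
#' carries target information. Significant clusters left unpaired are
#' emitted as single-sided calls when their support reaches
#' `2 * min_support`.
#'
#' @param clusters Output of [scan_anchor_windows()].
#' @param max_gap Maximum distance between the left cluster's end and the
#'   right cluster's start; use about `insert_mean + 3 * insert_sd`.
#' @param min_support Minimum total supporting mates per call.
#' @return A `data.frame`: `replicon`, `bp_start`, `bp_end` (0-based
#'   half-open breakpoint interval), `element`, `support_left`,
#'   `support_right`, `p_value` (max of the flank p-values), sorted by
#'   position.
#' @export
call_insertions <- function(clusters, max_gap = 390L, min_support = 4L) {
  empty <- data.frame(replicon = character(0), bp_start = integer(0),
                      bp_end = integer(0), element = character(0),
                      support_left = integer(0), support_right = integer(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  if (is.null(clusters) || nrow(clusters) == 0L) return(empty)
  calls <- list()
  for (rep_name in unique(clusters$replicon)) {
    cl <- clusters[clusters$replicon == rep_name, , drop = FALSE]
    lefts <- cl[cl$side == "left", , drop = FALSE]
    rights <- cl[cl$side == "right", , drop = FALSE]
    used_r <- logical(nrow(rights))
    used_l <- logical(nrow(lefts))
    for (i in seq_len(nrow(lefts))) {
      gap <- rights$start - lefts$end[i]
      cand <- which(!used_r & rights$start >= lefts$start[i] & gap <= max_gap)
      if (length(cand) == 0L) next
      j <- cand[which.min(abs(gap[cand]))]
      used_r[j] <- TRUE
      used_l[i] <- TRUE
      a <- lefts$end[i]; b <- rights$start[j]
      if (b <= a) { m <- (a + b) %/% 2L; a <- m; b <- m + 1L }
      calls[[length(calls) + 1L]] <- data.frame(
        replicon = rep_name, bp_start = a, bp_end = b,
        element = vote_element(c(lefts$mate_targets[[i]],
                                 rights$mate_targets[[j]])),
        support_left = lefts$support[i], support_right = rights$support[j],
        p_value = max(lefts$p_value[i], rights$p_value[j]),
        stringsAsFactors = FALSE)
    }
    single <- function(df, used, is_left) {
      for (i in which(!used)) {
        if (df$support[i] < 2L * min_support) next
        bp <- if (is_left) df$end[i] else df$start[i]
        calls[[length(calls) + 1L]] <<- data.frame(
          replicon = rep_name, bp_start = bp, bp_end = bp + 1L,
          element = vote_element(df$mate_targets[[i]]),
          support_left = if (is_left) df$support[i] else 0L,
          support_right = if (is_left) 0L else df$support[i],
          p_value = df$p_value[i], stringsAsFactors = FALSE)
      }
    }
    single(lefts, used_l, TRUE)
    single(rights, used_r, FALSE)
  }
  if (length(calls) == 0L) return(empty)
  res <- do.call(rbind, calls)
  res <- res[res$support_left + res$support_right >= min_support, , drop = FALSE]
  res[order(res$replicon, res$bp_start), , drop = FALSE]
}

# Majority vote over pooled mate-target counts; "ambiguous" on tie or when
# no anchored mate mapped into a catalog element.
vote_element <- function(counts) {
  if (length(counts) == 0L) return("ambiguous")
  tot <- tapply(as.integer(counts), names(counts), sum)
  tot <- sort(tot, decreasing = TRUE)
  if (length(tot) > 1L && tot[1] == tot[2]) return("ambiguous")
  names(tot)[1]
}
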