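#' Collect insert-stretched pairs, grouped by replicon
#'
#' Returns exactly the `STRETCHED` records with their inner interval: the
#' half-open span between the leftmost mate's end and the rightmost mate's
#' start, which must contain any deletion the pair bridges.
#'
#' @param pairs Pair records from [read_alignments()].
#' @param classes Factor from [classify_pairs()].
#' @return A `data.frame` sorted by (replicon, leftmost position):
#'   `replicon`, `inner_start`, `inner_end`, `insert_size`, `pair_id`.
#' @export
collect_stretched_pairs <- function(pairs, classes) {
  sel <- which(classes == "STRETCHED")
  if (length(sel) == 0L)
    return(data.frame(replicon = character(0), inner_start = integer(0),
                      inner_end = integer(0), insert_size = integer(0),
                      pair_id = character(0), stringsAsFactors = FALSE))
  p <- pairs[sel, , drop = FALSE]
  left_is_r1 <- p$r1_start <= p$r2_start
  inner_start <- ifelse(left_is_r1, p$r1_end, p$r2_end)
  inner_end <- ifelse(left_is_r1, p$r2_start, p$r1_start)
  out <- data.frame(replicon = p$r1_ref,
                    inner_start = pmin(inner_start, inner_end),
                    inner_end = pmax(inner_start, inner_end),
                    insert_size = p$insert_size, pair_id = p$pair_id,
                    stringsAsFactors = FALSE)
  out[order(out$replicon, out$inner_start), , drop = FALSE]
}

#' Call large deletions from clusters of stretched pairs
#'
#' Stretched pairs whose inner intervals overlap or lie within
#' `cluster_gap` bases are single-linkage clustered per replicon. Each
#' cluster's interval is the intersection of its pairs' inner intervals
#' (their bounding interval when the intersection is empty) and its size
#' estimate is the median insert-size excess over the library median,
#' minus a fragment length-bias correction: pairs are recruited with
#' probability proportional to their inner span, which inflates the median
#' bridging fragment by about `sigma^2 / (median - 2 * read_len)` bases.
#' Calls smaller than `min_event_size` (200 bp by default: the pipeline
#' targets *large* events, leaving smaller indels to point-mutation
#' callers) or with fewer than `min_support` pairs are suppressed.
#'
#' @param stretched Output of [collect_stretched_pairs()].
#' @param model The [estimate_insert_model()] fit.
#' @param ref_lengths Named replicon lengths for the background rate.
#' @param min_event_size Minimum estimated deletion size in bases.
#' @param min_support Minimum supporting pairs per call.
#' @param cluster_gap Single-linkage gap in bases; defaults to the model
#'   sigma.
#' @param lam_min Floor for the Poisson background rate.
#' @return A `data.frame`: `replicon`, `start`, `end` (0-based half-open),
#'   `est_size`, `support`, `p_value`.
#' @export
call_deletions <- function(stretched, model, ref_lengths,
                           min_event_size = 200L, min_support = 4L,
                           cluster_gap = NULL, lam_min = 0.05) {
  stopifnot(inherits(model, "insert_size_model"))
  cluster_gap <- cluster_gap %||% max(1, round(model$sigma))
  empty <- data.frame(replicon = character(0), start = integer(0),
                      end = integer(0), est_size = numeric(0),
                      support = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(stretched) == 0L) return(empty)
  inner_mean <- max(model$median - 2 * model$read_len, model$sigma, 1)
  bias <- model$sigma^2 / inner_mean
  calls <- list()
  for (rep_name in unique(stretched$replicon)) {
    s <- stretched[stretched$replicon == rep_name, , drop = FALSE]
    s <- s[order(s$inner_start), , drop = FALSE]
    # single-linkage: a new cluster opens when the next inner interval
    # starts beyond the running max end plus the gap
    grp <- cumsum(c(1L, as.integer(
      s$inner_start[-1L] > cummax(s$inner_end[-nrow(s)]) + cluster_gap)))
    rate <- nrow(s) / ref_lengths[[rep_name]]
    for (g in unique(grp)) {
      cl <- s[grp == g, , drop = FALSE]
      iv_start <- max(cl$inner_start)
      iv_end <- min(cl$inner_end)
      if (iv_end <= iv_start) {  # empty intersection: fall back to bounds
        iv_start <- min(cl$inner_start)
        iv_end <- max(cl$inner_end)
      }
      span <- max(cl$inner_end) - min(cl$inner_start)
      lam <- max(lam_min, rate * span)
      calls[[length(calls) + 1L]] <- data.frame(
        replicon = rep_name, start = iv_start, end = iv_end,
        est_size = stats::median(cl$insert_size) - model$median - bias,
        support = nrow(cl),
        p_value = poisson_upper_tail(nrow(cl), lam),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, calls)
  res <- res[res$est_size > min_event_size & res$support >= min_support, ,
             drop = FALSE]
  res[order(res$replicon, res$start), , drop = FALSE]
}
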