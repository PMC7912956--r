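#' Read paired alignments from a SAM/BAM file into pair records
#'
#' Parses an alignment stream (via [Rsamtools]) and collapses it to one
#' record per query name carrying both mates. The outer insert size is
#' defined only when both mates map to the same non-catalog replicon in
#' head-to-head orientation (leftmost mate forward, rightmost reverse), and
#' is computed as `max(end) - min(start)` over the two mates (0-based
#' half-open, so this equals the outer fragment span).
#'
#' @param path SAM (plain text) or BAM file.
#' @param catalog_names Character vector of IS catalog reference names;
#'   reference entries in this set are treated as mobile-element targets,
#'   not genomic replicons. Defaults to names read from `catalog_fasta`.
#' @param catalog_fasta Optional FASTA whose headers define `catalog_names`.
#' @return A `data.frame` with one row per pair: per-mate columns
#'   (`r1_ref`, `r1_start`, `r1_end`, `r1_strand`, `r1_mapped`, `r1_mapq`,
#'   `r1_on_catalog`, same for `r2`) plus `insert_size` (`NA` when
#'   undefined). Attributes `ref_lengths` (named, catalog entries excluded)
#'   and `catalog_names` carry the reference geometry for the callers.
#' @export
read_alignments <- function(path, catalog_names = NULL, catalog_fasta = NULL) {
  if (is.null(catalog_names) && !is.null(catalog_fasta))
    catalog_names <- names(Biostrings::readDNAStringSet(catalog_fasta))
  catalog_names <- catalog_names %||% character(0)
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  is_sam <- !grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  } else path
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
  b <- Rsamtools::scanBam(bam, param = prm)[[1]]
  if (is_sam) unlink(bam)
  fl <- b$flag
  reads <- data.frame(
    qname = b$qname,
    first = bitwAnd(fl, 64L) > 0L,
    mapped = bitwAnd(fl, 4L) == 0L,
    ref = as.character(b$rname),
    start = ifelse(is.na(b$pos), NA_integer_, b$pos - 1L),
    strand = ifelse(bitwAnd(fl, 16L) > 0L, "-", "+"),
    mapq = ifelse(is.na(b$mapq) | b$mapq == 255L, 0L, b$mapq),
    secondary = bitwAnd(fl, 256L) > 0L | bitwAnd(fl, 2048L) > 0L,
    stringsAsFactors = FALSE)
  reads$end <- reads$start + cigar_ref_width(b$cigar)
  reads$ref[!reads$mapped] <- NA_character_
  reads$start[!reads$mapped] <- NA_integer_
  reads$end[!reads$mapped] <- NA_integer_
  if (any(reads$secondary)) {
    warning("dropping secondary/supplementary alignments; keeping primary only")
    reads <- reads[!reads$secondary, , drop = FALSE]
  }
  dup <- duplicated(paste(reads$qname, reads$first))
  if (any(dup)) {
    warning(sum(dup), " extra alignments per (query, mate) kept as first seen")
    reads <- reads[!dup, , drop = FALSE]
  }

  r1 <- reads[reads$first, , drop = FALSE]
  r2 <- reads[!reads$first, , drop = FALSE]
  ids <- union(r1$qname, r2$qname)
  i1 <- match(ids, r1$qname)
  i2 <- match(ids, r2$qname)
  mate_cols <- function(r, i, prefix) {
    out <- data.frame(
      ref = r$ref[i], start = r$start[i], end = r$end[i],
      strand = r$strand[i], mapped = !is.na(i) & r$mapped[i],
      mapq = ifelse(is.na(i), 0L, r$mapq[i]), stringsAsFactors = FALSE)
    out$on_catalog <- out$mapped & out$ref %in% catalog_names
    names(out) <- paste0(prefix, "_", names(out))
    out
  }
  pairs <- cbind(data.frame(pair_id = ids, stringsAsFactors = FALSE),
                 mate_cols(r1, i1, "r1"), mate_cols(r2, i2, "r2"))
  pairs$insert_size <- pair_insert_size(pairs)
  ref_lengths <- hdr[setdiff(names(hdr), catalog_names)]
  attr(pairs, "ref_lengths") <- ref_lengths
  attr(pairs, "catalog_names") <- catalog_names
  pairs
}

# Outer insert size where defined: both mates on the same non-catalog
# replicon, head-to-head (leftmost forward, rightmost reverse).
pair_insert_size <- function(pairs) {
  both <- pairs$r1_mapped & pairs$r2_mapped &
    !pairs$r1_on_catalog & !pairs$r2_on_catalog &
    !is.na(pairs$r1_ref) & !is.na(pairs$r2_ref) &
    pairs$r1_ref == pairs$r2_ref
  left_fwd <- ifelse(pairs$r1_start <= pairs$r2_start,
                     pairs$r1_strand == "+" & pairs$r2_strand == "-",
                     pairs$r2_strand == "+" & pairs$r1_strand == "-")
  ok <- both & !is.na(left_fwd) & left_fwd
  ins <- pmax(pairs$r1_end, pairs$r2_end) - pmin(pairs$r1_start, pairs$r2_start)
  ifelse(ok & !is.na(ins) & ins > 0L, ins, NA_integer_)
}

#' Fit a robust insert-size model from concordantly mapped pairs
#'
#' Location is the median and scale the normal-consistent MAD
#' (`1.4826 * MAD`) of the defined insert sizes, after discarding the
#' largest 1% of values (`floor(0.01 * n)` observations). The pre-trim keeps
#' deletion-bridging pairs, whose inserts are inflated by the deletion size,
#' from contaminating the scale estimate. The stretched-pair threshold is
#' `median + k_sd * sigma`.
#'
#' @param pairs Pair records from [read_alignments()].
#' @param k_sd Threshold multiplier for calling a pair stretched.
#' @param min_model_pairs Minimum pairs with a defined insert size.
#' @return An object of class `insert_size_model` with fields `median`,
#'   `sigma`, `n`, `k_sd`, `stretch_threshold`, `read_len`.
#' @export
estimate_insert_model <- function(pairs, k_sd = 5, min_model_pairs = 500L) {
  x <- pairs$insert_size
  x <- x[!is.na(x)]
  if (length(x) < min_model_pairs)
    stopf(paste("only %d pairs with a defined insert size (need >= %d);",
                "supply more alignments or lower min_model_pairs"),
          length(x), min_model_pairs)
  drop_n <- floor(0.01 * length(x))
  if (drop_n > 0L) x <- sort(x)[seq_len(length(x) - drop_n)]
  med <- stats::median(x)
  sigma <- stats::mad(x, center = med)   # 1.4826 * MAD
  rl <- stats::median(c(pairs$r1_end - pairs$r1_start,
                        pairs$r2_end - pairs$r2_start), na.rm = TRUE)
  structure(list(median = med, sigma = sigma, n = length(x), k_sd = k_sd,
                 stretch_threshold = med + k_sd * sigma,
                 read_len = as.integer(rl)),
            class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat(sprintf(
    "Insert-size model: median %.1f, sigma %.2f (robust), n = %d\n",
    x$median, x$sigma, x$n))
  cat(sprintf("Stretched-pair threshold: %.1f (median + %g sigma)\n",
              x$stretch_threshold, x$k_sd))
  invisible(x)
}

#' Classify read pairs into structural-variant evidence classes
#'
#' Classes, evaluated in order so that they are mutually exclusive:
#' `IS_ANCHORED` (one mate on a genomic replicon, the other on an IS catalog
#' entry), `MATE_UNMAPPED` (one mate mapped on a genomic replicon, the other
#' unmapped), `STRETCHED` (defined insert size above the model threshold),
#' `CONCORDANT` (defined insert size at or below the threshold), `OTHER`
#' (interchromosomal, inverted, both unmapped, both on catalog, or low
#' mapping quality). `IS_ANCHORED` and `MATE_UNMAPPED` jointly operationalize
#' the "unpaired read" insertion signal; a mate dying at an IS junction
#' either fails to map or maps into an existing IS copy.
#'
#' @param pairs Pair records from [read_alignments()].
#' @param model An [estimate_insert_model()] fit.
#' @param min_mapq Pairs whose mapped mates include one with mapping quality
#'   below this are demoted to `OTHER`.
#' @return A factor with levels `IS_ANCHORED`, `MATE_UNMAPPED`, `STRETCHED`,
#'   `CONCORDANT`, `OTHER`, one per row of `pairs`.
#' @export
classify_pairs <- function(pairs, model, min_mapq = 20L) {
  stopifnot(inherits(model, "insert_size_model"))
  low_mapq <- (pairs$r1_mapped & pairs$r1_mapq < min_mapq) |
    (pairs$r2_mapped & pairs$r2_mapq < min_mapq)
  is_anch <- (pairs$r1_mapped & pairs$r2_mapped) &
    xor(pairs$r1_on_catalog, pairs$r2_on_catalog)
  unm <- xor(pairs$r1_mapped, pairs$r2_mapped) &
    ((pairs$r1_mapped & !pairs$r1_on_catalog) |
       (pairs$r2_mapped & !pairs$r2_on_catalog))
  stretched <- !is.na(pairs$insert_size) &
    pairs$insert_size > model$stretch_threshold
  concord <- !is.na(pairs$insert_size) &
    pairs$insert_size <= model$stretch_threshold
  cls <- rep("OTHER", nrow(pairs))
  cls[concord] <- "CONCORDANT"
  cls[stretched] <- "STRETCHED"
  cls[unm] <- "MATE_UNMAPPED"
  cls[is_anch] <- "IS_ANCHORED"
  cls[low_mapq] <- "OTHER"
  factor(cls, levels = c("IS_ANCHORED", "MATE_UNMAPPED", "STRETCHED",
                         "CONCORDANT", "OTHER"))
}
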