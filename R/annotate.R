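#' Read gene annotations from GFF3 or tabular TSV
#'
#' Accepts either GFF3 (gene/CDS features carrying `locus_tag` and
#' `product` attributes, parsed with [rtracklayer::import]) or a 6-column
#' headerless TSV (`replicon`, `start`, `end`, `strand`, `locus_tag`,
#' `product`; 1-based inclusive coordinates). Both are converted to the
#' package's internal 0-based half-open convention.
#'
#' @param path Annotation file; format inferred from the extension
#'   (`.gff`/`.gff3` vs anything else) unless `format` is given.
#' @param format `"gff3"`, `"tsv"`, or `"auto"`.
#' @return A `data.frame`: `replicon`, `start`, `end` (0-based half-open),
#'   `strand`, `locus_tag`, `product`.
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type %in% c("gene", "CDS")]
    tags <- as.character(gr$locus_tag %||% rep(NA_character_, length(gr)))
    if (any(is.na(tags) | !nzchar(tags)))
      stopf("feature(s) %s lack a locus_tag attribute",
            paste(which(is.na(tags) | !nzchar(tags)), collapse = ", "))
    prod <- if ("product" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$product) else rep("", length(gr))
    prod[is.na(prod)] <- ""
    feats <- data.frame(replicon = as.character(GenomeInfoDb::seqnames(gr)),
                        start = BiocGenerics::start(gr) - 1L,
                        end = BiocGenerics::end(gr),
                        strand = as.character(BiocGenerics::strand(gr)),
                        locus_tag = tags, product = prod,
                        stringsAsFactors = FALSE)
  } else {
    txt <- readLines(path)
    txt <- txt[!grepl("^\\s*(#|$)", txt)]
    raw <- if (length(txt))
      utils::read.delim(text = txt, header = FALSE, stringsAsFactors = FALSE,
                        quote = "") else data.frame()
    if (nrow(raw) == 0L)
      return(data.frame(replicon = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        locus_tag = character(0), product = character(0),
                        stringsAsFactors = FALSE))
    if (ncol(raw) < 6L)
      stopf("TSV annotations need 6 columns: replicon, start, end, strand, locus_tag, product")
    bad <- which(is.na(raw[[5]]) | !nzchar(raw[[5]]))
    if (length(bad))
      stopf("line(s) %s lack a locus_tag", paste(bad, collapse = ", "))
    feats <- data.frame(replicon = as.character(raw[[1]]),
                        start = as.integer(raw[[2]]) - 1L,
                        end = as.integer(raw[[3]]),
                        strand = as.character(raw[[4]]),
                        locus_tag = as.character(raw[[5]]),
                        product = as.character(raw[[6]]),
                        stringsAsFactors = FALSE)
  }
  dup <- duplicated(feats$locus_tag)
  if (any(dup))
    stopf("duplicated locus_tag(s): %s",
          paste(unique(feats$locus_tag[dup]), collapse = ", "))
  feats[order(feats$replicon, feats$start), , drop = FALSE]
}

#' Annotate structural-variant calls with gene features
#'
#' Insertion calls are assigned the gene whose interval contains the
#' breakpoint midpoint (ties broken by larger overlap with the breakpoint
#' interval, then lexicographic locus_tag); calls hitting no gene are
#' reported as `intergenic(upstream|downstream)`. Deletions list every
#' overlapped gene, `;`-joined. One report row per call.
#'
#' @param insertions Calls from [call_insertions()].
#' @param deletions Calls from [call_deletions()].
#' @param features Gene table from [read_annotations()].
#' @return A `data.frame` (rows sorted by gene label): `gene`, `protein`,
#'   `inserted_element`, `replicon`, `coord_start`, `coord_end` (1-based
#'   inclusive), `support`, `p_value`.
#' @export
annotate_calls <- function(insertions, deletions, features) {
  call_reps <- unique(c(insertions$replicon, deletions$replicon))
  unmatched <- setdiff(call_reps, unique(features$replicon))
  if (length(unmatched) && nrow(features) > 0L)
    stopf("call replicon(s) absent from annotations: %s",
          paste(unmatched, collapse = ", "))
  rows <- list()
  for (i in seq_len(NROW(insertions))) {
    ins <- insertions[i, ]
    hit <- locate_gene(features, ins$replicon, ins$bp_start, ins$bp_end)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = hit$gene, protein = hit$protein,
      inserted_element = ins$element, replicon = ins$replicon,
      coord_start = ins$bp_start + 1L, coord_end = ins$bp_end,
      support = ins$support_left + ins$support_right,
      p_value = ins$p_value, stringsAsFactors = FALSE)
  }
  for (i in seq_len(NROW(deletions))) {
    del <- deletions[i, ]
    f <- features[features$replicon == del$replicon &
                    features$start < del$end & features$end > del$start, ,
                  drop = FALSE]
    if (nrow(f) > 0L) {
      f <- f[order(f$start), , drop = FALSE]
      gene <- paste(f$locus_tag, collapse = ";")
      protein <- paste(f$product, collapse = ";")
    } else {
      hit <- locate_gene(features, del$replicon, del$start, del$end)
      gene <- hit$gene; protein <- hit$protein
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, protein = protein,
      inserted_element = sprintf("deletion(%d)", round(del$est_size)),
      replicon = del$replicon, coord_start = del$start + 1L,
      coord_end = del$end, support = del$support, p_value = del$p_value,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(0), protein = character(0),
                      inserted_element = character(0), replicon = character(0),
                      coord_start = integer(0), coord_end = integer(0),
                      support = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res[order(res$gene, res$replicon, res$coord_start), , drop = FALSE]
}

# Midpoint-containment gene assignment with overlap/lexicographic
# tie-breaks; intergenic fallback names the flanking tags ("-" at ends).
locate_gene <- function(features, replicon, start, end) {
  mid <- (start + end) %/% 2L
  f <- features[features$replicon == replicon, , drop = FALSE]
  hit <- f[f$start <= mid & mid < f$end, , drop = FALSE]
  if (nrow(hit) >= 1L) {
    ov <- pmin(hit$end, end) - pmax(hit$start, start)
    hit <- hit[order(-ov, hit$locus_tag), , drop = FALSE]
    return(list(gene = hit$locus_tag[1], protein = hit$product[1]))
  }
  up <- f[f$end <= mid, , drop = FALSE]
  dn <- f[f$start > mid, , drop = FALSE]
  up_tag <- if (nrow(up)) up$locus_tag[which.max(up$end)] else "-"
  dn_tag <- if (nrow(dn)) dn$locus_tag[which.min(dn$start)] else "-"
  list(gene = sprintf("intergenic(%s|%s)", up_tag, dn_tag), protein = "")
}
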