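#' Suppress insertion calls that fall inside called deletions
#'
#' Reads straddling a deletion edge fail to map just as reads straddling an
#' IS junction do, so an unreconciled caller would report a spurious,
#' element-less insertion at each deletion breakpoint. An insertion call
#' whose breakpoint midpoint lies within `margin` bases of a deletion
#' interval is therefore dropped.
#'
#' @param insertions Calls from [call_insertions()].
#' @param deletions Calls from [call_deletions()].
#' @param margin Guard band in bases, typically the library insert median.
#' @return `insertions` with conflicting rows removed.
#' @export
filter_insertions_near_deletions <- function(insertions, deletions,
                                             margin = 300L) {
  if (NROW(insertions) == 0L || NROW(deletions) == 0L) return(insertions)
  mid <- (insertions$bp_start + insertions$bp_end) %/% 2L
  drop <- vapply(seq_len(nrow(insertions)), function(i) {
    d <- deletions[deletions$replicon == insertions$replicon[i], , drop = FALSE]
    any(mid[i] >= d$start - margin & mid[i] < d$end + margin)
  }, logical(1))
  insertions[!drop, , drop = FALSE]
}

write_calls_tsv <- function(insertions, deletions, report, outdir) {
  fmt_p <- function(p) sprintf("%.6g", p)
  ins <- data.frame(replicon = insertions$replicon,
                    bp_start = insertions$bp_start + 1L,
                    bp_end = insertions$bp_end,
                    element = insertions$element,
                    support_left = insertions$support_left,
                    support_right = insertions$support_right,
                    p_value = fmt_p(insertions$p_value))
  del <- data.frame(replicon = deletions$replicon,
                    start = deletions$start + 1L, end = deletions$end,
                    est_size = round(deletions$est_size),
                    support = deletions$support,
                    p_value = fmt_p(deletions$p_value))
  rep_out <- report
  rep_out$p_value <- fmt_p(report$p_value)
  paths <- list(insertions = file.path(outdir, "insertions.tsv"),
                deletions = file.path(outdir, "deletions.tsv"),
                report = file.path(outdir, "report.tsv"))
  utils::write.table(ins, paths$insertions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(del, paths$deletions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(rep_out, paths$report, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Read a plain-text pipeline configuration file
#'
#' `key: value` lines (YAML-subset); parsed with the `yaml` package when
#' available, otherwise with a minimal scalar parser. Values are
#' type-converted where unambiguous.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (requireNamespace("yaml", quietly = TRUE))
    return(yaml::read_yaml(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3L) next
    v <- trimws(m[3])
    vn <- suppressWarnings(as.numeric(v))
    out[[trimws(m[2])]] <- if (!is.na(vn)) vn else v
  }
  out
}

#' Run the full detection pipeline
#'
#' Executes read parsing, insert-size model fitting, pair classification,
#' insertion and deletion calling, reconciliation, and gene annotation,
#' writing `insertions.tsv`, `deletions.tsv`, `report.tsv` and `run.log`
#' to `outdir`. Inputs are either a simulation scenario (`scenario`) or
#' real files (`sam` + `catalog` + `annotations`). All coordinates in the
#' output files are 1-based inclusive. Identical configuration and inputs
#' yield byte-identical outputs.
#'
#' @param config A named list (or path to a [read_config()] file) with any
#'   of: `scenario`, `seed`, `coverage`, `read_len`, `insert_mean`,
#'   `insert_sd`, `error_rate` (simulation); `sam`, `catalog`,
#'   `annotations` (file inputs); `outdir`; and tuning parameters `k_sd`,
#'   `min_mapq`, `min_model_pairs`, `window`, `step`, `alpha`, `lam_min`,
#'   `min_support`, `max_gap`, `min_event_size`, `cluster_gap`. Unset keys
#'   take the documented defaults of the stage functions.
#' @return Invisibly, a list: `report`, `insertions`, `deletions`, `model`,
#'   `class_counts`, `paths`, and (for scenarios) `truth`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  cfgv <- function(key, default) config[[key]] %||% default
  outdir <- cfgv("outdir", tempfile("mobsv_run_"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  cat("", file = log_path)  # truncate any previous run's log
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  seed <- as.integer(cfgv("seed", 17L))
  truth <- NULL
  if (!is.null(config$scenario)) {
    cfg <- sim_config(coverage = cfgv("coverage", 50),
                      read_len = cfgv("read_len", 100L),
                      insert_mean = cfgv("insert_mean", 300),
                      insert_sd = cfgv("insert_sd", 30),
                      error_rate = cfgv("error_rate", 0.002),
                      seed = seed)
    logf("simulating scenario '%s' (seed %d, coverage %gx, read_len %d, insert %g+/-%g, error %g)",
         config$scenario, seed, cfg$coverage, cfg$read_len, cfg$insert_mean,
         cfg$insert_sd, cfg$error_rate)
    sim <- simulate_scenario(config$scenario, cfg,
                             outdir = file.path(outdir, "sim"))
    sam <- sim$paths$sam
    catalog_names <- names(sim$scenario$catalog)
    annotations <- sim$paths$annotations
    truth <- sim$truth
  } else {
    sam <- config$sam %||% stopf("config needs either 'scenario' or 'sam'")
    catalog_names <- if (!is.null(config$catalog))
      names(Biostrings::readDNAStringSet(config$catalog)) else character(0)
    annotations <- config$annotations
    logf("reading alignments from %s", sam)
  }
  pairs <- read_alignments(sam, catalog_names = catalog_names)
  model <- estimate_insert_model(pairs, k_sd = cfgv("k_sd", 5),
                                 min_model_pairs = cfgv("min_model_pairs", 500L))
  logf("insert-size model: median %.1f, sigma %.2f over %d pairs; stretch threshold %.1f",
       model$median, model$sigma, model$n, model$stretch_threshold)
  classes <- classify_pairs(pairs, model, min_mapq = cfgv("min_mapq", 20L))
  cc <- table(classes)
  logf("pair classes: %s", paste(names(cc), as.integer(cc), collapse = ", "))
  clusters <- scan_anchor_windows(pairs, classes,
                                  window = cfgv("window", 200L),
                                  step = cfgv("step", 50L),
                                  alpha = cfgv("alpha", 0.01),
                                  lam_min = cfgv("lam_min", 0.05))
  max_gap <- cfgv("max_gap", round(model$median + 3 * model$sigma))
  min_support <- cfgv("min_support", 4L)
  insertions <- call_insertions(clusters, max_gap = max_gap,
                                min_support = min_support)
  stretched <- collect_stretched_pairs(pairs, classes)
  # size filtering is applied only to *reported* deletions; reconciliation
  # below uses every stretched-pair cluster, so that sub-cutoff deletions
  # cannot masquerade as element-less insertion calls at their junctions
  deletions_any <- call_deletions(stretched, model,
                                  ref_lengths = attr(pairs, "ref_lengths"),
                                  min_event_size = 0L,
                                  min_support = min_support,
                                  cluster_gap = config$cluster_gap,
                                  lam_min = cfgv("lam_min", 0.05))
  deletions <- deletions_any[
    deletions_any$est_size > cfgv("min_event_size", 200L), , drop = FALSE]
  n_before <- nrow(insertions)
  insertions <- filter_insertions_near_deletions(insertions, deletions_any,
                                                 margin = round(model$median))
  if (nrow(insertions) < n_before)
    logf("dropped %d insertion call(s) at deletion breakpoints",
         n_before - nrow(insertions))
  logf("calls: %d insertion(s), %d deletion(s)", nrow(insertions),
       nrow(deletions))
  features <- if (!is.null(annotations)) read_annotations(annotations) else
    data.frame(replicon = character(0), start = integer(0), end = integer(0),
               strand = character(0), locus_tag = character(0),
               product = character(0), stringsAsFactors = FALSE)
  report <- annotate_calls(insertions, deletions, features)
  paths <- write_calls_tsv(insertions, deletions, report, outdir)
  paths$log <- log_path
  logf("report: %d row(s) written to %s", nrow(report), paths$report)
  invisible(list(report = report, insertions = insertions,
                 deletions = deletions, model = model,
                 class_counts = cc, n_pairs = nrow(pairs),
                 paths = paths, truth = truth, outdir = outdir))
}
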