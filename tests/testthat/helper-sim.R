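# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small (tens of kb, a few thousand pairs) so each stage
# still sees realistic coverage.

tiny_catalog <- function(seed = 2L) {
  generate_is_catalog(c("IS1088", "ISRme5", "ISRme15"),
                      c(1050L, 1200L, 1500L), seed = seed)
}

# Run the simulation chain through the SAM round trip and the classifier.
# Returns the stage outputs most tests need.
sim_stage <- function(genome, events, catalog, cfg,
                      clip_mode = "unmapped", min_anchor = 20L,
                      fit_model = TRUE) {
  planted <- plant_events(genome, events, catalog)
  rp <- simulate_read_pairs(planted$genome, cfg)
  sam <- tempfile(fileext = ".sam")
  project_ideal_alignments(rp, genome, catalog, planted$truth, sam,
                           min_anchor = min_anchor, clip_mode = clip_mode)
  pairs <- read_alignments(sam, catalog_names = names(catalog))
  out <- list(truth = planted$truth, mutated = planted$genome,
              sim_pairs = rp, sam = sam, pairs = pairs)
  if (fit_model) {
    out$model <- estimate_insert_model(pairs)
    out$classes <- classify_pairs(pairs, out$model)
  }
  out
}

# Random event set on a single-replicon genome: n_ins insertions and n_del
# deletions (>= 300 bp), spaced at least 2 * insert_mean apart, each inside
# its own synthetic gene so gene-level truth matching is exact.
rand_scenario <- function(seed, len = 100000L, n_ins = NULL, n_del = NULL,
                          spacing = 600L) {
  set.seed(seed)
  n_ins <- n_ins %||% sample(3:10, 1)
  n_del <- n_del %||% sample(0:3, 1)
  genome <- generate_genome(len, gc = 0.61, seed = seed, names = "chr")
  catalog <- tiny_catalog(seed + 1L)
  n_ev <- n_ins + n_del
  # event anchor positions with guaranteed spacing
  repeat {
    pos <- sort(sample(seq(4000L, len - 4000L), n_ev))
    if (n_ev < 2L || min(diff(pos)) > spacing + 2400L) break
  }
  kind <- sample(c(rep("insertion", n_ins), rep("deletion", n_del)))
  del_len <- sample(300:1200, n_ev, replace = TRUE)
  events <- truth_events(
    kind = kind, replicon = "chr", start = pos,
    end = ifelse(kind == "deletion", pos + del_len, pos),
    element = ifelse(kind == "insertion",
                     sample(names(catalog), n_ev, replace = TRUE), NA),
    strand = ifelse(kind == "insertion", sample(c("+", "-"), n_ev, TRUE), NA))
  features <- data.frame(
    replicon = "chr", start = pos - 500L,
    end = ifelse(kind == "deletion", pos + del_len + 500L, pos + 500L),
    strand = "+", locus_tag = sprintf("synth_%04d", seq_len(n_ev)),
    product = sprintf("synthetic fixture gene %d", seq_len(n_ev)),
    stringsAsFactors = FALSE)
  list(name = "random", genome = genome, catalog = catalog, events = events,
       features = features)
}

# The headline scenario is expensive enough to share across test files.
.cache <- new.env(parent = emptyenv())
cached_table4 <- function() {
  if (is.null(.cache$table4)) {
    outdir <- file.path(tempdir(), "mobsv_table4")
    .cache$table4 <- suppressMessages(
      run_pipeline(list(scenario = "table4", seed = 17L, outdir = outdir)))
  }
  .cache$table4
}

# Size-estimate errors for a planted 1-kb deletion across 20 seeds; shared
# between the deletion-caller unit test and the acceptance suite.
cached_del_errors <- function() {
  if (is.null(.cache$del_errs)) {
    .cache$del_errs <- vapply(1:20, function(seed) {
      g <- generate_genome(40000L, gc = 0.61, seed = 300L + 2L * seed,
                           names = "chr")
      ev <- truth_events("deletion", "chr", 20000L, end = 21000L)
      st <- sim_stage(g, ev, tiny_catalog(),
                      sim_config(coverage = 50, seed = 301L + 2L * seed))
      sp <- collect_stretched_pairs(st$pairs, st$classes)
      calls <- call_deletions(sp, st$model, attr(st$pairs, "ref_lengths"))
      stopifnot(nrow(calls) == 1L)
      calls$est_size - 1000
    }, numeric(1))
  }
  .cache$del_errs
}

# Expected (gene, element) pairs for the table4 scenario, derived from the
# truth events and the scenario's own annotation table.
table4_truth_pairs <- function() {
  sc <- mobsv_scenario("table4", seed = 17L)
  ev <- sc$events
  f <- sc$features
  gene <- vapply(seq_len(nrow(ev)), function(i) {
    g <- f[f$replicon == ev$replicon[i] & f$start <= ev$start[i] &
             ev$start[i] < f$end, ]
    g$locus_tag[1]
  }, character(1))
  sort(paste(gene, ev$element, sep = "|"))
}
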