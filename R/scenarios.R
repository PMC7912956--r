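#' Built-in simulation scenarios
#'
#' Bundled study-condition generators. `"table4"` re-enacts a zinc-adapted
#' *Cupriavidus metallidurans* CH34-style resequencing experiment on a
#' scaled-down four-replicon genome (~400 kb; proportions mimicking
#' chromosome, chromid and the pMOL28/pMOL30 megaplasmids): seven IS
#' insertions are planted inside genes carrying the locus_tags and products
#' of the adaptation experiment's mutation table, with elements IS1088 (5
#' copies), ISRme15 and ISRme5. `"null"` is the same genome with no events;
#' `"size_rule"` plants one 150-base and one 500-base deletion on a single
#' replicon, bracketing the 200-bp reporting cutoff.
#'
#' Fixture coordinates are synthetic stand-ins: the original study reports
#' no genomic coordinates for its insertions, only gene identities.
#'
#' @param name Scenario name.
#' @param seed Integer seed for genome and catalog construction.
#' @return A list: `genome`, `catalog`, `events`, `features` (annotation
#'   `data.frame`), `name`.
#' @export
mobsv_scenario <- function(name = c("table4", "null", "size_rule"),
                           seed = 17L) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  if (name %in% c("table4", "null")) {
    genome <- generate_genome(c(200000L, 130000L, 30000L, 40000L), gc = 0.61,
                              seed = seed,
                              names = c("chromosome", "chromid", "pMOL28", "pMOL30"))
    catalog <- generate_is_catalog(c("IS1088", "ISRme5", "ISRme15"),
                                   c(1050L, 1200L, 1500L), seed = seed + 1L)
    features <- table4_features()
    events <- if (name == "table4") table4_events() else
      truth_events(character(0), character(0), integer(0))
  } else {
    genome <- generate_genome(80000L, gc = 0.61, seed = seed,
                              names = "chromosome")
    catalog <- generate_is_catalog(c("IS1088", "ISRme5", "ISRme15"),
                                   c(1050L, 1200L, 1500L), seed = seed + 1L)
    features <- data.frame(
      replicon = "chromosome",
      start = c(19500L, 49500L), end = c(21000L, 51500L),
      strand = c("+", "+"),
      locus_tag = c("synth_0001", "synth_0002"),
      product = c("synthetic fixture gene A", "synthetic fixture gene B"),
      stringsAsFactors = FALSE)
    events <- truth_events(kind = c("deletion", "deletion"),
                           replicon = "chromosome",
                           start = c(20000L, 50000L),
                           end = c(20150L, 50500L))
  }
  list(name = name, genome = genome, catalog = catalog, events = events,
       features = features)
}

# The seven disrupted loci (locus_tag, product, inserted element) plus
# undisrupted neighbours; coordinates are fixture choices on the synthetic
# replicons, spaced far beyond the fragment length so calls cannot merge.
table4_loci <- function() {
  data.frame(
    replicon = c(rep("chromosome", 3), rep("chromid", 4)),
    locus_tag = c("Rmet_2146", "Rmet_2171", "Rmet_2235",
                  "Rmet_4452", "Rmet_4521", "Rmet_4574", "Rmet_5200"),
    product = c("ABC superfamily transporter subunit",
                "Conserved hypothetical protein",
                "DNA-binding transcriptional repressor",
                "Response regulator receiver domain protein (CheY-like)",
                "Transcriptional regulator",
                "Acyl-CoA dehydrogenase protein",
                "Putative glyoxalase/bleomycin resistance protein/dihydroxy-biphenyl dioxygenase"),
    element = c("IS1088", "ISRme15", "IS1088", "IS1088", "ISRme5",
                "IS1088", "IS1088"),
    start = c(30000L, 75000L, 120000L, 25000L, 60000L, 95000L, 118000L),
    end = c(31200L, 76000L, 120800L, 25700L, 61000L, 96200L, 118900L),
    strand = c("+", "+", "-", "+", "-", "+", "+"),
    stringsAsFactors = FALSE)
}

table4_features <- function() {
  loci <- table4_loci()
  extra <- data.frame(
    replicon = c("chromosome", "chromosome", "chromid", "pMOL28", "pMOL30"),
    start = c(28000L, 116500L, 119500L, 12000L, 18000L),
    end = c(29000L, 117800L, 120400L, 13200L, 19100L),
    strand = c("+", "-", "+", "+", "-"),
    locus_tag = c("Rmet_2145", "Rmet_2229", "Rmet_5201", "Rmet_6205",
                  "Rmet_5890"),
    product = c("Conserved hypothetical protein",
                "ABC-type transporter, periplasmic component",
                "Conserved hypothetical protein",
                "CzcD-family cation transporter",
                "Heavy-metal efflux outer membrane protein"),
    stringsAsFactors = FALSE)
  f <- rbind(loci[, c("replicon", "start", "end", "strand", "locus_tag",
                      "product")], extra)
  f[order(f$replicon, f$start), , drop = FALSE]
}

table4_events <- function() {
  loci <- table4_loci()
  mid <- (loci$start + loci$end) %/% 2L
  truth_events(kind = "insertion", replicon = loci$replicon, start = mid,
               element = loci$element, strand = loci$strand)
}

#' Simulate a scenario and materialise its files
#'
#' Runs the full synthetic-data chain for a scenario: genome and catalog
#' construction, event planting, read-pair simulation, ideal alignment
#' projection, and file output (reference/mutated/catalog FASTA, SAM,
#' truth JSON, annotation TSV, optionally FASTQ).
#'
#' @param scenario A [mobsv_scenario()] list (or a scenario name).
#' @param cfg A [sim_config()]; its `seed` drives the read simulation.
#' @param outdir Output directory, created if missing.
#' @param write_reads Also write `reads_1.fastq`/`reads_2.fastq`.
#' @param min_anchor,clip_mode Passed to [project_ideal_alignments()].
#' @return A list with the in-memory objects (`scenario`, `mutated`,
#'   `truth`, `pairs`) and a `paths` list of every file written.
#' @export
simulate_scenario <- function(scenario, cfg = sim_config(), outdir = tempfile("mobsv_"),
                              write_reads = FALSE, min_anchor = 20L,
                              clip_mode = "unmapped") {
  if (is.character(scenario)) scenario <- mobsv_scenario(scenario, seed = cfg$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  planted <- plant_events(scenario$genome, scenario$events, scenario$catalog)
  pairs <- simulate_read_pairs(planted$genome, cfg)
  paths <- list(ref = file.path(outdir, "reference.fasta"),
                mutated = file.path(outdir, "mutated.fasta"),
                catalog = file.path(outdir, "catalog.fasta"),
                sam = file.path(outdir, "alignments.sam"),
                truth = file.path(outdir, "truth.json"),
                annotations = file.path(outdir, "annotations.tsv"))
  Biostrings::writeXStringSet(scenario$genome, paths$ref)
  Biostrings::writeXStringSet(planted$genome, paths$mutated)
  Biostrings::writeXStringSet(scenario$catalog, paths$catalog)
  project_ideal_alignments(pairs, scenario$genome, scenario$catalog,
                           planted$truth, paths$sam, min_anchor = min_anchor,
                           clip_mode = clip_mode)
  jsonlite::write_json(planted$truth, paths$truth, dataframe = "rows",
                       na = "null")
  feats <- scenario$features
  utils::write.table(
    data.frame(feats$replicon, feats$start + 1L, feats$end, feats$strand,
               feats$locus_tag, feats$product),
    paths$annotations, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  if (write_reads)
    paths$fastq <- write_fastq(pairs, file.path(outdir, "reads"))
  list(scenario = scenario, mutated = planted$genome, truth = planted$truth,
       pairs = pairs, paths = paths, outdir = outdir)
}
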