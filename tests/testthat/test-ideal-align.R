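# Hand-constructed fragments with known mutated-frame coordinates, pushed
# through the lift-over aligner and read back through the SAM parser.

make_pairs <- function(mut, replicon, fs, fl, rl = 100L) {
  sq <- as.character(mut[[replicon]])
  data.frame(pair_id = sprintf("hand%03d", seq_along(fs)),
             replicon = replicon, frag_start = as.integer(fs),
             frag_len = as.integer(fl),
             seq1 = substring(sq, fs + 1L, fs + rl),
             seq2 = as.character(Biostrings::reverseComplement(
               Biostrings::DNAStringSet(
                 substring(sq, fs + fl - rl + 1L, fs + fl)))),
             stringsAsFactors = FALSE)
}

ins_fixture <- function() {
  g <- generate_genome(10000L, gc = 0.5, seed = 3L, names = "chr")
  cat1 <- generate_is_catalog("IS1088", 1050L, tsd_len = 8L, seed = 4L)
  ev <- truth_events("insertion", "chr", 6000L, element = "IS1088", strand = "+")
  planted <- plant_events(g, ev, cat1)
  list(g = g, cat = cat1, truth = planted$truth, mut = planted$genome)
}

test_that("pairs in unchanged sequence map as proper pairs with insert = fragment", {
  fx <- ins_fixture()
  rp <- make_pairs(fx$mut, "chr", fs = c(1000L, 2500L), fl = c(300L, 320L))
  sam <- tempfile(fileext = ".sam")
  project_ideal_alignments(rp, fx$g, fx$cat, fx$truth, sam)
  pr <- read_alignments(sam, catalog_names = "IS1088")
  expect_equal(nrow(pr), 2L)
  expect_true(all(pr$r1_mapped & pr$r2_mapped))
  expect_equal(sort(pr$insert_size), c(300L, 320L))
  expect_equal(sort(pr$r1_start), c(1000L, 2500L))
})

test_that("a mate inside an inserted element maps to the catalog entry", {
  fx <- ins_fixture()
  # element occupies mutated [6008, 7058); mate2 of this fragment sits at
  # mutated [6208, 6308), i.e. 200 bases into IS1088
  rp <- make_pairs(fx$mut, "chr", fs = 5858L, fl = 450L)
  sam <- tempfile(fileext = ".sam")
  project_ideal_alignments(rp, fx$g, fx$cat, fx$truth, sam)
  pr <- read_alignments(sam, catalog_names = "IS1088")
  expect_true(pr$r1_mapped && pr$r2_mapped)
  expect_identical(pr$r2_ref, "IS1088")
  expect_true(pr$r2_on_catalog)
  expect_equal(pr$r2_start, 200L)
  expect_true(is.na(pr$insert_size))
})

test_that("pairs bridging a deletion report insert inflated by the deletion size", {
  g <- generate_genome(10000L, gc = 0.5, seed = 3L, names = "chr")
  cat1 <- generate_is_catalog("IS1088", 1050L, seed = 4L)
  ev <- truth_events("deletion", "chr", 4000L, end = 5000L)
  planted <- plant_events(g, ev, cat1)
  # mutated coordinate 4000 is the deletion point; fragment [3850, 4150)
  rp <- make_pairs(planted$genome, "chr", fs = 3850L, fl = 300L)
  sam <- tempfile(fileext = ".sam")
  project_ideal_alignments(rp, g, cat1, planted$truth, sam)
  pr <- read_alignments(sam, catalog_names = "IS1088")
  expect_true(pr$r1_mapped && pr$r2_mapped)
  expect_equal(pr$r1_start, 3850L)
  expect_equal(pr$r2_start, 5050L)   # lifted across the deleted kilobase
  expect_equal(pr$insert_size, 1300L)
})

test_that("junction-straddling mates are unmapped by default, clipped on request", {
  fx <- ins_fixture()
  # mate1 spans the left IS junction at mutated 6008 with 58 bases of flank
  rp <- make_pairs(fx$mut, "chr", fs = 5950L, fl = 400L)
  sam <- tempfile(fileext = ".sam")
  project_ideal_alignments(rp, fx$g, fx$cat, fx$truth, sam)
  pr <- read_alignments(sam, catalog_names = "IS1088")
  expect_false(pr$r1_mapped)
  expect_true(pr$r2_mapped)

  sam2 <- tempfile(fileext = ".sam")
  project_ideal_alignments(rp, fx$g, fx$cat, fx$truth, sam2,
                           clip_mode = "softclip", min_anchor = 20L)
  pr2 <- read_alignments(sam2, catalog_names = "IS1088")
  expect_true(pr2$r1_mapped)
  expect_equal(pr2$r1_start, 5950L)
  expect_equal(pr2$r1_end - pr2$r1_start, 58L)  # clipped to the anchor
})

test_that("round trip: every mapped mate's SEQ matches its reference at its coordinates", {
  g <- generate_genome(c(15000L, 12000L), gc = 0.55, seed = 5L,
                       names = c("chrA", "chrB"))
  cat3 <- tiny_catalog()
  ev <- truth_events(c("insertion", "deletion", "insertion"),
                     c("chrA", "chrA", "chrB"),
                     start = c(5000L, 9000L, 6000L),
                     end = c(5000L, 9600L, 6000L),
                     element = c("IS1088", NA, "ISRme5"),
                     strand = c("+", NA, "-"))
  planted <- plant_events(g, ev, cat3)
  rp <- simulate_read_pairs(planted$genome,
                            sim_config(coverage = 20, error_rate = 0, seed = 6L))
  sam <- tempfile(fileext = ".sam")
  project_ideal_alignments(rp, g, cat3, planted$truth, sam, min_anchor = 1L)
  refs <- c(as.character(g), as.character(cat3))
  lines <- readLines(sam)
  lines <- lines[!startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_checked <- 0L
  for (f in fields) {
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next
    pos <- as.integer(f[4])
    expect_identical(f[6], "100M")
    expect_identical(f[10], substr(refs[[f[3]]], pos, pos + 99L))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 1000L)
  # and both-mapped pairs straddle no junction, so their count is conserved
  pr <- read_alignments(sam, catalog_names = names(cat3))
  expect_equal(nrow(pr), nrow(rp))
})

test_that("identical seeds give byte-identical SAM output", {
  fx <- ins_fixture()
  cfg <- sim_config(coverage = 10, seed = 8L)
  sams <- replicate(2, {
    rp <- simulate_read_pairs(fx$mut, cfg)
    sam <- tempfile(fileext = ".sam")
    project_ideal_alignments(rp, fx$g, fx$cat, fx$truth, sam)
    sam
  })
  expect_identical(readLines(sams[1]), readLines(sams[2]))
})

test_that("realized depth over an unchanged window matches the coverage setting", {
  g <- generate_genome(20000L, gc = 0.5, seed = 12L, names = "chr")
  cfg <- sim_config(coverage = 40, seed = 13L)
  rp <- simulate_read_pairs(g, cfg)
  win <- c(5000L, 15000L)
  # per-mate overlap with the window, clamped at zero
  ov1 <- pmax(0L, pmin(rp$frag_start + 100L, win[2]) - pmax(rp$frag_start, win[1]))
  ov2 <- pmax(0L, pmin(rp$frag_start + rp$frag_len, win[2]) -
                pmax(rp$frag_start + rp$frag_len - 100L, win[1]))
  depth <- sum(ov1 + ov2) / diff(win)
  expect_lt(abs(depth - 40) / 40, 0.1)
})
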