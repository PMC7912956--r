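# A minimal hand-written SAM stream exercising the parser's corner cases.
hand_sam <- function() {
  path <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr\tLN:10000",
    "@SQ\tSN:IS1088\tLN:1050",
    # proper pair at 0-based 99 and 299 (1-based 100/300), insert 300
    paste("p1", 99, "chr", 100, 60, "100M", "=", 300, 300,
          strrep("A", 100), strrep("I", 100), sep = "\t"),
    paste("p1", 147, "chr", 300, 60, "100M", "=", 100, -300,
          strrep("A", 100), strrep("I", 100), sep = "\t"),
    # mate 2 unmapped
    paste("p2", 73, "chr", 500, 60, "100M", "=", 500, 0,
          strrep("C", 100), strrep("I", 100), sep = "\t"),
    paste("p2", 133, "chr", 500, 0, "*", "=", 500, 0,
          strrep("C", 100), strrep("I", 100), sep = "\t"),
    # mate 2 on the IS catalog entry
    paste("p3", 97, "chr", 700, 60, "100M", "IS1088", 10, 0,
          strrep("G", 100), strrep("I", 100), sep = "\t"),
    paste("p3", 145, "IS1088", 10, 60, "100M", "chr", 700, 0,
          strrep("G", 100), strrep("I", 100), sep = "\t")),
    path)
  path
}

test_that("SAM parsing pairs mates and computes outer insert sizes", {
  pr <- read_alignments(hand_sam(), catalog_names = "IS1088")
  pr <- pr[order(pr$pair_id), ]
  expect_equal(pr$pair_id, c("p1", "p2", "p3"))
  expect_equal(pr$insert_size, c(300L, NA, NA))
  expect_equal(pr$r1_start[1], 99L)      # 1-based file, 0-based internal
  expect_false(pr$r2_mapped[2])
  expect_true(pr$r2_on_catalog[3])
  expect_equal(attr(pr, "ref_lengths"), c(chr = 10000L))
  expect_error(read_alignments(tempfile()), "not found")
})

test_that("the insert-size model matches hand-computed location and scale", {
  mk <- function(x) data.frame(insert_size = x,
                               r1_end = 100L, r1_start = 0L,
                               r2_end = 100L, r2_start = 0L)
  m <- estimate_insert_model(mk(rep(300L, 600)))
  expect_equal(m$median, 300)
  expect_equal(m$sigma, 0)
  expect_equal(m$stretch_threshold, 300)
  m2 <- estimate_insert_model(mk(c(290L, 300L, 310L)), min_model_pairs = 3L)
  expect_equal(m2$median, 300)
  expect_equal(m2$sigma, 14.826)
  expect_error(estimate_insert_model(mk(rep(300L, 10))), "min_model_pairs")
})

test_that("the top-1% pre-trim shields the scale from deletion-bridging pairs", {
  set.seed(1)
  x <- as.integer(c(round(rnorm(5000, 300, 30)), rep(1300L, 40)))
  pr <- data.frame(insert_size = x, r1_end = 100L, r1_start = 0L,
                   r2_end = 100L, r2_start = 0L)
  m <- estimate_insert_model(pr)
  expect_lt(abs(m$median - 300), 3)
  expect_lt(abs(m$sigma - 30), 3)
})

test_that("model recovery on simulated data is within stated tolerances", {
  g <- generate_genome(40000L, gc = 0.61, seed = 2L, names = "chr")
  st <- sim_stage(g, truth_events(character(0), character(0), integer(0)),
                  tiny_catalog(), sim_config(coverage = 50, seed = 31L),
                  fit_model = FALSE)
  expect_equal(nrow(st$pairs), 10000L)
  m <- estimate_insert_model(st$pairs)
  expect_lt(abs(m$median - 300) / 300, 0.01)
  expect_lt(abs(m$sigma - 30) / 30, 0.10)
})

fake_pair <- function(r1_ref = "chr", r2_ref = "chr", r1_start = 0L,
                      r2_start = 200L, r1_strand = "+", r2_strand = "-",
                      r1_mapped = TRUE, r2_mapped = TRUE, mapq = 60L,
                      on_cat1 = FALSE, on_cat2 = FALSE) {
  df <- data.frame(pair_id = "x",
                   r1_ref = r1_ref, r1_start = r1_start,
                   r1_end = r1_start + 100L, r1_strand = r1_strand,
                   r1_mapped = r1_mapped, r1_mapq = mapq,
                   r1_on_catalog = on_cat1,
                   r2_ref = r2_ref, r2_start = r2_start,
                   r2_end = r2_start + 100L, r2_strand = r2_strand,
                   r2_mapped = r2_mapped, r2_mapq = mapq,
                   r2_on_catalog = on_cat2, stringsAsFactors = FALSE)
  df$r1_ref[!df$r1_mapped] <- NA; df$r2_ref[!df$r2_mapped] <- NA
  df$r1_start[!df$r1_mapped] <- NA; df$r2_start[!df$r2_mapped] <- NA
  df$r1_end[!df$r1_mapped] <- NA; df$r2_end[!df$r2_mapped] <- NA
  df$insert_size <- mobsv:::pair_insert_size(df)
  df
}

test_that("pair classes follow their definitions and partition the records", {
  model <- structure(list(median = 300, sigma = 18, n = 1000, k_sd = 5,
                          stretch_threshold = 390, read_len = 100L),
                     class = "insert_size_model")
  cases <- rbind(
    fake_pair(),                                           # CONCORDANT (300)
    fake_pair(r2_start = 900L),                            # STRETCHED (1000)
    fake_pair(on_cat2 = TRUE),                             # IS_ANCHORED
    fake_pair(r2_mapped = FALSE),                          # MATE_UNMAPPED
    fake_pair(r2_ref = "chr2"),                            # OTHER: interchrom
    fake_pair(r2_strand = "+"),                            # OTHER: inverted
    fake_pair(mapq = 5L))                                  # OTHER: low mapq
  cls <- classify_pairs(cases, model, min_mapq = 20L)
  expect_equal(as.character(cls),
               c("CONCORDANT", "STRETCHED", "IS_ANCHORED", "MATE_UNMAPPED",
                 "OTHER", "OTHER", "OTHER"))
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), nrow(cases))
})

test_that("a null simulation yields no anchored pairs and a tiny stretched tail", {
  g <- generate_genome(40000L, gc = 0.61, seed = 2L, names = "chr")
  st <- sim_stage(g, truth_events(character(0), character(0), integer(0)),
                  tiny_catalog(),
                  sim_config(coverage = 50, error_rate = 0, seed = 33L),
                  min_anchor = 1L)
  tab <- table(st$classes)
  expect_equal(unname(tab["IS_ANCHORED"]), 0L)
  expect_equal(unname(tab["MATE_UNMAPPED"]), 0L)
  # upper-tail mass beyond median + 5 sigma, plus binomial slack
  p_tail <- pnorm(5, lower.tail = FALSE)
  n <- nrow(st$pairs)
  expect_lte(unname(tab["STRETCHED"]), stats::qbinom(0.999, n, p_tail) + 3)
})
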