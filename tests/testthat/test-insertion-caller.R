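# Independent oracle: direct log-space summation of the Poisson pmf over the
# upper tail, terminated when terms stop contributing.
pois_tail_oracle <- function(k, lam) {
  if (k == 0) return(1)
  if (lam == 0) return(0)
  j <- seq(k, k + 3000L)
  sum(exp(j * log(lam) - lam - lgamma(j + 1)))
}

test_that("poisson_upper_tail matches closed forms and the summation oracle", {
  expect_equal(poisson_upper_tail(0, 5), 1.0)
  expect_equal(poisson_upper_tail(0, 0), 1.0)
  expect_equal(poisson_upper_tail(1, log(2)), 0.5)
  expect_equal(poisson_upper_tail(5, 2.0),
               1 - sum(exp(-2) * 2^(0:4) / factorial(0:4)), tolerance = 1e-14)
  for (lam in c(0.1, 3, 15)) for (k in c(1L, 4L, 20L))
    expect_lt(abs(poisson_upper_tail(k, lam) - pois_tail_oracle(k, lam)), 1e-13)
  expect_error(poisson_upper_tail(-1, 2), "non-negative")
  expect_error(poisson_upper_tail(2, -1), "non-negative")
})

test_that("anchor windows around a planted insertion flank the true breakpoint", {
  g <- generate_genome(20000L, gc = 0.61, seed = 41L, names = "chr")
  ev <- truth_events("insertion", "chr", 10000L, element = "IS1088",
                     strand = "+")
  st <- sim_stage(g, ev, tiny_catalog(), sim_config(coverage = 50, seed = 42L))
  cl <- scan_anchor_windows(st$pairs, st$classes)
  expect_setequal(cl$side, c("left", "right"))
  left <- cl[cl$side == "left", ]
  right <- cl[cl$side == "right", ]
  expect_true(all(left$end <= 10000L + 300L & left$end >= 10000L - 300L))
  expect_true(all(abs(right$start - 10000L) <= 300L))
  expect_true(all(cl$support >= 15L))
  calls <- call_insertions(cl, max_gap = 390L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$element, "IS1088")
  expect_lt(abs((calls$bp_start + calls$bp_end) / 2 - 10000), 300)
})

test_that("a null simulation produces no anchor clusters or calls", {
  g <- generate_genome(20000L, gc = 0.61, seed = 43L, names = "chr")
  st <- sim_stage(g, truth_events(character(0), character(0), integer(0)),
                  tiny_catalog(), sim_config(coverage = 50, seed = 44L))
  cl <- scan_anchor_windows(st$pairs, st$classes)
  expect_equal(nrow(cl), 0L)
  expect_equal(nrow(call_insertions(cl)), 0L)
})

test_that("element assignment votes over mate targets and reports ties as ambiguous", {
  mk_cluster <- function(side, start, end, support, targets) {
    df <- data.frame(replicon = "chr", start = start, end = end, side = side,
                     support = support, p_value = 1e-20,
                     stringsAsFactors = FALSE)
    df$mate_targets <- list(targets)
    df
  }
  cl <- rbind(mk_cluster("left", 900L, 1100L, 20L, c(IS1088 = 9L)),
              mk_cluster("right", 1150L, 1350L, 20L, c(ISRme5 = 9L)))
  expect_equal(call_insertions(cl)$element, "ambiguous")
  cl2 <- rbind(mk_cluster("left", 900L, 1100L, 20L, c(IS1088 = 9L)),
               mk_cluster("right", 1150L, 1350L, 20L, c(IS1088 = 2L, ISRme5 = 1L)))
  call2 <- call_insertions(cl2)
  expect_equal(call2$element, "IS1088")
  expect_equal(call2$bp_start, 1100L)
  expect_equal(call2$bp_end, 1150L)
  # no target information at all
  cl3 <- rbind(mk_cluster("left", 900L, 1100L, 20L, integer(0)),
               mk_cluster("right", 1150L, 1350L, 20L, integer(0)))
  expect_equal(call_insertions(cl3)$element, "ambiguous")
  expect_equal(nrow(call_insertions(NULL)), 0L)
})

test_that("unpaired clusters become single-sided calls only at doubled support", {
  mk <- function(support) {
    df <- data.frame(replicon = "chr", start = 5000L, end = 5200L,
                     side = "left", support = support, p_value = 1e-30,
                     stringsAsFactors = FALSE)
    df$mate_targets <- list(c(IS1088 = support))
    df
  }
  expect_equal(nrow(call_insertions(mk(7L), min_support = 4L)), 0L)
  one <- call_insertions(mk(8L), min_support = 4L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$support_right, 0L)
  expect_equal(one$bp_start, 5200L)
})

test_that("raising min_support never increases the number of calls", {
  g <- generate_genome(30000L, gc = 0.61, seed = 45L, names = "chr")
  ev <- truth_events("insertion", c("chr", "chr"), c(8000L, 20000L),
                     element = c("IS1088", "ISRme15"), strand = c("+", "-"))
  st <- sim_stage(g, ev, tiny_catalog(), sim_config(coverage = 50, seed = 46L))
  cl <- scan_anchor_windows(st$pairs, st$classes)
  counts <- vapply(c(2L, 4L, 8L, 40L, 200L),
                   function(ms) nrow(call_insertions(cl, min_support = ms)),
                   integer(1))
  expect_true(all(diff(counts) <= 0L))
  expect_equal(counts[2], 2L)
})

test_that("well-separated insertions are recovered across many seeds", {
  cat3 <- tiny_catalog()
  hits <- 0L
  for (seed in 1:20) {
    g <- generate_genome(15000L, gc = 0.61, seed = 100L + seed, names = "chr")
    el <- names(cat3)[1L + (seed %% 3L)]
    ev <- truth_events("insertion", "chr", 7500L, element = el,
                       strand = if (seed %% 2L) "+" else "-")
    st <- sim_stage(g, ev, cat3,
                    sim_config(coverage = 30, error_rate = 0.005,
                               seed = 200L + seed))
    calls <- call_insertions(scan_anchor_windows(st$pairs, st$classes))
    ok <- nrow(calls) == 1L && calls$element == el &&
      abs((calls$bp_start + calls$bp_end) / 2 - 7500) <= 300
    hits <- hits + ok
  }
  expect_equal(hits, 20L)
})
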