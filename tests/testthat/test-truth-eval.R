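test_that("reciprocal overlap computes per-interval fractions", {
  expect_equal(unname(reciprocal_overlap(100, 200, 150, 250)[1, ]),
               c(0.5, 0.5))
  expect_equal(unname(reciprocal_overlap(10, 50, 10, 50)[1, ]), c(1, 1))
  ## touching half-open intervals share nothing
  expect_equal(unname(reciprocal_overlap(0, 100, 100, 200)[1, ]), c(0, 0))
  ## different chromosomes never overlap
  expect_equal(unname(reciprocal_overlap(0, 100, 0, 100,
                                         chrom1 = "chr1",
                                         chrom2 = "chr2")[1, ]), c(0, 0))
  expect_error(reciprocal_overlap(10, 10, 0, 5), "positive length")
})

truth_df <- function(start, end, id = paste0("t", seq_along(start)),
                     chrom = "chr1", zyg = "HET") {
  data.frame(chrom = chrom, start = start, end = end, type = "DEL",
             zygosity = zyg, event_id = id, stringsAsFactors = FALSE)
}
calls_df <- function(start, end, id = paste0("c", seq_along(start)),
                     chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, site_id = id,
              stringsAsFactors = FALSE)
}

test_that("match_calls applies the 50% reciprocal criterion inclusively", {
  ## 60-bp overlap over two 100-bp intervals: detected (>= is inclusive)
  m <- match_calls(truth_df(1000, 1100), calls_df(1040, 1140))
  expect_equal(nrow(m), 1L)
  expect_equal(m$frac_truth, 0.6)

  ## exactly 50% on both sides still counts
  m50 <- match_calls(truth_df(100, 200), calls_df(150, 250))
  expect_equal(nrow(m50), 1L)

  ## one-sided overlap of 10% fails
  expect_equal(nrow(match_calls(truth_df(1000, 1100), calls_df(1090, 1500))),
               0L)
})

test_that("one-to-one assignment picks one call per truth event", {
  tr <- truth_df(1000, 1100)
  cl <- calls_df(c(1000, 1010), c(1100, 1110))
  m <- match_calls(tr, cl, one_to_one = TRUE)
  expect_equal(nrow(m), 1L)
  expect_equal(m$call_id, "c1")  # perfect overlap wins
  m_all <- match_calls(tr, cl, one_to_one = FALSE)
  expect_equal(nrow(m_all), 2L)
})

test_that("match_calls agrees with the all-pairs brute-force oracle", {
  set.seed(91)
  for (rep in 1:5) {
    n_t <- sample(5:25, 1); n_c <- sample(5:25, 1)
    t_start <- sample(0:2000, n_t)
    t_len <- sample(20:400, n_t, replace = TRUE)
    c_start <- sample(0:2000, n_c)
    c_len <- sample(20:400, n_c, replace = TRUE)
    tr <- truth_df(t_start, t_start + t_len,
                   chrom = sample(c("chr1", "chr2"), n_t, replace = TRUE))
    cl <- calls_df(c_start, c_start + c_len,
                   chrom = sample(c("chr1", "chr2"), n_c, replace = TRUE))
    got <- match_calls(tr, cl)
    got <- got[order(got$truth_id), c("truth_id", "call_id")]
    want <- bf_match(tr, cl)
    expect_equal(got$truth_id, want$truth_id)
    expect_equal(got$call_id, want$call_id)
  }
})

test_that("matched pair set is symmetric in which set plays truth", {
  set.seed(17)
  a_start <- sample(0:5000, 30); a_len <- sample(50:300, 30, replace = TRUE)
  b_start <- sample(0:5000, 30); b_len <- sample(50:300, 30, replace = TRUE)
  aa <- truth_df(a_start, a_start + a_len, id = paste0("a", 1:30))
  bb <- calls_df(b_start, b_start + b_len, id = paste0("b", 1:30))
  fwd <- match_calls(aa, bb)
  bb_as_truth <- truth_df(b_start, b_start + b_len, id = paste0("b", 1:30))
  aa_as_calls <- calls_df(a_start, a_start + a_len, id = paste0("a", 1:30))
  rev <- match_calls(bb_as_truth, aa_as_calls)
  expect_setequal(paste(fwd$truth_id, fwd$call_id),
                  paste(rev$call_id, rev$truth_id))
})

test_that("raising the reciprocal fraction never detects more events", {
  set.seed(23)
  s <- sample(0:3000, 40); l <- sample(30:500, 40, replace = TRUE)
  tr <- truth_df(s, s + l)
  cs <- sample(0:3000, 40); clen <- sample(30:500, 40, replace = TRUE)
  cl <- calls_df(cs, cs + clen)
  detected <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0), function(fr) {
    length(unique(match_calls(tr, cl, reciprocal_fraction = fr)$truth_id))
  }, numeric(1))
  expect_true(all(diff(detected) <= 0))
})

test_that("sensitivity is detected over true, with NA (not 0) empty cells", {
  tr <- truth_df(c(100, 1000, 2000, 3000), c(200, 1100, 2100, 3100),
                 zyg = c("HET", "HET", "HOM", "HOM"))
  cl <- calls_df(c(100, 1000, 2000), c(200, 1100, 2100))
  m <- match_calls(tr, cl)
  tab <- sensitivity_table(tr, m)
  expect_equal(tab$sensitivity[tab$bin == "all"], 0.75)

  ## all / none detected
  expect_equal(sensitivity_table(tr, match_calls(tr, calls_df(
    tr$start, tr$end)))$sensitivity, 1)
  expect_equal(sensitivity_table(tr, m[0, ])$sensitivity, 0)

  ## a bin with no truth events is undefined, not 0
  bins <- size_bin_scheme(c(50, 500), c(200, 1000))
  tab_b <- sensitivity_table(tr, m, bins = bins)
  expect_true(is.na(tab_b$sensitivity[tab_b$bin == "500-1000"]))
  expect_equal(tab_b$n_true[tab_b$bin == "500-1000"], 0L)

  ## unknown truth ids are an error
  bad <- data.frame(truth_id = "nope", call_id = "c1")
  expect_error(sensitivity_table(tr, bad), "unknown truth id")
})

test_that("pooled sensitivity recomposes exactly from per-bin counts", {
  set.seed(41)
  tr <- generate_spikein_truth(n_del = 400, n_ins = 0, n_inv = 0, n_dup = 0,
                               fail_rate = 0, seed = 8)
  cl <- degrade_truth_to_calls(tr, 0.7, 0.9, seed = 9)
  m <- match_calls(tr, cl)
  bins <- size_bin_scheme(c(2, 1001), c(1000, 5000))
  tab <- sensitivity_table(tr, m, bins = bins)
  per_bin <- tab[tab$bin != "all", ]
  pooled <- tab[tab$bin == "all", ]
  expect_equal(sum(per_bin$n_true), pooled$n_true)
  expect_equal(sum(per_bin$n_detected), pooled$n_detected)
  expect_equal(pooled$sensitivity, pooled$n_detected / pooled$n_true)
})

test_that("estimate_beta splits detection by truth zygosity", {
  ## 10 het truths with 8 detected, 10 hom truths with 9 detected
  start <- seq(0, by = 1000, length.out = 20)
  tr <- truth_df(start, start + 100,
                 zyg = rep(c("HET", "HOM"), each = 10))
  detected_idx <- c(1:8, 11:19)
  cl <- calls_df(start[detected_idx], start[detected_idx] + 100)
  b <- estimate_beta(tr, match_calls(tr, cl))
  expect_equal(b$beta_het, 0.8)
  expect_equal(b$beta_hom, 0.9)

  ## no hom truths in a bin -> undefined cell with count 0
  bins <- size_bin_scheme(c(50, 500), c(200, 1000))
  tr_het <- truth_df(c(100, 1000), c(200, 1100), zyg = "HET")
  b2 <- estimate_beta(tr_het, match_calls(tr_het, calls_df(
    c(100, 1000), c(200, 1100))), bins = bins)
  expect_true(all(is.na(b2$beta_hom[b2$bin != "all"]) |
                  b2$n_hom_true[b2$bin != "all"] == 0))
  expect_equal(b2$beta_het[b2$bin == "all"], 1)
})

test_that("excluded and non-DEL truth events stay out of matching", {
  tr <- data.frame(chrom = "chr1", start = c(100, 300, 500),
                   end = c(200, 400, 600),
                   type = c("DEL", "INS", "DEL"),
                   zygosity = "HET", event_id = c("t1", "t2", "t3"),
                   excluded = c(FALSE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  cl <- calls_df(c(100, 300, 500), c(200, 400, 600))
  m <- match_calls(tr, cl)
  expect_equal(m$truth_id, "t1")
  expect_equal(sensitivity_table(tr, m)$n_true, 1L)
})

test_that("truth lists round trip through TSV", {
  tr <- generate_spikein_truth(n_del = 20, n_ins = 5, n_inv = 5, n_dup = 5,
                               fail_rate = 0.1, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(tr, f)
  back <- read_truth_tsv(f)
  expect_equal(back$event_id, tr$event_id)
  expect_equal(back$start, tr$start)
  expect_equal(back$zygosity, tr$zygosity)
  expect_equal(back$excluded, tr$excluded)
})
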