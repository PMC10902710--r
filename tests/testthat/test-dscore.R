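test_that("overall call rate excludes missing genotypes", {
  expect_equal(overall_call_rate(c(1L, 1L, 2L, rep(0L, 7))), 0.3)
  expect_equal(overall_call_rate(rep(0L, 5)), 0)
  expect_equal(overall_call_rate(c(1L, 1L, rep(0L, 6), NA, NA)), 0.25)
  expect_error(overall_call_rate(c(NA_integer_, NA_integer_)), "missing")
})

test_that("allele-frequency inversion matches the closed form and round-trips", {
  expect_equal(infer_allele_frequency(0.19, 1, 1), 0.1, tolerance = 1e-9)
  expect_equal(infer_allele_frequency(0, 0.5, 0.5), 0)

  ## forward-then-invert across a grid of betas and frequencies
  for (bh in c(0.3, 0.5, 1)) for (bb in c(0.4, 1)) {
    for (q in c(0.01, 0.1, 0.3)) {
      f <- 2 * q * (1 - q) * bh + q^2 * bb
      expect_equal(infer_allele_frequency(f, bh, bb), q, tolerance = 1e-6)
    }
  }

  ## unattainable call rate reports the ceiling
  expect_error(infer_allele_frequency(0.9, 0.5, 0.5), "maximum")
  expect_error(infer_allele_frequency(0.5, 0, 0), "unattainable")
})

test_that("sibling sharing probability has the right limits", {
  ## rare-variant limit: a single het parent transmits w.p. 1/2
  expect_equal(sib_sharing_prob(1e-6, 1, 1), 0.5, tolerance = 1e-5)
  ## fixed variant: every child is HOM_ALT
  expect_equal(sib_sharing_prob(1, 0.3, 0.7), 0.7)
  expect_equal(sib_sharing_prob(1, 1, 0.25), 0.25)
  ## undetectable hets: conditional still defined through hom-alt children
  expect_gt(sib_sharing_prob(1e-6, 0, 1), 0)
  expect_error(sib_sharing_prob(0.5, 0, 0), "undefined")
  expect_error(sib_sharing_prob(0, 1, 1), "undefined")
})

test_that("sibling sharing enumeration matches Monte Carlo on a (q, beta) grid", {
  set.seed(314)
  grid <- expand.grid(q = c(0.02, 0.1, 0.3),
                      bh = c(0.5, 0.9), bb = c(0.7, 1))
  for (r in seq_len(nrow(grid))) {
    exact <- sib_sharing_prob(grid$q[r], grid$bh[r], grid$bb[r])
    mc <- mc_sharing_discrepancy(grid$q[r], grid$bh[r], grid$bb[r], exact,
                                 n_fam = 2e5)
    expect_lt(abs(mc$delta), 3 * mc$se + 1e-12)
  }
})

test_that("observed sibling sharing counts ordered pairs", {
  ped <- toy_ped(1, sibs = 2)
  g <- c(F1_p1 = 0L, F1_p2 = 0L, F1_s1 = 1L, F1_s2 = 1L)
  obs <- observe_sib_sharing(g, ped)
  expect_equal(obs[c("k", "n")], list(k = 2L, n = 2L))
  expect_equal(obs$f_sib_observed, 1)

  g2 <- c(F1_p1 = 0L, F1_p2 = 0L, F1_s1 = 1L, F1_s2 = 0L)
  obs2 <- observe_sib_sharing(g2, ped)
  expect_equal(obs2[c("k", "n")], list(k = 0L, n = 1L))

  ## trio of sibs all called: 3x2 ordered pairs
  ped3 <- toy_ped(1, sibs = 3)
  g3 <- c(F1_p1 = 0L, F1_p2 = 0L, F1_s1 = 1L, F1_s2 = 2L, F1_s3 = 1L)
  obs3 <- observe_sib_sharing(g3, ped3)
  expect_equal(obs3[c("k", "n")], list(k = 6L, n = 6L))

  ## a missing member drops its ordered pairs
  g4 <- c(F1_p1 = 0L, F1_p2 = 0L, F1_s1 = 1L, F1_s2 = NA)
  obs4 <- observe_sib_sharing(g4, ped)
  expect_equal(obs4[c("k", "n")], list(k = 0L, n = 0L))
})

test_that("d_score reproduces the hand-computed binomial ratio", {
  ## P(X1 < 1) = (1-0.5)^2 = 0.25; P(X0 > 1) = 0.05^2 = 0.0025
  sc <- d_score(k = 1, n = 2, f = 0.05, f_sib = 0.5, n_called = 2)
  expect_equal(sc$D, log(100), tolerance = 1e-12)
  expect_equal(sc$status, "scored")
})

test_that("d_score handles degenerate counts and the minimum-call rule", {
  ## k = 0: empty numerator event floored, strongly negative, capped
  sc0 <- d_score(k = 0, n = 3, f = 0.05, f_sib = 0.5, n_called = 2)
  expect_equal(sc0$status, "capped")
  expect_lt(sc0$D, -100)

  expect_equal(d_score(1, 2, 0.05, 0.5, n_called = 1)$status, "too_few_calls")
  expect_equal(d_score(0, 0, 0.05, 0.5, n_called = 5)$status, "no_sib_pairs")
  expect_error(d_score(3, 2, 0.05, 0.5), "exceed")
})

test_that("d_score is nondecreasing in k when f_sib > f", {
  n <- 20
  d <- vapply(0:n, function(k) d_score(k, n, f = 0.05, f_sib = 0.4)$D,
              numeric(1))
  expect_true(all(diff(d) >= 0))
})

test_that("non-strict tails give a bounded score for unshared singletons", {
  sc <- d_score(k = 0, n = 1, f = 0.004, f_sib = 0.5, strict = FALSE)
  expect_equal(sc$status, "scored")
  expect_equal(sc$D, log(0.5), tolerance = 1e-12)
})

test_that("score_callset separates true variants from reproducible artifacts", {
  cfg <- sim_config(n_families = 100, n_sites = 300, q_range = c(0.05, 0.05),
                    beta_het = 0.8, beta_hom = 0.95,
                    fp_locus_fraction = 0.3, fp_locus_call_rate = 0.05)
  co <- simulate_cohort(cfg, seed = 21)
  res <- score_callset(co$observed, co$ped, betas = c(0.8, 0.95))
  tab <- res$table
  lab <- co$labels[tab$site_id]
  d_true <- tab$D[lab == "true_variant" & !is.na(tab$D)]
  d_false <- tab$D[lab == "reproducible_false" & !is.na(tab$D)]
  expect_gt(median(d_true), median(d_false))
  expect_gt(median(d_true), 0)
})

test_that("score_callset statuses and determinism contracts hold", {
  ped <- toy_ped(2, sibs = 2)
  ## identical (k, n, f) triples give identical D
  g <- rbind(rep(c(0L, 0L, 1L, 1L), 2), rep(c(0L, 0L, 1L, 1L), 2))
  cm <- make_cm(g, samples = ped$iid)
  res <- score_callset(cm, ped, betas = c(1, 1))
  expect_equal(res$table$D[1], res$table$D[2])

  ## one called sample -> too_few_calls
  g1 <- rbind(c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))
  res1 <- score_callset(make_cm(g1, samples = ped$iid), ped, betas = c(1, 1))
  expect_equal(res1$table$status, "too_few_calls")

  ## cohort without sib pairs -> every site no_sib_pairs
  ped_nf <- pedigree(data.frame(fid = paste0("F", 1:4),
                                iid = paste0("u", 1:4), pat = NA, mat = NA,
                                sex = 0L, affection = "unknown"))
  g2 <- rbind(c(1L, 1L, 0L, 0L), c(0L, 1L, 1L, 0L))
  res2 <- score_callset(make_cm(g2, samples = ped_nf$iid), ped_nf,
                        betas = c(1, 1))
  expect_true(all(res2$table$status == "no_sib_pairs"))
})

test_that("per-bin beta tables fall back to pooled with a warning", {
  ped <- toy_ped(2, sibs = 2)
  g <- rbind(rep(c(0L, 0L, 1L, 1L), 2))
  cm <- make_cm(g, samples = ped$iid, size = 5000)  # outside validation bins
  beta_tab <- data.frame(bin = c("41-60", "all"),
                         beta_het = c(0.7, 0.9), beta_hom = c(0.8, 0.95))
  expect_warning(
    res <- score_callset(cm, ped, betas = beta_tab, bins = validation_bins()),
    "pooled")
  expect_false(is.na(res$table$D))  # scored (capped is fine: k = n here)
})

test_that("reproducible false calls share at the population rate, true variants above it", {
  cfg <- sim_config(n_families = 300, n_sites = 200, q_range = c(0.1, 0.1),
                    beta_het = 0.9, beta_hom = 0.95,
                    fp_locus_fraction = 0.5, fp_locus_call_rate = 0.1)
  co <- simulate_cohort(cfg, seed = 33)
  res <- score_callset(co$observed, co$ped, betas = c(0.9, 0.95))
  tab <- res$table
  lab <- co$labels[tab$site_id]
  ok <- tab$n > 0 & !is.na(tab$f)
  f_obs_sib <- tab$k / tab$n
  ## E[f_sib_observed] ~ f at artifact sites, ~ f_sib at true sites
  false_sel <- ok & lab == "reproducible_false"
  true_sel <- ok & lab == "true_variant"
  expect_lt(abs(mean(f_obs_sib[false_sel]) - mean(tab$f[false_sel])), 0.02)
  expect_lt(abs(mean(f_obs_sib[true_sel]) - mean(tab$f_sib[true_sel])), 0.02)
})

test_that("dscore_result methods print, summarise and export", {
  co <- simulate_cohort(sim_config(n_families = 20, n_sites = 30), seed = 2)
  res <- score_callset(co$observed, co$ped, betas = c(1, 1),
                       bins = validation_bins())
  expect_output(print(res), "D-score scan")
  expect_output(summary(res), "median_D")
  expect_true("all" %in% res$by_bin$bin)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dscore_tsv(res, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 30L)
})
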