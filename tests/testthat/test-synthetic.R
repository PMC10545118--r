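test_that("binning conserves counts, normalizes mass and keeps boundary scores", {
  g <- opinion_grid2d(20, 20)

  # a single record lands in its cell with total mass one
  ds <- sentiment_dataset(t = 0, w_plus = 0.5, w_minus = 0.5)
  f <- bin_to_density(ds, g)
  expect_equal(f$mass, 1)
  expect_equal(f$values[11, 11], 1 / g$cell_area)
  expect_equal(sum(f$values > 0), 1L)

  # a score of exactly 1 goes to the last cell, not out of range
  ds1 <- sentiment_dataset(t = 0, w_plus = 1, w_minus = 0)
  f1 <- bin_to_density(ds1, g)
  expect_equal(f1$values[20, 1], 1 / g$cell_area)

  # counts are conserved exactly for a generated corpus
  ds2 <- generate_synthetic_dataset(stationary_truth(pos_mix(), neg_mix()),
                                    500, seed = 4)
  f2 <- bin_to_density(ds2, g)
  expect_equal(f2$n_records, 500L)
  expect_equal(sum(f2$values) * g$cell_area, 1, tolerance = 1e-12)

  # empty window: zero field, not NaN
  f0 <- bin_to_density(ds2, g, window = c(500, 600))
  expect_equal(f0$mass, 0)
  expect_false(anyNA(f0$values))
})

test_that("marginalization conserves mass and reproduces raw sample means", {
  g <- opinion_grid2d(20, 20)
  ds <- generate_synthetic_dataset(stationary_truth(pos_mix(), neg_mix()),
                                   2000, seed = 11)
  f <- bin_to_density(ds, g)
  m <- empirical_marginals(f)
  expect_equal(sum(m$plus$values) * g$plus$dw, 1, tolerance = 1e-12)
  expect_equal(sum(m$minus$values) * g$minus$dw, 1, tolerance = 1e-12)
  # binned means agree with raw averages to within one cell width
  expect_lt(abs(m$m_plus - mean(ds$w_plus)), g$plus$dw)
  expect_lt(abs(m$m_minus - mean(ds$w_minus)), g$minus$dw)
  # point mass marginals are point masses
  p <- bin_to_density(sentiment_dataset(0, 0.33, 0.77), g)
  pm <- empirical_marginals(p)
  expect_equal(sum(pm$plus$values > 0), 1L)
  expect_equal(sum(pm$minus$values > 0), 1L)
  expect_error(empirical_marginals(bin_to_density(
    sentiment_dataset(t_span = c(0, 1)), g)), "zero mass")
})

test_that("generator is reproducible, handles edge cases, rejects bad mixtures", {
  tr <- stationary_truth(pos_mix(), neg_mix())
  a <- generate_synthetic_dataset(tr, 100, seed = 7)
  b <- generate_synthetic_dataset(tr, 100, seed = 7)
  expect_identical(a, b)
  c2 <- generate_synthetic_dataset(tr, 100, seed = 8)
  expect_false(identical(a$w_plus, c2$w_plus))

  e <- generate_synthetic_dataset(tr, 0, seed = 1)
  expect_s3_class(e, "sentiment_dataset")
  expect_equal(nrow(e), 0L)

  expect_error(beta_mixture_spec(1.2, beta_spec(0.3, 0.2),
                                 beta_spec(0.6, 0.2)), "weight")
  expect_error(generate_synthetic_dataset(tr, 10), "seed")
})

test_that("sampled scores follow the analytic mixture law (KS at the 1% level)", {
  n <- 1e5
  ds <- generate_synthetic_dataset(stationary_truth(pos_mix(), neg_mix()),
                                   n, seed = 2024)
  ks <- suppressWarnings(
    stats::ks.test(ds$w_minus, function(q) mixture_cdf(neg_mix(), q)))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(n))
})

test_that("a drifting truth interpolates between its endpoint densities", {
  tr <- drifting_truth(
    initial = list(plus = beta_spec(0.3, 0.05), minus = beta_spec(0.3, 0.05)),
    final = list(plus = beta_spec(0.3, 0.05), minus = neg_mix()))
  mid <- tr$at(0.5)$minus
  expect_equal(mid$weight_S, (1 + neg_mix()$weight_S) / 2)
  ds <- generate_synthetic_dataset(tr, 4000, seed = 5)
  early <- ds$w_minus[ds$t < 40]
  late <- ds$w_minus[ds$t > 150]
  # the community drifts negative: late mean above early mean
  expect_gt(mean(late), mean(early))
})

test_that("csv round trip is the identity and strict mode names bad rows", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  ds <- generate_synthetic_dataset(stationary_truth(pos_mix(), neg_mix()),
                                   50, seed = 3)
  write_sentiment_csv(ds, tmp)
  back <- read_sentiment_csv(tmp)
  expect_equal(back$t, ds$t)
  expect_equal(back$w_plus, ds$w_plus)
  expect_equal(back$w_minus, ds$w_minus)
  expect_equal(back$group, ds$group)

  writeLines(c("t,w_plus,w_minus", "0,0.1,0.2", "1,1.2,0.3", "2,0.5,0.5"),
             tmp)
  expect_error(read_sentiment_csv(tmp), "row\\(s\\) 2")
  lax <- suppressWarnings(read_sentiment_csv(tmp, strict = FALSE))
  expect_equal(nrow(lax), 2L)
  writeLines(c("time,pos,neg", "0,0.1,0.2"), tmp)
  d2 <- read_sentiment_csv(tmp, columns = c(t = "time", w_plus = "pos",
                                            w_minus = "neg", group = NA))
  expect_equal(d2$w_minus, 0.2)
  expect_error(read_sentiment_csv(tmp), "missing columns")
})

test_that("binned densities are statistically faithful to the truth", {
  # uniform truth: every cell within 5 Monte-Carlo standard errors of 1
  n <- 1e6
  tr <- stationary_truth(beta_spec(0.5, 0.5), beta_spec(0.5, 0.5)) # Beta(1,1)
  ds <- generate_synthetic_dataset(tr, n, seed = 314)
  g <- opinion_grid2d(20, 20)
  f <- bin_to_density(ds, g)
  p <- g$cell_area
  se <- sqrt(p * (1 - p) / n) / p
  expect_true(all(abs(f$values - 1) < 5 * se))

  # mixture truth: binned moments match analytic moments within 3 SE
  ds2 <- generate_synthetic_dataset(stationary_truth(pos_mix(), neg_mix()),
                                    1e5, seed = 99)
  f2 <- bin_to_density(ds2, g)
  m2 <- empirical_marginals(f2)
  th <- mixture_moments(neg_mix())
  se_mean <- sqrt(th$var / 1e5)
  # allow the O(dw) cell-center binning bias on top of sampling noise
  expect_lt(abs(m2$m_minus - th$mean), 3 * se_mean + g$minus$dw / 2)
})
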