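grid <- diel_grid()
t <- grid$time

test_that("detrending removes exactly the least-squares line", {
  d <- detrend(2 * t + 1, grid)
  expect_equal(d$alpha, 2, tolerance = 1e-12)
  expect_equal(d$beta, 1, tolerance = 1e-12)
  expect_equal(d$detrended, rep(0, 24), tolerance = 1e-12)

  y <- cos(2 * pi * t / 24)           # orthogonal to constant + linear here
  d2 <- detrend(y, grid)
  expect_equal(d2$alpha, 0, tolerance = 1e-12)
  expect_equal(d2$beta, 0, tolerance = 1e-12)
  expect_equal(d2$detrended, y, tolerance = 1e-12)

  d3 <- detrend(rep(3.2, 24), grid)
  expect_equal(d3$alpha, 0, tolerance = 1e-12)
  expect_equal(d3$beta, 3.2, tolerance = 1e-12)
  # refit on residuals is flat
  d4 <- detrend(d2$detrended, grid)
  expect_lt(abs(d4$alpha) + abs(d4$beta), 1e-9)
})

test_that("cosine projection recovers exact harmonics on the uniform grid", {
  y <- cos(2 * pi * t / 24)
  f <- fit_cosine(y, grid, 24)
  expect_equal(f$a, 1, tolerance = 1e-12)
  expect_equal(f$b, 0, tolerance = 1e-12)
  expect_equal(f$phi, 0, tolerance = 1e-12)
  expect_equal(f$amplitude, 2, tolerance = 1e-12)
  expect_equal(f$ef, 0, tolerance = 1e-12)
  expect_equal(f$peak_time, 0, tolerance = 1e-12)

  f12 <- fit_cosine(y, grid, 12)      # orthogonal harmonic: all power residual
  expect_equal(f12$a, 0, tolerance = 1e-12)
  expect_equal(f12$b, 0, tolerance = 1e-12)
  expect_equal(f12$ef, 0.5, tolerance = 1e-12)

  f0 <- fit_cosine(rep(0, 24), grid, 17.3)
  expect_equal(f0$amplitude, 0)
  expect_equal(f0$ef, 0)
})

test_that("best_fit equals an independent exhaustive scan on random series", {
  set.seed(101)
  for (k in 1:25) {
    gp <- rnorm(24)
    got <- best_fit(gp, grid)
    want <- naive_best_fit(gp, t, period_grid())
    expect_equal(got$period, want$period)
    expect_lt(abs(got$ef - want$ef), 1e-12)
  }
})

test_that("best_fit lands on the grid period nearest an off-grid truth", {
  # the operation takes an already-detrended series; feed the pure cosine
  y <- cos(2 * pi * t / 23.65)
  bf <- best_fit(y, grid)
  expect_identical(bf$period, naive_best_fit(y, t, period_grid())$period)
  expect_true(bf$period %in% c(23.6, 23.7))
  y24 <- cos(2 * pi * t / 24)
  expect_equal(best_fit(y24, grid)$period, 24)
  expect_lt(best_fit(y24, grid)$ef, 1e-12)   # zero up to double-precision cancellation
})

test_that("best-fit Ef is bounded by the zero-amplitude model", {
  set.seed(55)
  for (k in 1:20) {
    gp <- detrend(rnorm(24), grid)$detrended
    expect_lte(best_fit(gp, grid)$ef, mean(gp^2) + 1e-12)
  }
})

test_that("peak/trough t test separates antiphase groups and honours conventions", {
  # peak at t = 3 h (D3), trough at L3: strongly separated values
  set.seed(7)
  fit <- data.frame(period = 24, phi = 2 * pi * 3 / 24)
  g <- rep(0, 24)
  g[grid$label %in% c("D1", "D3", "D5")] <- 1 + rnorm(6, 0, 1e-4)
  g[grid$label %in% c("L1", "L3", "L5")] <- -1 + rnorm(6, 0, 1e-4)
  expect_lt(peak_trough_test(g, fit, grid), 1e-6)

  # equal group means with within-group spread: t ~ 0
  g2 <- rep(0, 24)
  g2[grid$label %in% c("D1", "D3", "D5")] <- c(0.9, 1.0, 1.1, 0.9, 1.0, 1.1)
  g2[grid$label %in% c("L1", "L3", "L5")] <- c(1.1, 1.0, 0.9, 1.1, 1.0, 0.9)
  expect_gt(peak_trough_test(g2, fit, grid), 0.99)

  # both groups constant: p = 1 by convention
  expect_equal(peak_trough_test(rep(0.5, 24), fit, grid), 1)
})

test_that("classification calls a clean cosine cyclic with the right peak label", {
  spec <- synthetic_spec(n_genes = 12, fraction_cyclic = 1, period_range = 24,
                         amplitude_range = 2, acrophase_range = 2 * pi * 13 / 24,
                         trend_slope_range = 0, intercept_range = 0,
                         noise_sd = 0.001, seed = 2)
  sim <- generate_expression(spec, grid)   # peaks at t = 13 h -> label L1
  calls <- classify_rhythms(feature_scale(sim$matrix), grid)
  expect_true(all(calls$is_cyclic))
  expect_true(all(calls$peak_label == "L1"))
  expect_true(all(abs(calls$period - 24) <= 0.1))
  expect_true(all(calls$crit_period & calls$crit_ef & calls$crit_test))
})

test_that("the period window is hierarchical: out-of-window genes are never cyclic", {
  y <- cos(2 * pi * t / 17)            # best fit well under 18 h
  m <- rbind(short = y, ok = cos(2 * pi * t / 24))
  colnames(m) <- paste0(grid$label, "_", grid$cycle)
  calls <- classify_rhythms(feature_scale(m + 1e-9), grid)
  short <- calls[calls$gene == "short", ]
  expect_lt(short$period, 18)
  expect_false(short$crit_period)
  expect_false(short$is_cyclic)
  expect_true(is.na(short$p_raw))      # never entered the t-test family
})

test_that("unscaled input is rejected", {
  m <- matrix(rnorm(48), 2, 24)
  expect_error(classify_rhythms(m, grid), "feature-scaled")
})

test_that("Holm adjustment in the pipeline matches a hand-executed step-down", {
  sim <- generate_expression(synthetic_spec(n_genes = 300, seed = 13), grid)
  calls <- classify_rhythms(feature_scale(sim$matrix), grid)
  fam <- !is.na(calls$p_raw)
  expect_true(any(fam))
  expect_equal(calls$p_adj[fam], naive_holm(calls$p_raw[fam]), tolerance = 1e-12)
  expect_true(all(calls$p_adj[fam] >= calls$p_raw[fam] - 1e-15))
  expect_lte(sum(calls$p_adj[fam] < 0.05), sum(calls$p_raw[fam] < 0.05))
  # family is exactly the genes passing criteria (i) and (ii)
  expect_identical(fam, calls$crit_period & calls$crit_ef)
})

test_that("peak summaries tally cyclic genes per category and label", {
  calls <- fake_calls(c("a", "b", "c", "d"),
                      cyclic = c(TRUE, TRUE, TRUE, FALSE),
                      peak_label = c("L1", "L1", "D11", "L5"))
  cats <- data.frame(gene = c("a", "b", "c"), category = "Photosynthesis")
  tab <- summarize_peaks(calls, cats, grid)
  expect_equal(tab["Photosynthesis", "L1"], 2L)
  expect_equal(tab["Photosynthesis", "D11"], 1L)
  expect_equal(sum(tab), 3L)
  # unassigned genes fall into the catch-all row
  tab2 <- summarize_peaks(calls, data.frame(gene = "a", category = "PS"), grid)
  expect_equal(tab2["Unassigned and hypothetical", "L1"], 1L)
  expect_equal(tab2["Unassigned and hypothetical", "D11"], 1L)
  # no cyclic genes: all-zero table
  none <- fake_calls("x", cyclic = FALSE)
  expect_equal(sum(summarize_peaks(none, grid = grid)), 0L)
})
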