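test_that("transform obeys the arsinh identities and is invertible", {
  params <- structure(data.frame(channel = "ch1", a = 0, b = 1),
                      class = c("vsn_params", "data.frame"))
  expect_equal(apply_vsn(matrix(0), params)[1, 1], 0)     # arsinh(0) = 0
  # large-y asymptote: value approx log2(2 b y)
  y <- matrix(c(150, 1e3, 1e5), 3, 1)
  v <- apply_vsn(y, params)
  expect_equal(v, log2(2 * y), tolerance = 0.01)
  # strict monotonicity
  ys <- matrix(sort(stats::runif(50, 0, 1e4)), 50, 1)
  expect_true(all(diff(apply_vsn(ys, params)[, 1]) > 0))
  # invert(apply(.)) = identity
  p2 <- structure(data.frame(channel = c("a", "b"), a = c(-1, 2),
                             b = c(0.01, 0.5)),
                  class = c("vsn_params", "data.frame"))
  ym <- matrix(stats::runif(100, 0, 5e3), 50, 2)
  expect_equal(invert_vsn(apply_vsn(ym, p2), p2), ym, tolerance = 1e-9)
})

test_that("fit recovers the generative channel gains on null data", {
  tr <- gen_truth(n_peptides = 1000, substrate_rate = 0, seed = 21)
  psm <- gen_screen(tr, multiplicity = 0)
  pm <- collapse_fractions(average_within_fraction(psm))
  par <- fit_vsn(pm)
  expect_true(attr(par, "converged"))
  # fitted gains are inverse to the generative channel gains: the ratio
  # b_hat_1 / b_hat_i should match the truth ratio b_i / b_1 within 10%
  est_ratio <- par$b[1] / par$b
  true_ratio <- tr$channel_gain / tr$channel_gain[1]
  expect_lt(max(abs(est_ratio / true_ratio - 1)), 0.10)
})

test_that("all-identical channels give identical per-channel parameters", {
  col <- exp(stats::rnorm(200, 8, 1))
  m <- matrix(col, 200, 6)
  par <- fit_vsn(m)
  expect_lt(diff(range(par$a)), 1e-8)
  expect_lt(diff(range(par$b)), 1e-8)
})

test_that("trim_quantile = 1 matches an untrimmed direct-optimizer oracle", {
  set.seed(31)
  n <- 120; d <- 4
  mu <- exp(stats::rnorm(n, 7, 1))
  b_true <- c(1, 1.4, 0.8, 1.1)
  y <- sweep(matrix(mu, n, d) * exp(matrix(stats::rnorm(n * d, 0, 0.2), n, d)),
             2, b_true, `*`) + 30
  fit <- fit_vsn(y, trim_quantile = 1)
  # independent oracle: same likelihood written from scratch, different
  # optimizer (Nelder-Mead) and start
  nll <- function(theta) {
    a <- theta[1:d]; b <- exp(theta[(d + 1):(2 * d)])
    u <- sweep(sweep(y, 2, b, `*`), 2, a, `+`)
    h <- asinh(u)
    rss <- sum((h - rowMeans(h))^2)
    length(h) / 2 * log(rss / length(h)) -
      (n * sum(log(b)) - 0.5 * sum(log1p(u^2)))
  }
  start <- c(rep(0, d), -apply(log(y), 2, stats::median))
  oracle <- stats::optim(start, nll, method = "Nelder-Mead",
                         control = list(maxit = 20000, reltol = 1e-12))
  fitted_nll <- nll(c(fit$a, log(fit$b)))
  # the trim=1 fit is at least as good an untrimmed ML solution as the
  # direct optimizer finds
  expect_lt(fitted_nll, oracle$value + 0.01)
  # and it is a genuine optimum of the independently coded likelihood:
  # polishing from it changes neither the value nor the transform
  polish <- stats::optim(c(fit$a, log(fit$b)), nll, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-12))
  expect_lt(abs(polish$value - fitted_nll), 0.05)
  tr_fit <- apply_vsn(y, fit)
  op <- structure(data.frame(channel = 1:d, a = polish$par[1:d],
                             b = exp(polish$par[(d + 1):(2 * d)])),
                  class = c("vsn_params", "data.frame"))
  tr_or <- apply_vsn(y, op)
  expect_lt(stats::sd((tr_fit - rowMeans(tr_fit)) - (tr_or - rowMeans(tr_or))),
            0.02)
})

test_that("fitting is invariant to row permutation and rejects degenerate input", {
  tr <- gen_truth(n_peptides = 300, substrate_rate = 0, seed = 12)
  psm <- gen_screen(tr, multiplicity = 0)
  pm <- collapse_fractions(average_within_fraction(psm))
  p1 <- fit_vsn(pm$intensity)
  set.seed(1)
  p2 <- fit_vsn(pm$intensity[sample(nrow(pm$intensity)), ])
  expect_equal(p1$a, p2$a, tolerance = 1e-6)
  expect_equal(p1$b, p2$b, tolerance = 1e-6)
  constant <- cbind(rep(5, 100), stats::runif(100))
  expect_error(fit_vsn(constant), "constant")
  expect_error(fit_vsn(matrix(1:40, 40, 1)), "channels")
  expect_error(fit_vsn(matrix(stats::runif(20), 10, 2)), "50 rows")
})

test_that("variance stabilization flattens the SD-vs-rank trend on null data", {
  tr <- gen_truth(n_peptides = 2000, substrate_rate = 0, seed = 1)
  psm <- gen_screen(tr, multiplicity = 0)
  pm <- collapse_fractions(average_within_fraction(psm))
  raw_qc <- qc_diagnostics(pm)
  par <- fit_vsn(pm)
  tm <- apply_vsn(pm, par)
  qc <- qc_diagnostics(tm)
  # raw data: SD strongly increasing with intensity rank
  expect_gt(raw_qc$sd_rank_slope_rel, 1)
  # transformed: relative slope reduced at least 5-fold
  expect_lt(abs(qc$sd_rank_slope_rel), abs(raw_qc$sd_rank_slope_rel) / 5)
  # channel medians calibrated to the global median
  expect_lt(qc$max_median_offset, 0.05)
  # near-normal residuals after the transform
  expect_lt(qc$qq_dev, 1)
})

test_that("QC on a constant matrix reports an identically zero SD curve", {
  qc <- qc_diagnostics(matrix(3, 60, 5))
  expect_true(all(qc$sd_rank$sd == 0))
  expect_equal(qc$max_median_offset, 0)
})
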