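des10 <- group_design()

test_that("two-group fits match the textbook pooled-variance formulas", {
  m <- rbind(c(rep(1, 5), rep(0, 5)),
             c(rep(2, 5), rep(2, 5)))
  f <- fit_two_group(m, des10)
  expect_equal(f$effect, c(1, 0))
  expect_equal(f$s2, c(0, 0))
  expect_equal(f$df, c(8, 8))

  set.seed(2)
  row <- stats::rnorm(10, 5, 2)
  f1 <- fit_two_group(matrix(row, 1), des10)
  a <- row[1:5]; b <- row[6:10]
  expect_equal(f1$effect, mean(a) - mean(b), tolerance = 1e-12)
  expect_equal(f1$s2, (4 * stats::var(a) + 4 * stats::var(b)) / 8,
               tolerance = 1e-12)

  # missing values reduce df; < 2 per group is skipped
  row2 <- row; row2[1:2] <- NA
  f2 <- fit_two_group(matrix(row2, 1), des10)
  expect_equal(f2$df, 6)
  row3 <- row; row3[1:4] <- NA
  expect_true(fit_two_group(matrix(row3, 1), des10)$skipped)
})

test_that("hyperparameter estimation recovers a scaled-F prior", {
  set.seed(42)
  n <- 5000; d0 <- 4; s0 <- 2; dg <- 8
  s2 <- s0 * stats::rf(n, dg, d0)
  h <- estimate_hyperparams(s2, dg)
  expect_lt(abs(h$d0 / d0 - 1), 0.20)
  expect_lt(abs(h$s0_sq / s0 - 1), 0.10)
  # identical variances: zero-dispersion limit, d0 infinite
  h_inf <- estimate_hyperparams(rep(1.3, 100), 8)
  expect_identical(h_inf$d0, Inf)
  expect_equal(h_inf$s0_sq, 1.3, tolerance = 1e-9)
})

test_that("robust estimation tolerates variance outliers", {
  set.seed(42)
  n <- 5000; d0 <- 4; s0 <- 2; dg <- 8
  s2 <- s0 * stats::rf(n, dg, d0)
  clean <- estimate_hyperparams(s2, dg, robust = TRUE)
  s2o <- s2
  idx <- sample(n, n * 0.01)
  s2o[idx] <- s2o[idx] * 100
  rob <- estimate_hyperparams(s2o, dg, robust = TRUE)
  plain <- estimate_hyperparams(s2o, dg, robust = FALSE)
  expect_lt(abs(rob$d0 / clean$d0 - 1), 0.25)
  expect_lt(plain$d0, clean$d0 * 0.9)         # non-robust is biased low
  # outlier rows get individually reduced prior df (less moderation)
  expect_true(all(rob$d0_row[idx] <= rob$d0))
  expect_lt(stats::median(rob$d0_row[idx]), rob$d0 / 2)
})

test_that("hyperparameters and moderated p agree with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(5)
  m <- matrix(stats::rnorm(400 * 10), 400, 10) *
    sqrt(stats::rchisq(400, 4) / 4)
  fits <- fit_two_group(m, des10)
  h <- estimate_hyperparams(fits$s2, 8)
  design <- cbind(1, c(rep(1, 5), rep(0, 5)))
  lf <- limma::lmFit(m, design)
  lf <- limma::eBayes(lf)
  expect_equal(h$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(h$s0_sq, lf$s2.prior, tolerance = 1e-6)
  res <- moderated_test(fits, h)
  expect_equal(res$t, lf$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$p, lf$p.value[, 2], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("shrinkage arithmetic and the d0 limits match closed forms", {
  fits <- data.frame(effect = 1, s2 = 2, df = 8, n_wt = 5, n_kd = 5,
                     skipped = FALSE)
  res <- moderated_test(fits, list(d0 = 4, s0_sq = 1))
  expect_equal(res$s_tilde_sq, 20 / 12, tolerance = 1e-12)

  set.seed(9)
  m <- matrix(stats::rnorm(100 * 10, 0, 2), 100, 10)
  f <- fit_two_group(m, des10)
  # d0 = 0: ordinary two-sample pooled t-test
  r0 <- moderated_test(f, list(d0 = 0, s0_sq = 1))
  p_oracle <- apply(m, 1, function(row)
    stats::t.test(row[1:5], row[6:10], var.equal = TRUE)$p.value)
  expect_equal(r0$p, unname(p_oracle), tolerance = 1e-10)
  # d0 = Inf: z-test against the prior variance
  rinf <- moderated_test(f, list(d0 = Inf, s0_sq = 4))
  z <- f$effect / sqrt(4 * (1 / 5 + 1 / 5))
  expect_equal(rinf$p, 2 * stats::pnorm(-abs(z)), tolerance = 1e-12)
  # |t| ordering equals |effect| ordering when all s2 equal
  feq <- data.frame(effect = stats::rnorm(20), s2 = 1.5, df = 8,
                    n_wt = 5, n_kd = 5, skipped = FALSE)
  req <- moderated_test(feq, list(d0 = 4, s0_sq = 1))
  expect_equal(order(abs(req$t)), order(abs(feq$effect)))
})

test_that("null p-values are uniform", {
  set.seed(11)
  m <- matrix(stats::rnorm(3000 * 10), 3000, 10)
  f <- fit_two_group(m, des10)
  h <- estimate_hyperparams(f$s2, 8, robust = TRUE)
  res <- moderated_test(f, h)
  ks <- stats::ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("hit selection applies the strict p, direction, uniqueness and localization gates", {
  meta <- data.frame(
    peptide_id = paste0("P", 1:6),
    protein_id = paste0("PR", 1:6),
    modified_sequence = c("AAARPAS(ph)AKAA", "AAARPAS(ph)AKAA",
                          "AAAKAAS(ph)AKAA", "AAARPAS(ph)AKAA",
                          "AAARPAS(ph)S(ph)KAA", "AAARPAS(ph)AKAA"),
    site_position = 7, unique_single_site = c(T, T, T, T, F, T),
    ptm_probability = c(0.99, 0.99, 0.99, 0.70, 0.99, 0.995),
    stringsAsFactors = FALSE)
  res <- data.frame(effect = c(2, -2, 2, 2, 2, 2),
                    s2 = 1, df = 8, n_wt = 5, n_kd = 5, skipped = FALSE,
                    s_tilde_sq = 1, t = 5, df_total = 12,
                    p = c(1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 5e-4))
  hits <- select_hits(res, meta)
  # P2 fails direction, P4 fails localization, P5 fails uniqueness,
  # P6 fails the strict p < 5e-4 (boundary excluded)
  expect_setequal(hits$peptide_id, c("P1", "P3"))
  # motif is annotation, not a filter: P3 (K at -3) is kept, flagged FALSE
  expect_false(hits$motif_match[hits$peptide_id == "P3"])
  expect_true(hits$motif_match[hits$peptide_id == "P1"])
  # direction gate off admits the negative effect
  hits2 <- select_hits(res, meta, require_wt_up = FALSE)
  expect_true("P2" %in% hits2$peptide_id)
  # monotonicity: raising the threshold never removes a hit
  hits3 <- select_hits(res, meta, p_threshold = 1e-3)
  expect_true(all(hits$peptide_id %in% hits3$peptide_id))
})

test_that("the default screen recovers spiked substrates with high sensitivity and precision", {
  tr <- gen_truth(seed = 1)
  psm <- gen_screen(tr)
  pm <- filter_localization(collapse_fractions(average_within_fraction(psm)))
  tm <- apply_vsn(pm, fit_vsn(pm))
  f <- fit_two_group(tm, des10)
  h <- estimate_hyperparams(f$s2, f$df[is.finite(f$df)][1], robust = TRUE)
  hits <- select_hits(moderated_test(f, h), pm$meta)
  rec <- hit_recovery(hits, tr)
  expect_gte(rec$sensitivity, 0.90)
  expect_gte(rec$precision, 0.95)
})
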