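#' Per-row two-group fits
#'
#' For every row of a glog2-scale matrix, computes the WT-minus-KD effect
#' (difference of group means), the pooled within-group variance and its
#' residual degrees of freedom. Missing values reduce the per-row group
#' sizes and df; rows with fewer than 2 finite values in either group are
#' flagged `skipped` and carry NA statistics.
#'
#' @param x `transformed_matrix`, `peptide_matrix` or numeric matrix.
#' @param design A [group_design()].
#' @return Data frame: effect, s2 (pooled variance), df, n_wt, n_kd,
#'   skipped.
#' @export
fit_two_group <- function(x, design) {
  m <- if (inherits(x, "peptide_matrix")) x$intensity else as.matrix(x)
  stopifnot(ncol(m) == length(design$group))
  wt <- design$group == "WT"
  kd <- design$group == "KD"
  out <- t(apply(m, 1, function(row) {
    a <- row[wt][is.finite(row[wt])]
    b <- row[kd][is.finite(row[kd])]
    if (length(a) < 2 || length(b) < 2)
      return(c(NA, NA, NA, length(a), length(b), 1))
    df <- length(a) + length(b) - 2
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
    c(mean(a) - mean(b), s2, df, length(a), length(b), 0)
  }))
  out <- as.data.frame(out)
  names(out) <- c("effect", "s2", "df", "n_wt", "n_kd", "skipped")
  out$skipped <- out$skipped == 1
  rownames(out) <- NULL
  out
}

#' Inverse of the trigamma function
#'
#' Solves trigamma(y) = x by Newton iteration on the monotone decreasing
#' trigamma; used to moment-match the scaled-F prior of sample variances.
#'
#' @param x Positive target value(s).
#' @return y with trigamma(y) = x.
#' @export
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, 0)
}

# Theoretical mean and variance of winsorized log F(df1, df2) computed on a
# fine probability grid; used by the robust moment correction.
winsorized_logf_moments <- function(df1, df2, winsor, n_grid = 2001L) {
  p <- (seq_len(n_grid) - 0.5) / n_grid
  z <- log(stats::qf(p, df1, df2))
  lo <- stats::quantile(z, winsor[1])
  hi <- stats::quantile(z, 1 - winsor[2])
  zw <- pmin(pmax(z, lo), hi)
  c(mean = mean(zw), var = stats::var(zw))
}

#' Empirical-Bayes hyperparameters for variance shrinkage
#'
#' Fits a scaled-F prior s2 ~ s0_sq * F(df, d0) to the per-row sample
#' variances by moment matching on z = log(s2), using the digamma/trigamma
#' identities for log chi-square moments (d0 solved with a Newton trigamma
#' inverse). With `robust = TRUE`, z is winsorized at `winsor_tails`
#' (default 5% lower, 10% upper) and the winsorized moments are matched
#' against the theoretical winsorized moments of log F, computed
#' numerically, so a small share of hypervariable rows cannot inflate the
#' prior; rows beyond the upper winsorization limit are treated as variance
#' outliers and assigned an individual, smaller prior df (down to 0 =
#' no moderation) proportional to how extreme they are under the fitted
#' prior.
#'
#' @param s2 Per-row sample variances.
#' @param df Per-row residual df (scalar or vector).
#' @param robust Use the winsorized robust estimator.
#' @param winsor_tails c(lower, upper) winsorization proportions.
#' @return `ebayes_hyper`: list d0, s0_sq, robust, winsor_tails, d0_row
#'   (per-row prior df; all equal d0 unless robust flags outliers).
#' @export
estimate_hyperparams <- function(s2, df, robust = FALSE,
                                 winsor_tails = c(0.05, 0.10)) {
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df > 0
  if (sum(ok) < 20) stop("need at least 20 rows with positive variance")
  z <- log(s2[ok])
  dfv <- if (length(df) == 1) rep(df, sum(ok)) else df[ok]
  n <- length(z)
  # remove the known sampling-df contribution from the mean of z
  e <- z - digamma(dfv / 2) + log(dfv / 2)

  # zero-dispersion limit: identical variances mean a point-mass prior
  if (stats::var(z) < 1e-14) {
    return(structure(list(d0 = Inf, s0_sq = exp(mean(z)), robust = robust,
                          winsor_tails = winsor_tails,
                          d0_row = rep(Inf, length(s2))),
                     class = "ebayes_hyper"))
  }
  if (!robust) {
    evar <- stats::var(e) - mean(trigamma(dfv / 2))
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0 <- exp(mean(e))
    }
    d0_row <- rep(d0, length(s2))
  } else {
    dfc <- mean(dfv)
    lo <- stats::quantile(z, winsor_tails[1])
    hi <- stats::quantile(z, 1 - winsor_tails[2])
    zw <- pmin(pmax(z, lo), hi)
    vw <- stats::var(zw)
    # d0 solves: theoretical winsorized var of log F(dfc, d0) = vw
    vfun <- function(log_d0)
      winsorized_logf_moments(dfc, exp(log_d0), winsor_tails)[["var"]] - vw
    v_inf <- winsorized_logf_moments(dfc, 1e8, winsor_tails)[["var"]]
    if (vw <= v_inf) {
      d0 <- Inf
      mom_mean <- winsorized_logf_moments(dfc, 1e8, winsor_tails)[["mean"]]
    } else {
      root <- stats::uniroot(vfun, lower = log(0.1), upper = log(1e6),
                             extendInt = "downX", tol = 1e-8)
      d0 <- exp(root$root)
      mom_mean <- winsorized_logf_moments(dfc, d0, winsor_tails)[["mean"]]
    }
    s0 <- exp(mean(zw) - mom_mean)
    # rows beyond the upper winsorization limit are variance outliers:
    # their prior df shrinks with how far their tail probability falls
    # below that of the limit itself, so extreme rows get (almost) no
    # moderation while rows at the limit keep the global d0
    d0_row <- rep(d0, length(s2))
    if (is.finite(d0)) {
      dfr <- if (length(df) == 1) rep(df, length(s2)) else df
      out_rows <- which(is.finite(s2) & s2 > 0 & log(s2) > hi)
      if (length(out_rows) > 0) {
        p_up <- stats::pf(s2[out_rows] / s0, dfr[out_rows], d0,
                          lower.tail = FALSE)
        p_hi <- stats::pf(exp(hi) / s0, mean(dfr[out_rows]), d0,
                          lower.tail = FALSE)
        d0_row[out_rows] <- d0 * pmin(1, p_up / p_hi)
      }
    }
  }
  structure(list(d0 = unname(d0), s0_sq = unname(s0), robust = robust,
                 winsor_tails = winsor_tails, d0_row = d0_row),
            class = "ebayes_hyper")
}

#' Moderated t-tests with empirical-Bayes shrunken variances
#'
#' Shrinks each row's variance toward the prior: s_tilde^2 = (d0 * s0^2 +
#' df * s2) / (d0 + df), forms t = effect / sqrt(s_tilde^2 * (1/n_WT +
#' 1/n_KD)) and two-sided p-values from the t distribution with d0 + df
#' degrees of freedom (standard normal when d0 = Inf; ordinary t when
#' d0 = 0).
#'
#' @param fits A [fit_two_group()] result.
#' @param hyper An [estimate_hyperparams()] result (or list with d0, s0_sq).
#' @return Data frame: effect, s2, df, s_tilde_sq, t, df_total, p plus the
#'   fit columns.
#' @export
moderated_test <- function(fits, hyper) {
  d0 <- if (!is.null(hyper$d0_row)) hyper$d0_row else rep(hyper$d0, nrow(fits))
  if (length(d0) == 1) d0 <- rep(d0, nrow(fits))
  s0 <- hyper$s0_sq
  s_tilde <- ifelse(is.infinite(d0), s0,
                    (d0 * s0 + fits$df * fits$s2) / (d0 + fits$df))
  se <- sqrt(s_tilde * (1 / fits$n_wt + 1 / fits$n_kd))
  t <- fits$effect / se
  df_total <- d0 + fits$df
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t)),
              2 * stats::pt(-abs(t), df_total))
  out <- cbind(fits,
               data.frame(s_tilde_sq = s_tilde, t = t,
                          df_total = df_total, p = p))
  rownames(out) <- NULL
  out
}

#' Select screen hits with the paper-style gates
#'
#' A row is a hit iff p < `p_threshold` (strict), the effect direction
#' passes (WT-up by default), the peptide has a single unique phosphosite
#' and its localization probability passes the >= 0.75 gate. The FLR flag
#' (>= 0.994) and consensus-motif match are annotated but never used as
#' filters.
#'
#' @param res A [moderated_test()] result.
#' @param meta Peptide metadata (from `peptide_matrix$meta`), same row
#'   order; must contain unique_single_site, ptm_probability and
#'   modified_sequence (for motif annotation); flr_flag if present is
#'   carried through.
#' @param p_threshold Strict p-value cutoff (default 5e-4).
#' @param require_wt_up Require effect > 0 (default TRUE).
#' @param min_prob Localization gate (default 0.75).
#' @param spec Consensus [motif_spec()] for annotation.
#' @return `hit_table` data frame of passing rows with flag columns
#'   direction_wt_up, unique_single_site, loc_ge_075, flr_flag,
#'   motif_match.
#' @export
select_hits <- function(res, meta, p_threshold = 5e-4,
                        require_wt_up = TRUE, min_prob = 0.75,
                        spec = motif_spec()) {
  stopifnot(nrow(res) == nrow(meta))
  tab <- cbind(meta, res[setdiff(names(res), names(meta))])
  tab$direction_wt_up <- !is.na(tab$effect) & tab$effect > 0
  tab$loc_ge_075 <- tab$ptm_probability >= min_prob
  if (!"flr_flag" %in% names(tab))
    tab$flr_flag <- tab$ptm_probability >= 0.994
  tab$motif_match <- vapply(seq_len(nrow(tab)), function(i) {
    ps <- parse_phospho_sites(tab$modified_sequence[i])
    if (ps$n == 0) return(FALSE)
    w <- extract_window(ps$stripped, ps$positions[1])
    match_motif(w, spec)$match
  }, TRUE)
  pass <- !is.na(tab$p) & tab$p < p_threshold &
    (!require_wt_up | tab$direction_wt_up) &
    tab$unique_single_site & tab$loc_ge_075
  out <- tab[pass, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", class(out))
  out
}

#' Recovery metrics of a synthetic screen
#'
#' Compares a hit table against the generator's ground truth. Sensitivity
#' is computed among substrates eligible for selection (single unique
#' site and localization >= `min_prob`), since the localization filter is
#' an upstream data-quality gate rather than a property of the test;
#' precision is computed over all selected rows.
#'
#' @param hits A [select_hits()] result.
#' @param truth A [gen_truth()] object.
#' @param min_prob Localization gate used in selection.
#' @return List: sensitivity, precision, n_hits, n_eligible_substrates,
#'   n_true_positive.
#' @export
hit_recovery <- function(hits, truth, min_prob = 0.75) {
  pep <- truth$peptides
  eligible <- pep$is_substrate & !pep$multi_site &
    pep$ptm_probability >= min_prob & pep$delta > 0
  tp <- sum(hits$peptide_id %in% pep$peptide_id[eligible])
  truth_sub <- pep$peptide_id[pep$is_substrate]
  list(sensitivity = tp / sum(eligible),
       precision = if (nrow(hits) == 0) NA_real_
                   else mean(hits$peptide_id %in% truth_sub),
       n_hits = nrow(hits),
       n_eligible_substrates = sum(eligible),
       n_true_positive = tp)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Optional FDR column for the moderated results; emitted for reference
#' only, never used by the default hit selection.
#'
#' @param p Numeric p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
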