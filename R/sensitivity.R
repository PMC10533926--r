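#' Cochran Q heterogeneity statistic
#'
#' For the IVW reference, `Q = sum_j w_j (ratio_j - theta_FE)^2` over the
#' per-SNP Wald ratios with inverse-variance weights, `df = k - 1`. For
#' the Egger reference, `Q` is the weighted residual sum of squares of
#' the intercept model (weights `1/SE_outcome^2`), `df = k - 2`. The
#' p-value is the upper tail of the chi-square distribution; values below
#' 0.05 indicate significant heterogeneity. `Q` is invariant to
#' rescaling of the exposure units.
#'
#' @param h An [mr_instruments] set.
#' @param reference `"ivw"` (default) or `"egger"`.
#' @param se_order Delta-method order of the Wald-ratio weights for the
#'   IVW reference, `"first"` (default) or `"second"`.
#' @return A list of class `mr_q` with `q`, `df`, `pval`.
#' @examples
#' cochran_q(ltl_constipation())
#' @export
cochran_q <- function(h, reference = c("ivw", "egger"),
                      se_order = c("first", "second")) {
  reference <- match.arg(reference)
  se_order <- match.arg(se_order)
  k <- nrow(h)
  if (reference == "ivw") {
    if (k < 2) stop("Cochran Q (IVW) needs >= 2 SNPs", call. = FALSE)
    wr <- wald_ratios(h, se_order = se_order)
    theta <- sum(wr$weight * wr$ratio) / sum(wr$weight)
    q <- sum(wr$weight * (wr$ratio - theta)^2)
    df <- k - 1
  } else {
    if (k < 3) stop("Cochran Q (Egger) needs >= 3 SNPs", call. = FALSE)
    flip <- sign(h$beta_exposure) == -1
    bx <- abs(h$beta_exposure)
    by <- ifelse(flip, -h$beta_outcome, h$beta_outcome)
    w <- 1 / h$se_outcome^2
    fit <- stats::lm(by ~ bx, weights = w)
    q <- sum(w * stats::residuals(fit)^2)
    df <- k - 2
  }
  structure(list(q = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "mr_q")
}

#' @export
print.mr_q <- function(x, digits = 3, ...) {
  cat(sprintf("Cochran Q = %.3f, df = %d, p = %.*f\n",
              x$q, x$df, digits, x$pval))
  invisible(x)
}

# leave-one-out IVW slopes (first-order weights 1/SE_Y^2), vectorized:
# theta_{-j} = (S_xy - w_j bx_j by_j) / (S_xx - w_j bx_j^2)
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global heterogeneity and outlier test
#'
#' Simulation-based residual test. For each SNP `j` the IVW slope is
#' fitted on the other `k - 1` SNPs; the observed statistic is the
#' weighted residual sum of squares
#' `RSS_obs = sum_j (beta_Yj - theta_{-j} beta_Xj)^2 / SE_Yj^2`. Under
#' the null, `n_sim` datasets are drawn with
#' `beta_Xj* ~ N(beta_Xj, SE_Xj)` and
#' `beta_Yj* ~ N(theta_{-j} beta_Xj, SE_Yj)` and the statistic is
#' recomputed (including refitted leave-one-out slopes). The global
#' empirical p-value is `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`, so it
#' is never zero. Per-SNP outlier p-values compare each observed squared
#' residual with its simulated distribution and are Bonferroni-adjusted
#' across the `k` SNPs; SNPs with adjusted p below `outlier_alpha` are
#' flagged.
#'
#' @param h An [mr_instruments] set with at least 4 SNPs.
#' @param n_sim Simulation iterations, >= 100; default 1000.
#' @param outlier_alpha Flagging threshold on the Bonferroni-adjusted
#'   per-SNP p-values, default 0.05.
#' @param seed RNG seed, default 20230913.
#' @return A list of class `mr_presso` with `rss_obs`, `global_pval`,
#'   `n_sim`, `outlier_pvals` (adjusted, named by SNP), `outliers`, `seed`.
#' @examples
#' mr_presso(ltl_constipation(), n_sim = 200, seed = 1)
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 20230913) {
  k <- nrow(h)
  if (k < 4) stop("MR-PRESSO needs >= 4 SNPs", call. = FALSE)
  stopifnot(n_sim >= 100)
  bx <- h$beta_exposure
  by <- h$beta_outcome
  w <- 1 / h$se_outcome^2
  theta_loo <- loo_slopes(bx, by, w)
  res_obs <- (by - theta_loo * bx)^2 * w
  rss_obs <- sum(res_obs)
  sim <- withr_seed(seed, {
    bxs <- matrix(stats::rnorm(k * n_sim, bx, h$se_exposure), nrow = k)
    bys <- matrix(stats::rnorm(k * n_sim, theta_loo * bx, h$se_outcome),
                  nrow = k)
    sxy <- colSums(w * bxs * bys)
    sxx <- colSums(w * bxs^2)
    loos <- (rep(sxy, each = k) - w * bxs * bys) /
      (rep(sxx, each = k) - w * bxs^2)
    (bys - loos * bxs)^2 * w          # k x n_sim matrix of residual terms
  })
  rss_sim <- colSums(sim)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  out_p <- (1 + rowSums(sim >= res_obs)) / (n_sim + 1)
  out_p_adj <- pmin(1, out_p * k)
  names(out_p_adj) <- h$snp
  outliers <- h$snp[out_p_adj < outlier_alpha]
  structure(list(rss_obs = rss_obs, global_pval = global_pval,
                 n_sim = n_sim, outlier_pvals = out_p_adj,
                 outliers = outliers, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, digits = 3, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.3f, p = %.*f (%d simulations)\n",
              x$rss_obs, digits, x$global_pval, x$n_sim))
  if (length(x$outliers) > 0L) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' Leave-one-out analysis
#'
#' Refits the main (IVW) estimate `k` times, omitting each SNP in turn,
#' to surface single instruments that drive the causal estimate. A row is
#' flagged when the estimate without that SNP falls outside the full-set
#' confidence interval.
#'
#' @param h An [mr_instruments] set with at least 3 SNPs.
#' @param model,se_order Passed to [mr_ivw()]; defaults match the main
#'   analysis (multiplicative random effects, first-order weights).
#' @return A data.frame of class `mr_loo` with one row per omitted SNP
#'   (`snp`, `b`, `se`, `ci_low`, `ci_high`, `outside_full_ci`); the
#'   full-set estimate is in `attr(, "full")`.
#' @examples
#' leave_one_out(ltl_constipation())
#' @export
leave_one_out <- function(h, model = "random", se_order = "first") {
  k <- nrow(h)
  if (k < 3) stop("leave-one-out needs >= 3 SNPs", call. = FALSE)
  full <- mr_ivw(h, model = model, se_order = se_order)
  rows <- lapply(seq_len(k), function(j) {
    e <- mr_ivw(h[-j, , drop = FALSE], model = model, se_order = se_order)
    data.frame(snp = h$snp[j], b = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$outside_full_ci <- tab$b < full$ci_low | tab$b > full$ci_high
  structure(tab, full = full, class = c("mr_loo", "data.frame"))
}

#' @export
print.mr_loo <- function(x, ...) {
  full <- attr(x, "full")
  cat("Leave-one-out IVW estimates (full set: b =",
      format(full$beta, digits = 4), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' Per-SNP Wald ratio against its precision (`1/SE`), with the IVW
#' estimate as reference line. Asymmetry of the scatter about the
#' reference suggests directional pleiotropy.
#'
#' @param h An [mr_instruments] set.
#' @param se_order Delta-method order of the ratio SEs, default `"first"`.
#' @return Data frame with `snp`, `ratio`, `precision`; the IVW reference
#'   value is in `attr(, "reference")`.
#' @export
funnel_data <- function(h, se_order = "first") {
  wr <- wald_ratios(h, se_order = se_order)
  ref <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  structure(data.frame(snp = wr$snp, ratio = wr$ratio,
                       precision = 1 / wr$se, stringsAsFactors = FALSE),
            reference = ref)
}

#' Full sensitivity suite
#'
#' Runs the heterogeneity, pleiotropy and influence diagnostics in one
#' call: Cochran Q against both the IVW and Egger references, the Egger
#' intercept test, MR-PRESSO, leave-one-out, and funnel coordinates.
#'
#' @param h An [mr_instruments] set.
#' @param n_sim MR-PRESSO iterations, default 1000.
#' @param outlier_alpha MR-PRESSO flagging threshold, default 0.05.
#' @param seed RNG seed for MR-PRESSO, default 20230913.
#' @param se_order Wald-ratio weight order for Q and leave-one-out.
#' @return A list of class `mr_sensitivity` with elements `q_ivw`,
#'   `q_egger`, `egger_intercept` (list: estimate, se, pval), `presso`,
#'   `loo`, `funnel`.
#' @examples
#' mr_sensitivity(ltl_constipation(), n_sim = 200, seed = 1)
#' @export
mr_sensitivity <- function(h, n_sim = 1000, outlier_alpha = 0.05,
                           seed = 20230913, se_order = "first") {
  eg <- mr_egger(h)
  structure(list(
    q_ivw = cochran_q(h, "ivw", se_order = se_order),
    q_egger = cochran_q(h, "egger"),
    egger_intercept = list(estimate = eg$intercept, se = eg$intercept_se,
                           pval = eg$intercept_pval),
    presso = mr_presso(h, n_sim = n_sim, outlier_alpha = outlier_alpha,
                       seed = seed),
    loo = leave_one_out(h, se_order = se_order),
    funnel = funnel_data(h)),
    class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, digits = 3, ...) {
  cat("Sensitivity analysis\n")
  cat(sprintf("  Cochran Q (IVW):   Q = %.3f, df = %d, p = %.*f\n",
              x$q_ivw$q, x$q_ivw$df, digits, x$q_ivw$pval))
  cat(sprintf("  Cochran Q (Egger): Q = %.3f, df = %d, p = %.*f\n",
              x$q_egger$q, x$q_egger$df, digits, x$q_egger$pval))
  cat(sprintf("  Egger intercept:   %.4f (SE %.4f), p = %.*f\n",
              x$egger_intercept$estimate, x$egger_intercept$se,
              digits, x$egger_intercept$pval))
  cat(sprintf("  MR-PRESSO global:  p = %.*f (%d simulations)%s\n",
              digits, x$presso$global_pval, x$presso$n_sim,
              if (length(x$presso$outliers) > 0L)
                paste0("; outliers: ",
                       paste(x$presso$outliers, collapse = ", "))
              else "; no outliers"))
  n_out <- sum(x$loo$outside_full_ci)
  cat(sprintf("  Leave-one-out:     %d of %d omissions outside full CI\n",
              n_out, nrow(x$loo)))
  invisible(x)
}
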