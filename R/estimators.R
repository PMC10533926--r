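#' Per-SNP Wald ratios
#'
#' The ratio estimate `beta_outcome / beta_exposure` per SNP with a
#' delta-method standard error. First order uses the outcome uncertainty
#' only, `SE_Y / |beta_X|`; second order adds the exposure uncertainty,
#' `sqrt(SE_Y^2 / beta_X^2 + beta_Y^2 SE_X^2 / beta_X^4)`, and is never
#' smaller than first order.
#'
#' @param h An [mr_instruments] set; all exposure betas must be nonzero.
#' @param se_order `"first"` (default) or `"second"`.
#' @return Data frame with `snp`, `ratio`, `se`, `weight` (`1/se^2`).
#' @export
wald_ratios <- function(h, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  zero <- h$beta_exposure == 0
  if (any(zero)) {
    stop("exposure beta is zero for SNP(s): ",
         paste(h$snp[zero], collapse = ", "), call. = FALSE)
  }
  ratio <- h$beta_outcome / h$beta_exposure
  se <- if (se_order == "first") {
    h$se_outcome / abs(h$beta_exposure)
  } else {
    sqrt(h$se_outcome^2 / h$beta_exposure^2 +
           h$beta_outcome^2 * h$se_exposure^2 / h$beta_exposure^4)
  }
  data.frame(snp = h$snp, ratio = ratio, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

#' Odds ratio with confidence interval from a log-odds effect
#'
#' @param beta Effect on the log-odds scale.
#' @param se Its standard error, > 0.
#' @param level Confidence level in (0, 1), default 0.95
#'   (`z = 1.959964`).
#' @return List with `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(beta, se, level = 0.95) {
  stopifnot(se > 0, level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  list(or = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se))
}

new_mr_estimate <- function(method, beta, se, pval, n_snp, level = 0.95,
                            intercept = NULL, intercept_se = NULL,
                            intercept_pval = NULL) {
  z <- stats::qnorm((1 + level) / 2)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  structure(list(
    method = method, beta = beta, se = se, pval = pval,
    ci_low = ci_low, ci_high = ci_high,
    or_ = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
    n_snp = n_snp, level = level,
    intercept = intercept, intercept_se = intercept_se,
    intercept_pval = intercept_pval),
    class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s (k = %d): OR %.*f (%g%% CI %.*f-%.*f), SE(log) %.*f, p = %.*f\n",
              x$method, x$n_snp, digits, x$or_, 100 * x$level,
              digits, x$or_ci_low, digits, x$or_ci_high,
              digits, x$se, digits, x$pval))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept %.4f (SE %.4f), p = %.*f\n",
                x$intercept, x$intercept_se, digits, x$intercept_pval))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snp, b = x$beta, se = x$se,
             pval = x$pval, ci_low = x$ci_low, ci_high = x$ci_high,
             or = x$or_, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines the per-SNP Wald ratios by inverse-variance weighting, which
#' equals (for first-order weights) the weighted regression of outcome
#' betas on exposure betas through the origin with weights
#' `1/SE_outcome^2`. The random-effects variant (default, the main
#' analysis model) uses multiplicative over-dispersion: the fixed-effect
#' standard error is scaled by `max(1, sqrt(Q / (k - 1)))` where `Q` is
#' Cochran's statistic, so standard errors are never deflated below the
#' fixed-effect value. `se_order` selects the delta-method order of the
#' per-SNP standard errors used for the weights and `Q`; `"second"`
#' also propagates the exposure-side uncertainty.
#'
#' P-values are two-sided normal; the confidence interval is
#' `beta +/- z * SE` on the log-odds scale.
#'
#' @param h An [mr_instruments] set.
#' @param model `"random"` (default; needs k >= 2) or `"fixed"` (k >= 1).
#' @param se_order Delta-method order for weights, `"first"` (default)
#'   or `"second"`.
#' @param level Confidence level, default 0.95.
#' @return An object of class `mr_estimate`.
#' @examples
#' h <- ltl_constipation()
#' mr_ivw(h)
#' @export
mr_ivw <- function(h, model = c("random", "fixed"),
                   se_order = c("first", "second"), level = 0.95) {
  model <- match.arg(model)
  se_order <- match.arg(se_order)
  k <- nrow(h)
  if (model == "fixed" && k < 1) stop("fixed-effect IVW needs >= 1 SNP",
                                      call. = FALSE)
  if (model == "random" && k < 2) stop("random-effects IVW needs >= 2 SNPs",
                                       call. = FALSE)
  wr <- wald_ratios(h, se_order = se_order)
  w <- wr$weight
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  se <- se_fixed
  if (model == "random") {
    q <- sum(w * (wr$ratio - beta)^2)
    se <- se_fixed * max(1, sqrt(q / (k - 1)))
  }
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(paste0("ivw-", if (model == "random") "re" else "fe"),
                  beta, se, pval, k, level)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' unconstrained intercept, weights `1/SE_outcome^2`, after orienting
#' every SNP so its exposure beta is positive (the conventional
#' parameterization; the slope is otherwise not identified). The slope is
#' the pleiotropy-robust causal estimate under the InSIDE assumption; the
#' intercept estimates average directional pleiotropy and its test is the
#' Egger intercept test. Standard errors carry the multiplicative
#' residual-variance scaling of the weighted fit (not floored at 1);
#' slope and intercept p-values are two-sided t with `k - 2` degrees of
#' freedom.
#'
#' @param h An [mr_instruments] set with at least 3 SNPs.
#' @param level Confidence level, default 0.95.
#' @return An `mr_estimate` with `intercept`, `intercept_se`,
#'   `intercept_pval` filled in.
#' @examples
#' h <- ltl_constipation()
#' mr_egger(h)
#' @export
mr_egger <- function(h, level = 0.95) {
  k <- nrow(h)
  if (k < 3) stop("MR-Egger needs >= 3 SNPs", call. = FALSE)
  flip <- sign(h$beta_exposure) == -1
  bx <- abs(h$beta_exposure)
  by <- ifelse(flip, -h$beta_outcome, h$beta_outcome)
  if (stats::sd(bx) == 0) {
    stop("all exposure betas identical: Egger design matrix singular",
         call. = FALSE)
  }
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  beta <- sm["bx", "Estimate"]
  se <- sm["bx", "Std. Error"]
  pval <- 2 * stats::pt(-abs(beta / se), df = k - 2)
  i0 <- sm["(Intercept)", "Estimate"]
  i0_se <- sm["(Intercept)", "Std. Error"]
  i0_p <- 2 * stats::pt(-abs(i0 / i0_se), df = k - 2)
  new_mr_estimate("egger", beta, se, pval, k, level,
                  intercept = i0, intercept_se = i0_se, intercept_pval = i0_p)
}

weighted_median_point <- function(ratio, weight, snp = NULL) {
  # deterministic ties: sort by ratio then identifier
  o <- if (is.null(snp)) order(ratio) else order(ratio, snp)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- cumsum(w) - w / 2
  if (length(r) == 1L) return(r)
  stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The 50th percentile of the inverse-variance-weighted empirical
#' distribution of per-SNP Wald ratios: ratios are sorted, normalized
#' weights accumulated, and the estimate is the linear interpolation of
#' ratio values at cumulative midpoint 0.5. Consistent when at least half
#' of the instrument weight comes from valid instruments. The standard
#' error is a parametric bootstrap: exposure and outcome betas are
#' resampled from normal distributions centered on their observed values
#' with their reported standard errors, the estimate (with recomputed
#' weights) is recalculated per resample, and the standard deviation over
#' resamples is taken. P-value two-sided normal.
#'
#' @param h An [mr_instruments] set with at least 3 SNPs.
#' @param n_boot Bootstrap iterations, default 1000.
#' @param seed RNG seed for the bootstrap, default 20230913.
#' @param se_order Delta-method order for the ratio weights, `"first"`
#'   (default) or `"second"`.
#' @param level Confidence level, default 0.95.
#' @return An `mr_estimate`.
#' @examples
#' h <- ltl_constipation()
#' mr_weighted_median(h, n_boot = 200, seed = 1)
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 20230913,
                               se_order = c("first", "second"),
                               level = 0.95) {
  se_order <- match.arg(se_order)
  k <- nrow(h)
  if (k < 3) stop("weighted median needs >= 3 SNPs", call. = FALSE)
  stopifnot(n_boot >= 1)
  wr <- wald_ratios(h, se_order = se_order)
  beta <- weighted_median_point(wr$ratio, wr$weight, wr$snp)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, h$beta_exposure, h$se_exposure)
      by <- stats::rnorm(k, h$beta_outcome, h$se_outcome)
      r <- by / bx
      v <- if (se_order == "first") {
        (h$se_outcome / abs(bx))^2
      } else {
        h$se_outcome^2 / bx^2 + by^2 * h$se_exposure^2 / bx^4
      }
      weighted_median_point(r, 1 / v)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted-median", beta, se, pval, k, level)
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
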