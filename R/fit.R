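#' Fit two-sample Mendelian randomization models
#'
#' The package's central fitting function: computes the requested causal
#' estimators on a harmonized instrument set and returns a classed model
#' object with the usual accessor methods (`print`, `summary`, `coef`,
#' `confint`, `residuals`, `plot`).
#'
#' @param h An [mr_instruments] set (or a data.frame coercible by
#'   [mr_instruments()]).
#' @param methods Estimators to run; any of `"ivw"`, `"egger"`,
#'   `"weighted_median"`.
#' @param model IVW model, `"random"` (default) or `"fixed"`.
#' @param se_order Delta-method order for Wald-ratio weights (IVW, Q and
#'   weighted median), `"first"` (default) or `"second"`.
#' @param n_boot Weighted-median bootstrap iterations, default 1000.
#' @param seed Seed for the weighted-median bootstrap, default 20230913.
#' @param level Confidence level, default 0.95.
#' @return An object of class `mr_fit`: a list with `instruments`, the
#'   named list `estimates` of [`mr_estimate`][mr_ivw] objects, and the
#'   call settings.
#' @examples
#' fit <- mr_fit(ltl_constipation(), n_boot = 200, seed = 1)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
mr_fit <- function(h, methods = c("ivw", "egger", "weighted_median"),
                   model = c("random", "fixed"),
                   se_order = c("first", "second"),
                   n_boot = 1000, seed = 20230913, level = 0.95) {
  methods <- match.arg(methods, several.ok = TRUE)
  model <- match.arg(model)
  se_order <- match.arg(se_order)
  if (!inherits(h, "mr_instruments")) h <- mr_instruments(h)
  est <- list()
  if ("ivw" %in% methods) {
    est$ivw <- mr_ivw(h, model = model, se_order = se_order, level = level)
  }
  if ("egger" %in% methods) {
    est$egger <- mr_egger(h, level = level)
  }
  if ("weighted_median" %in% methods) {
    est$weighted_median <- mr_weighted_median(
      h, n_boot = n_boot, seed = seed, se_order = se_order, level = level)
  }
  structure(list(instruments = h, estimates = est,
                 settings = list(model = model, se_order = se_order,
                                 n_boot = n_boot, seed = seed,
                                 level = level),
                 call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat("Two-sample MR fit:", nrow(x$instruments), "instruments\n\n")
  tab <- as.data.frame(x)
  tab_fmt <- tab
  num <- vapply(tab_fmt, is.numeric, logical(1))
  tab_fmt[num] <- lapply(tab_fmt[num], round, digits = digits)
  print.data.frame(tab_fmt, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  do.call(rbind, lapply(x$estimates, as.data.frame))
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level, ...) {
  m <- t(vapply(object$estimates,
                function(e) c(e$ci_low, e$ci_high), numeric(2)))
  colnames(m) <- c("low", "high")
  m
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  e <- object$estimates[[method]]
  if (is.null(e)) stop("method '", method, "' not in fit", call. = FALSE)
  h <- object$instruments
  r <- h$beta_outcome - e$beta * h$beta_exposure
  if (!is.null(e$intercept)) {
    r <- ifelse(sign(h$beta_exposure) == -1, -h$beta_outcome,
                h$beta_outcome) -
      e$intercept - e$beta * abs(h$beta_exposure)
  }
  stats::setNames(r, h$snp)
}

#' @export
summary.mr_fit <- function(object, n_sim = 1000, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$settings$seed
  structure(list(fit = object,
                 sensitivity = mr_sensitivity(
                   object$instruments, n_sim = n_sim, seed = seed,
                   se_order = object$settings$se_order)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\n")
  print(x$sensitivity, digits = digits)
  invisible(x)
}

#' Scatter plot of a two-sample MR fit
#'
#' Outcome betas against exposure betas with per-SNP error bars and one
#' fitted line per estimator (through the origin for IVW and weighted
#' median, with intercept for Egger). SNPs are oriented so exposure betas
#' are positive, matching the Egger parameterization.
#'
#' @param x An `mr_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, ...) {
  h <- x$instruments
  flip <- sign(h$beta_exposure) == -1
  bx <- abs(h$beta_exposure)
  by <- ifelse(flip, -h$beta_outcome, h$beta_outcome)
  graphics::plot(bx, by, pch = 19,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 xlim = c(0, max(bx + h$se_exposure)), ...)
  graphics::arrows(bx, by - h$se_outcome, bx, by + h$se_outcome,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  graphics::arrows(bx - h$se_exposure, by, bx + h$se_exposure, by,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  cols <- c(ivw = "black", egger = "firebrick",
            weighted_median = "steelblue")
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    a <- if (is.null(e$intercept)) 0 else e$intercept
    graphics::abline(a = a, b = e$beta, col = cols[[nm]],
                     lty = if (nm == "ivw") 1 else 2)
  }
  graphics::legend("topleft", bty = "n", lty = c(1, 2, 2),
                   col = cols[names(x$estimates)],
                   legend = names(x$estimates))
  invisible(x)
}

#' Funnel plot
#'
#' @param h An [mr_instruments] set.
#' @param ... Passed to [graphics::plot()].
#' @return The funnel coordinates, invisibly.
#' @export
plot_funnel <- function(h, ...) {
  fd <- funnel_data(h)
  graphics::plot(fd$ratio, fd$precision, pch = 19,
                 xlab = "Wald ratio", ylab = "Precision (1/SE)", ...)
  graphics::abline(v = attr(fd, "reference"), lty = 2)
  invisible(fd)
}
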