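#' Define a synthetic two-sample MR scenario
#'
#' Describes a generative model for two-sample GWAS summary statistics
#' with known ground truth. Per SNP `j`: a minor-allele frequency is
#' drawn uniformly from `maf_range`; a true exposure effect magnitude is
#' drawn uniformly from `beta_x_range` with random sign; sampling
#' standard errors follow the standardized-trait approximation
#' `SE = 1 / sqrt(2 MAF (1 - MAF) n)`; the observed exposure beta is the
#' true beta plus exposure-sample noise; the observed outcome beta is
#' `theta * beta_x + alpha_j` plus outcome-sample noise, where `alpha_j`
#' is the SNP's horizontal-pleiotropy effect (zero for valid SNPs,
#' `N(0, pleio_sd^2)` under balanced pleiotropy,
#' `N(pleio_mean, pleio_sd^2)` under directional pleiotropy, expressed in
#' the orientation whose allele increases the exposure; pleiotropy drawn
#' this way is independent of instrument strength, so the InSIDE
#' condition holds).
#'
#' Defaults mirror the shape of the telomere-length analysis: 15
#' instruments, exposure sample 78,592, outcome sample 309,154, exposure
#' effect magnitudes 0.03-0.09 SD per allele.
#'
#' @param k Number of instruments, >= 1.
#' @param theta True causal effect (log-odds per exposure SD), default 0.
#' @param maf_range MAF sampling interval, a sub-interval of (0, 0.5].
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param beta_x_range Range of true exposure effect magnitudes.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleio_mean Mean pleiotropic effect (directional regime only),
#'   default 0.02.
#' @param pleio_sd Pleiotropy standard deviation, default 0.01.
#' @param invalid_fraction Fraction of SNPs receiving pleiotropic
#'   effects, in \[0, 1\]; default 0 (1 under the pleiotropic regimes
#'   unless set).
#' @param palindromic_fraction Fraction of SNPs assigned A/T or C/G
#'   allele pairs, default 0.
#' @param seed Scenario seed, default 20230913.
#' @return A list of class `mr_scenario`.
#' @examples
#' sc <- mr_scenario(k = 10, theta = 0.1, seed = 1)
#' dat <- simulate(sc)
#' str(dat$truth)
#' @export
mr_scenario <- function(k = 15, theta = 0, maf_range = c(0.1, 0.5),
                        n_exposure = 78592, n_outcome = 309154,
                        beta_x_range = c(0.03, 0.09),
                        pleiotropy = c("none", "balanced", "directional"),
                        pleio_mean = 0.02, pleio_sd = 0.01,
                        invalid_fraction = NULL,
                        palindromic_fraction = 0, seed = 20230913) {
  pleiotropy <- match.arg(pleiotropy)
  if (is.null(invalid_fraction)) {
    invalid_fraction <- if (pleiotropy == "none") 0 else 1
  }
  stopifnot(k >= 1,
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            n_exposure > 0, n_outcome > 0,
            invalid_fraction >= 0, invalid_fraction <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            pleio_sd >= 0)
  if (maf_range[1] == maf_range[2] && maf_range[1] <= 0) {
    stop("degenerate maf_range", call. = FALSE)
  }
  structure(list(k = k, theta = theta, maf_range = maf_range,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 beta_x_range = beta_x_range, pleiotropy = pleiotropy,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 invalid_fraction = invalid_fraction,
                 palindromic_fraction = palindromic_fraction,
                 seed = seed),
            class = "mr_scenario")
}

#' @export
print.mr_scenario <- function(x, ...) {
  cat(sprintf(
    "MR scenario: k = %d, theta = %g, pleiotropy = %s (invalid fraction %g)\n",
    x$k, x$theta, x$pleiotropy, x$invalid_fraction))
  cat(sprintf("  n_exposure = %d, n_outcome = %d, MAF in [%g, %g], seed %d\n",
              x$n_exposure, x$n_outcome, x$maf_range[1], x$maf_range[2],
              x$seed))
  invisible(x)
}

#' Simulate summary statistics from a scenario
#'
#' Draws one (or `nsim`) two-sample summary-statistic dataset(s) from an
#' [mr_scenario()]. Output tables use the same canonical columns that
#' [read_association_table()] produces, so generated data flow through
#' [harmonize()] and the estimators unchanged. The `truth` element
#' carries everything needed to recompute each observed quantity's
#' generating mean: `theta`, the true per-SNP exposure effects, the
#' pleiotropic effects `alpha`, validity flags and MAFs.
#'
#' @param object An `mr_scenario`.
#' @param nsim Number of datasets, default 1.
#' @param seed Seed; defaults to the scenario's own seed. Fixed seed
#'   gives byte-identical output.
#' @param ... Unused.
#' @return For `nsim = 1` a list with `exposure`, `outcome` (class
#'   `mr_assoc`) and `truth`; otherwise a list of such lists.
#' @export
simulate.mr_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  s <- object
  if (is.null(seed)) seed <- s$seed
  out <- withr_seed(seed, {
    lapply(seq_len(nsim), function(i) generate_one(s))
  })
  if (nsim == 1) out[[1]] else out
}

generate_one <- function(s) {
  k <- s$k
  snp <- sprintf("rs%07d", seq_len(k))
  maf <- stats::runif(k, s$maf_range[1], s$maf_range[2])
  beta_x_true <- stats::runif(k, s$beta_x_range[1], s$beta_x_range[2]) *
    sample(c(-1, 1), k, replace = TRUE)
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * s$n_exposure)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * s$n_outcome)
  invalid <- stats::runif(k) < s$invalid_fraction
  alpha <- numeric(k)
  if (s$pleiotropy == "balanced") {
    alpha[invalid] <- stats::rnorm(sum(invalid), 0, s$pleio_sd)
  } else if (s$pleiotropy == "directional") {
    # directional relative to the exposure-increasing allele: in the
    # orientation with beta_x > 0 the pleiotropic shift has mean
    # pleio_mean, independent of instrument strength (InSIDE holds)
    alpha[invalid] <- sign(beta_x_true[invalid]) *
      stats::rnorm(sum(invalid), s$pleio_mean, s$pleio_sd)
  }
  beta_x <- stats::rnorm(k, beta_x_true, se_x)
  beta_y <- stats::rnorm(k, s$theta * beta_x_true + alpha, se_y)
  # allele pairs; palindromic_fraction of SNPs get strand-ambiguous pairs
  pal <- stats::runif(k) < s$palindromic_fraction
  pairs_np <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pairs_p <- list(c("A", "T"), c("C", "G"))
  al <- lapply(seq_len(k), function(j) {
    p <- if (pal[j]) sample(pairs_p, 1)[[1]] else sample(pairs_np, 1)[[1]]
    if (stats::runif(1) < 0.5) rev(p) else p
  })
  ea <- vapply(al, `[`, character(1), 1)
  oa <- vapply(al, `[`, character(1), 2)
  eaf <- ifelse(stats::runif(k) < 0.5, maf, 1 - maf)
  exposure <- data.frame(
    snp = snp, effect_allele = ea, other_allele = oa,
    beta = beta_x, se = se_x,
    pval = 2 * stats::pnorm(-abs(beta_x / se_x)),
    eaf = eaf, n = s$n_exposure, stringsAsFactors = FALSE)
  outcome <- data.frame(
    snp = snp, effect_allele = ea, other_allele = oa,
    beta = beta_y, se = se_y,
    pval = 2 * stats::pnorm(-abs(beta_y / se_y)),
    eaf = eaf, n = s$n_outcome, stringsAsFactors = FALSE)
  truth <- list(theta = s$theta, beta_x_true = beta_x_true, alpha = alpha,
                valid = !invalid | alpha == 0, maf = maf,
                scenario = s)
  list(exposure = validate_assoc(exposure, "synthetic exposure"),
       outcome = validate_assoc(outcome, "synthetic outcome"),
       truth = truth)
}

# instruments straight from a generated dataset (alleles agree by
# construction, so this equals harmonize() but without the overhead)
instruments_from_sim <- function(dat) {
  ex <- dat$exposure
  ou <- dat$outcome
  mr_instruments(data.frame(
    snp = ex$snp,
    beta_exposure = ex$beta, se_exposure = ex$se, pval_exposure = ex$pval,
    beta_outcome = ou$beta, se_outcome = ou$se, pval_outcome = ou$pval,
    eaf_exposure = ex$eaf, stringsAsFactors = FALSE))
}

#' Run a grid of simulation scenarios
#'
#' Draws `replicates` datasets from each scenario, fits the requested
#' estimators on every replicate, and summarizes bias, RMSE, confidence
#' interval coverage of the true effect, and rejection rate at the 0.05
#' level per method and scenario. For the Egger rows the intercept-test
#' rejection rate is reported as well. Per-replicate seeds are derived
#' deterministically from the base seed by a fixed counter, so the whole
#' grid is reproducible.
#'
#' @param scenarios A single [mr_scenario()] or a (optionally named)
#'   list of them.
#' @param replicates Replicates per scenario, >= 1; default 200.
#' @param seed Base seed, default 1.
#' @param methods Estimators to run per replicate.
#' @param n_boot Weighted-median bootstrap iterations per replicate
#'   (default 200; the bootstrap dominates grid runtime).
#' @return A data.frame of class `mr_grid` keyed by `scenario` and
#'   `method`, with columns `replicates`, `bias`, `rmse`, `coverage`,
#'   `rejection`, `intercept_rejection`.
#' @export
run_scenario_grid <- function(scenarios, replicates = 200, seed = 1,
                              methods = c("ivw", "egger",
                                          "weighted_median"),
                              n_boot = 200) {
  stopifnot(replicates >= 1)
  if (inherits(scenarios, "mr_scenario")) scenarios <- list(scenarios)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios)))) {
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  }
  methods <- match.arg(methods, several.ok = TRUE)
  counter <- 0L
  rows <- list()
  for (sc_name in names(scenarios)) {
    sc <- scenarios[[sc_name]]
    res <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      counter <- counter + 1L
      rep_seed <- (seed + 104729 * counter) %% 2147483647L
      dat <- simulate(sc, seed = rep_seed)
      h <- instruments_from_sim(dat)
      one <- list()
      if ("ivw" %in% methods) one$ivw <- mr_ivw(h)
      if ("egger" %in% methods) one$egger <- mr_egger(h)
      if ("weighted_median" %in% methods) {
        one$weighted_median <- mr_weighted_median(h, n_boot = n_boot,
                                                  seed = rep_seed + 1)
      }
      res[[r]] <- one
    }
    for (m in methods) {
      est <- vapply(res, function(x) x[[m]]$beta, numeric(1))
      lo <- vapply(res, function(x) x[[m]]$ci_low, numeric(1))
      hi <- vapply(res, function(x) x[[m]]$ci_high, numeric(1))
      p <- vapply(res, function(x) x[[m]]$pval, numeric(1))
      ip <- if (m == "egger") {
        mean(vapply(res, function(x) x[[m]]$intercept_pval,
                    numeric(1)) < 0.05)
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc_name, method = m, replicates = replicates,
        bias = mean(est) - sc$theta,
        rmse = sqrt(mean((est - sc$theta)^2)),
        coverage = mean(lo <= sc$theta & sc$theta <= hi),
        rejection = mean(p < 0.05),
        intercept_rejection = ip,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("mr_grid", "data.frame"))
}
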