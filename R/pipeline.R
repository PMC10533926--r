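#' Build and validate a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis into one validated
#' object. Configurations can also be read from YAML with
#' [read_mr_config()]; unknown keys are rejected in both cases.
#'
#' A single top-level `seed` governs both stochastic components
#' (weighted-median bootstrap and MR-PRESSO); stage sub-seeds are derived
#' from it deterministically, so rerunning the same configuration
#' reproduces the report exactly (up to timestamps).
#'
#' @param exposure,outcome Paths to association tables, or `NULL` when
#'   `fixture` is used.
#' @param fixture Name of a packaged dataset; currently
#'   `"ltl-constipation"`.
#' @param column_map_exposure,column_map_outcome Optional column
#'   mappings, see [read_association_table()].
#' @param p_exposure_max,p_outcome_min,exclude Instrument filters, see
#'   [filter_instruments()].
#' @param palindrome_policy,eaf_ambiguity_window See [harmonize()].
#' @param prune Apply [prune_by_distance()] (needs positions); default
#'   `FALSE` (pre-clumped input).
#' @param window_kb Pruning window, default 10,000 kb.
#' @param model,se_order,n_boot Estimator settings, see [mr_fit()].
#' @param n_sim,outlier_alpha MR-PRESSO settings.
#' @param maf Optional per-SNP MAF vector for [instrument_strength()].
#' @param n_exposure Exposure sample size for the F statistic.
#' @param seed Top-level seed, default 20230913.
#' @param out Output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @return A validated list of class `mr_config`.
#' @export
mr_config <- function(exposure = NULL, outcome = NULL, fixture = NULL,
                      column_map_exposure = NULL,
                      column_map_outcome = NULL,
                      p_exposure_max = 5e-8, p_outcome_min = 5e-8,
                      exclude = character(0),
                      palindrome_policy = "drop",
                      eaf_ambiguity_window = 0.08,
                      prune = FALSE, window_kb = 10000,
                      model = "random", se_order = "first",
                      n_boot = 1000, n_sim = 1000, outlier_alpha = 0.05,
                      maf = NULL, n_exposure = NULL,
                      seed = 20230913, out = NULL) {
  cfg <- as.list(environment())
  validate_config(cfg)
}

validate_config <- function(cfg) {
  allowed <- names(formals(mr_config))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(as.list(formals(mr_config))[
    setdiff(allowed, names(cfg))], cfg)
  # formals defaults may be unevaluated language objects
  cfg <- lapply(cfg, function(v) if (is.language(v)) eval(v) else v)
  if (is.null(cfg$fixture) && (is.null(cfg$exposure) || is.null(cfg$outcome))) {
    stop("config needs either a fixture name or exposure and outcome paths",
         call. = FALSE)
  }
  stopifnot(cfg$p_exposure_max > 0, cfg$p_exposure_max < 1,
            cfg$p_outcome_min > 0, cfg$p_outcome_min < 1,
            cfg$n_boot >= 1, cfg$n_sim >= 100,
            cfg$model %in% c("random", "fixed"),
            cfg$se_order %in% c("first", "second"),
            cfg$palindrome_policy %in% c("drop", "infer_by_eaf", "keep"))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "mr_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are arguments of [mr_config()].
#' @return A validated `mr_config`.
#' @export
read_mr_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a mapping", call. = FALSE)
  if (!is.null(cfg$exclude)) cfg$exclude <- as.character(cfg$exclude)
  validate_config(cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full two-sample MR pipeline
#'
#' Executes the analysis stages in order -- ingest, harmonize, filter,
#' (optionally) prune, estimate, sensitivity -- and assembles a report:
#' the instrument table, the estimate table (method, nSNP, OR, SE, p,
#' CI), the sensitivity block (Q statistics, Egger intercept, MR-PRESSO,
#' leave-one-out, funnel coordinates), the audit log accounting for every
#' input SNP, and seed/version provenance. With `out` set, the report is
#' written as TSV tables plus JSON.
#'
#' @param config An [mr_config()] (or the arguments to build one, passed
#'   via `...`).
#' @param ... Used to build a config when `config` is missing.
#' @return A list of class `mr_report`.
#' @examples
#' rep <- run_mr(mr_config(fixture = "ltl-constipation",
#'                         n_boot = 200, n_sim = 200))
#' rep$estimates
#' @export
run_mr <- function(config = NULL, ...) {
  if (is.null(config)) config <- mr_config(...)
  if (!inherits(config, "mr_config")) config <- validate_config(config)
  if (!is.null(config$fixture)) {
    if (config$fixture != "ltl-constipation") {
      stop("unknown fixture: ", config$fixture, call. = FALSE)
    }
    exp_tab <- stage("ingest", read_association_table(
      system.file("extdata", "ltl_exposure.tsv", package = "mrlite")))
    out_tab <- stage("ingest", read_association_table(
      system.file("extdata", "ltl_outcome_constipation.tsv",
                  package = "mrlite")))
    palindrome_policy <- "keep"  # fixture is published pre-harmonized
  } else {
    exp_tab <- stage("ingest", read_association_table(
      config$exposure, config$column_map_exposure))
    out_tab <- stage("ingest", read_association_table(
      config$outcome, config$column_map_outcome))
    palindrome_policy <- config$palindrome_policy
  }
  h <- stage("harmonize", harmonize(
    exp_tab, out_tab, palindrome_policy = palindrome_policy,
    eaf_ambiguity_window = config$eaf_ambiguity_window))
  h <- stage("filter", filter_instruments(
    h, p_exposure_max = config$p_exposure_max,
    p_outcome_min = config$p_outcome_min, exclude = config$exclude))
  if (isTRUE(config$prune)) {
    h <- stage("prune", prune_by_distance(h, window_kb = config$window_kb))
  }
  # deterministic per-stage sub-seeds from the single top-level seed
  seed_wm <- (config$seed + 1L) %% 2147483647L
  seed_presso <- (config$seed + 2L) %% 2147483647L
  fit <- stage("estimate", mr_fit(
    h, model = config$model, se_order = config$se_order,
    n_boot = config$n_boot, seed = seed_wm))
  sens <- stage("sensitivity", mr_sensitivity(
    h, n_sim = config$n_sim, outlier_alpha = config$outlier_alpha,
    seed = seed_presso, se_order = config$se_order))
  strength <- NULL
  if (!is.null(config$maf) || "eaf_exposure" %in% names(h)) {
    n_exp <- config$n_exposure %||% max(exp_tab$n %||% 0)
    if (!is.null(n_exp) && n_exp > nrow(h) + 1) {
      strength <- stage("strength",
                        instrument_strength(h, maf = config$maf, n = n_exp))
    }
  }
  report <- structure(list(
    instruments = as.data.frame(h),
    estimates = as.data.frame(fit),
    fit = fit,
    sensitivity = sens,
    strength = strength,
    audit = audit_log(h),
    n_input = length(union(exp_tab$snp, out_tab$snp)),
    provenance = list(
      package = "mrlite",
      version = as.character(utils::packageVersion("mrlite")),
      seed = config$seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "mr_report")
  if (!is.null(config$out)) write_report(report, config$out)
  report
}

#' @export
print.mr_report <- function(x, digits = 3, ...) {
  cat("MR analysis report (", nrow(x$instruments), " instruments)\n\n",
      sep = "")
  print(x$fit, digits = digits)
  cat("\n")
  print(x$sensitivity, digits = digits)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `instruments.tsv`, `estimates.tsv` (Table-2-style: method,
#' nSNP, OR, SE, p, CI bounds), `leave_one_out.tsv`, `funnel.tsv`,
#' `audit.log` and a machine-readable `report.json`.
#'
#' @param report An `mr_report` from [run_mr()].
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$instruments, file.path(dir, "instruments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  est <- report$estimates
  est_out <- data.frame(method = est$method, nsnp = est$nsnp,
                        or = round(est$or, 3), se = round(est$se, 3),
                        pval = round(est$pval, 3),
                        ci_low = round(est$or_ci_low, 3),
                        ci_high = round(est$or_ci_high, 3))
  utils::write.table(est_out, file.path(dir, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  loo <- as.data.frame(report$sensitivity$loo)
  utils::write.table(loo, file.path(dir, "leave_one_out.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fd <- report$sensitivity$funnel
  fd$ivw_reference <- attr(fd, "reference")
  utils::write.table(as.data.frame(fd), file.path(dir, "funnel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$audit, file.path(dir, "audit.log"))
  sens <- report$sensitivity
  json <- list(
    estimates = est,
    sensitivity = list(
      q_ivw = unclass(sens$q_ivw),
      q_egger = unclass(sens$q_egger),
      egger_intercept = sens$egger_intercept,
      presso = list(rss_obs = sens$presso$rss_obs,
                    global_pval = sens$presso$global_pval,
                    n_sim = sens$presso$n_sim,
                    outlier_pvals = as.list(sens$presso$outlier_pvals),
                    outliers = sens$presso$outliers),
      leave_one_out = loo),
    strength = if (!is.null(report$strength)) unclass(report$strength),
    audit = report$audit,
    n_input_snps = report$n_input,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Run a simulation scenario file
#'
#' Reads a YAML scenario description (keys are arguments of
#' [mr_scenario()], plus optional `replicates`, `methods`, `n_boot`),
#' runs [run_scenario_grid()], and optionally writes the summary table
#' as TSV.
#'
#' @param path YAML scenario file; may contain a single mapping or a
#'   list of named scenarios under `scenarios`.
#' @param replicates Replicates per scenario (overridden by the file).
#' @param seed Base seed.
#' @param out Optional output directory for `simulation.tsv`.
#' @return The `mr_grid` summary table.
#' @export
run_simulation <- function(path, replicates = 200, seed = 1, out = NULL) {
  spec <- yaml::read_yaml(path)
  if (!is.list(spec)) stop("invalid scenario file", call. = FALSE)
  replicates <- spec$replicates %||% replicates
  methods <- spec$methods %||% c("ivw", "egger", "weighted_median")
  n_boot <- spec$n_boot %||% 200
  spec$replicates <- spec$methods <- spec$n_boot <- NULL
  scen_args <- names(formals(mr_scenario))
  build <- function(lst, label) {
    unknown <- setdiff(names(lst), scen_args)
    if (length(unknown) > 0L) {
      stop("unknown scenario key(s) in ", label, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    do.call(mr_scenario, lst)
  }
  scenarios <- if (!is.null(spec$scenarios)) {
    lapply(spec$scenarios, build, label = "scenarios")
  } else {
    list(scenario1 = build(spec, label = path))
  }
  grid <- run_scenario_grid(scenarios, replicates = replicates,
                            seed = seed, methods = methods,
                            n_boot = n_boot)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(grid, file.path(out, "simulation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  grid
}
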