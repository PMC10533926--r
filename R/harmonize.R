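#' Construct a harmonized instrument set
#'
#' The unit of all estimation in the package: one row per SNP with paired
#' exposure and outcome effects expressed on a common effect-allele
#' orientation. Normally produced by [harmonize()]; the constructor is
#' exported so synthetic or pre-harmonized data can enter the pipeline
#' directly with the same validation.
#'
#' @param x A data.frame with columns `snp`, `beta_exposure`, `se_exposure`,
#'   `pval_exposure`, `beta_outcome`, `se_outcome`, `pval_outcome`, and
#'   optionally `effect_allele`, `other_allele`, `eaf_exposure`,
#'   `eaf_outcome`, `chrom`, `pos`, `action`.
#' @param audit Character vector of audit-log lines to attach.
#' @return `x` sorted by `snp`, classed `c("mr_instruments", "data.frame")`,
#'   with an `audit` attribute.
#' @export
mr_instruments <- function(x, audit = character(0)) {
  needed <- c("snp", "beta_exposure", "se_exposure", "pval_exposure",
              "beta_outcome", "se_outcome", "pval_outcome")
  miss <- setdiff(needed, names(x))
  if (length(miss) > 0L) {
    stop("instrument set lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$snp)) {
    stop("duplicate snp identifiers in instrument set", call. = FALSE)
  }
  if (any(x$se_exposure <= 0) || any(x$se_outcome <= 0)) {
    stop("all standard errors must be > 0", call. = FALSE)
  }
  if (!"action" %in% names(x)) x$action <- "kept-as-is"
  # deterministic iteration order
  x <- x[order(x$snp), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, audit = audit,
            class = unique(c("mr_instruments", "data.frame")))
}

#' @export
print.mr_instruments <- function(x, ...) {
  cat("Harmonized instrument set:", nrow(x), "SNPs\n")
  print.data.frame(x, ...)
  aud <- attr(x, "audit")
  if (length(aud) > 0L) {
    cat("Audit log (", length(aud), " entries); see audit_log(x)\n", sep = "")
  }
  invisible(x)
}

#' Audit log of an instrument set
#'
#' Every harmonization, filtering and pruning action is appended to a
#' line-oriented audit log carried on the instrument set.
#'
#' @param x An `mr_instruments` object.
#' @return Character vector of log lines.
#' @export
audit_log <- function(x) {
  attr(x, "audit") %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

append_audit <- function(x, lines) {
  attr(x, "audit") <- c(attr(x, "audit"), lines)
  x
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations to the exposure's effect-allele
#' orientation, SNP by SNP, over the intersection of the two tables:
#'
#' * outcome alleles identical to the exposure pair: kept as is;
#' * outcome alleles equal to the exposure pair swapped: the outcome beta
#'   changes sign (and `eaf` becomes `1 - eaf`), tag `outcome-flipped`;
#' * palindromic SNPs (A/T or C/G): removed under `palindrome_policy =
#'   "drop"`; under `"infer_by_eaf"` kept only when both effect-allele
#'   frequencies lie outside the ambiguity window around 0.5, oriented by
#'   frequency agreement; under `"keep"` the written allele labels are
#'   trusted (only appropriate for input that is already harmonized,
#'   such as a published instrument table);
#' * any other allele combination: tag `dropped-incompatible`.
#'
#' Every action is recorded in the audit log. Re-harmonizing an already
#' harmonized set against itself is a no-op.
#'
#' @param exposure,outcome Association tables (see
#'   [read_association_table()]); `snp` must be unique within each.
#' @param palindrome_policy `"drop"` (default, conservative),
#'   `"infer_by_eaf"`, or `"keep"`.
#' @param eaf_ambiguity_window Half-width `w` of the frequency window
#'   `[0.5 - w, 0.5 + w]` inside which a palindromic SNP is considered
#'   unresolvable (default 0.08).
#' @return An [mr_instruments] set of the retained SNPs. The full action
#'   tagging (including dropped SNPs) is in `attr(, "actions")`.
#' @examples
#' exp_tab <- read_association_table(
#'   system.file("extdata", "ltl_exposure.tsv", package = "mrlite"))
#' out_tab <- read_association_table(
#'   system.file("extdata", "ltl_outcome_constipation.tsv", package = "mrlite"))
#' h <- harmonize(exp_tab, out_tab)
#' table(h$action)
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "infer_by_eaf", "keep"),
                      eaf_ambiguity_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  for (nm in c("exposure", "outcome")) {
    tab <- get(nm)
    if (nrow(tab) == 0L) stop(nm, " table is empty", call. = FALSE)
    if (anyDuplicated(tab$snp)) {
      stop("duplicate snp identifiers in ", nm, " table", call. = FALSE)
    }
  }
  shared <- sort(intersect(exposure$snp, outcome$snp))
  if (length(shared) == 0L) {
    stop("no SNPs shared between exposure and outcome tables", call. = FALSE)
  }
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]
  audit <- paste0("harmonize: ", length(shared), " SNPs shared of ",
                  nrow(exposure), " exposure / ", nrow(outcome), " outcome")

  action <- character(length(shared))
  by <- ou$beta
  eafy <- if ("eaf" %in% names(ou)) ou$eaf else rep(NA_real_, nrow(ou))
  eafx <- if ("eaf" %in% names(ex)) ex$eaf else rep(NA_real_, nrow(ex))

  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  for (i in seq_along(shared)) {
    if (pal[i] && palindrome_policy != "keep") {
      if (!(same[i] || swapped[i])) {
        action[i] <- "dropped-incompatible"
      } else if (palindrome_policy == "drop") {
        action[i] <- "dropped-palindromic"
      } else if (is.na(eafx[i]) || is.na(eafy[i])) {
        action[i] <- "dropped-palindromic"
        warning("palindromic SNP ", shared[i],
                ": EAF missing, falling back to drop", call. = FALSE)
      } else {
        w <- eaf_ambiguity_window
        if (abs(eafx[i] - 0.5) <= w || abs(eafy[i] - 0.5) <= w) {
          action[i] <- "dropped-palindromic"
        } else if ((eafx[i] < 0.5) == (eafy[i] < 0.5)) {
          # frequencies agree: same strand and orientation as written
          action[i] <- "kept-as-is"
        } else {
          action[i] <- "outcome-flipped"
          by[i] <- -by[i]
          eafy[i] <- 1 - eafy[i]
        }
      }
    } else if (same[i]) {
      action[i] <- "kept-as-is"
    } else if (swapped[i]) {
      action[i] <- "outcome-flipped"
      by[i] <- -by[i]
      if (!is.na(eafy[i])) eafy[i] <- 1 - eafy[i]
    } else {
      action[i] <- "dropped-incompatible"
    }
    audit <- c(audit, paste0("harmonize: ", shared[i], " -> ", action[i]))
  }

  keep <- action %in% c("kept-as-is", "outcome-flipped")
  if (!any(keep)) {
    stop("harmonization removed every shared SNP", call. = FALSE)
  }
  h <- data.frame(
    snp = shared[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    pval_exposure = ex$pval[keep],
    beta_outcome = by[keep],
    se_outcome = ou$se[keep],
    pval_outcome = ou$pval[keep],
    action = action[keep],
    stringsAsFactors = FALSE
  )
  if (any(!is.na(eafx[keep]))) h$eaf_exposure <- eafx[keep]
  if (any(!is.na(eafy[keep]))) h$eaf_outcome <- eafy[keep]
  if ("chrom" %in% names(ex)) h$chrom <- ex$chrom[keep]
  if ("pos" %in% names(ex)) h$pos <- ex$pos[keep]
  out <- mr_instruments(h, audit = audit)
  attr(out, "actions") <- data.frame(snp = shared, action = action,
                                     stringsAsFactors = FALSE)
  out
}

#' Filter instruments by association thresholds and exclusion list
#'
#' Retains SNPs strongly associated with the exposure
#' (`pval_exposure < p_exposure_max`, strict), not associated with the
#' outcome at genome-wide significance (`pval_outcome > p_outcome_min`,
#' strict), and not on a user-supplied exclusion list (the hook for
#' curated confounder lookups). Each removal is recorded in the audit log
#' with its reason.
#'
#' @param h An [mr_instruments] set.
#' @param p_exposure_max Exposure significance threshold (default `5e-8`).
#' @param p_outcome_min Outcome p-value floor (default `5e-8`).
#' @param exclude Character vector of SNP identifiers to remove.
#' @return The filtered [mr_instruments] set.
#' @export
filter_instruments <- function(h, p_exposure_max = 5e-8,
                               p_outcome_min = 5e-8,
                               exclude = character(0)) {
  stopifnot(p_exposure_max > 0, p_exposure_max < 1,
            p_outcome_min > 0, p_outcome_min < 1)
  reason <- rep(NA_character_, nrow(h))
  reason[h$pval_exposure >= p_exposure_max] <-
    paste0("exposure p >= ", format(p_exposure_max))
  reason[is.na(reason) & h$pval_outcome <= p_outcome_min] <-
    paste0("outcome p <= ", format(p_outcome_min))
  reason[is.na(reason) & h$snp %in% exclude] <- "user exclusion"
  drop <- !is.na(reason)
  audit <- c(audit_log(h),
             paste0("filter: removed ", h$snp[drop], " (", reason[drop], ")"),
             paste0("filter: ", sum(!drop), " of ", nrow(h),
                    " instruments retained"))
  if (all(drop)) stop("no instruments survive filters", call. = FALSE)
  out <- h[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  attr(out, "actions") <- attr(h, "actions")
  out
}

#' Greedy distance-based instrument pruning
#'
#' Approximates linkage-disequilibrium clumping without a genotype
#' reference panel: SNPs are ranked by exposure p-value (ties broken by
#' identifier) and accepted greedily unless a previously accepted SNP on
#' the same chromosome lies within `window_kb`. When a pairwise LD table
#' is supplied, pairs with `r^2 >= ld_r2_max` are also excluded, mirroring
#' the usual clumping parameters (r^2 < 0.001, 10,000 kb).
#'
#' @param h An [mr_instruments] set with `chrom` and `pos` columns.
#' @param window_kb Exclusion window in kilobases (default 10,000).
#' @param require_positions If `TRUE` (default) error when positions are
#'   missing; if `FALSE`, SNPs without positions are kept and flagged in
#'   the audit log.
#' @param ld Optional data.frame with columns `snp1`, `snp2`, `r2` of
#'   pairwise LD estimates.
#' @param ld_r2_max LD threshold applied when `ld` is given (default 0.001).
#' @return The pruned [mr_instruments] set.
#' @export
prune_by_distance <- function(h, window_kb = 10000,
                              require_positions = TRUE,
                              ld = NULL, ld_r2_max = 0.001) {
  has_pos <- all(c("chrom", "pos") %in% names(h)) &&
    !anyNA(h$chrom) && !anyNA(h$pos)
  if (!has_pos && require_positions) {
    stop("chromosome/position columns required for distance pruning; ",
         "supply pre-clumped input or set require_positions = FALSE",
         call. = FALSE)
  }
  ord <- order(h$pval_exposure, h$snp)
  accepted <- integer(0)
  audit <- c(audit_log(h))
  ld_conflict <- function(a, b) {
    if (is.null(ld)) return(FALSE)
    hit <- (ld$snp1 == a & ld$snp2 == b) | (ld$snp1 == b & ld$snp2 == a)
    any(hit & ld$r2 >= ld_r2_max)
  }
  for (i in ord) {
    clash <- FALSE
    for (j in accepted) {
      near <- has_pos && !is.na(h$pos[i]) && !is.na(h$pos[j]) &&
        h$chrom[i] == h$chrom[j] &&
        abs(h$pos[i] - h$pos[j]) < window_kb * 1000
      if (near || ld_conflict(h$snp[i], h$snp[j])) {
        audit <- c(audit, paste0("prune: removed ", h$snp[i],
                                 " (within ", window_kb, " kb of ",
                                 h$snp[j], ")"))
        clash <- TRUE
        break
      }
    }
    if (!clash) {
      if (has_pos && (is.na(h$pos[i]))) {
        audit <- c(audit, paste0("prune: ", h$snp[i],
                                 " kept without position"))
      }
      accepted <- c(accepted, i)
    }
  }
  out <- h[sort(accepted), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- c(audit, paste0("prune: ", nrow(out), " of ",
                                        nrow(h), " instruments retained"))
  attr(out, "actions") <- attr(h, "actions")
  out
}

#' Instrument strength: variance explained and F statistic
#'
#' Per-SNP variance explained is `R^2_j = 2 MAF_j (1 - MAF_j) beta_j^2`
#' (standardized exposure), summed over instruments; the F statistic is
#' `F = (R^2 / (1 - R^2)) * ((n - k - 1) / k)` for `k` instruments and
#' exposure sample size `n`. Values below the conventional threshold of
#' 10 trigger a weak-instrument warning.
#'
#' @param h An [mr_instruments] set.
#' @param maf Minor-allele frequencies in (0, 0.5], one per SNP (recycled
#'   from `h$eaf_exposure` folded to MAF when omitted).
#' @param n Exposure GWAS sample size; must exceed `k + 1`.
#' @return A list of class `mr_strength` with `r2_total`, `f_stat`, `n`,
#'   `k` and `weak` (logical).
#' @export
instrument_strength <- function(h, maf = NULL, n) {
  k <- nrow(h)
  if (is.null(maf)) {
    if (!"eaf_exposure" %in% names(h)) {
      stop("maf must be supplied when the instrument set has no ",
           "eaf_exposure column", call. = FALSE)
    }
    maf <- pmin(h$eaf_exposure, 1 - h$eaf_exposure)
  }
  maf <- rep_len(maf, k)
  if (any(maf <= 0 | maf > 0.5)) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  if (n <= k + 1) stop("exposure sample size n must exceed k + 1",
                       call. = FALSE)
  r2 <- sum(2 * maf * (1 - maf) * h$beta_exposure^2)
  f <- (r2 / (1 - r2)) * ((n - k - 1) / k)
  weak <- f < 10
  if (weak) {
    warning("weak instruments: F = ", format(f, digits = 4), " < 10",
            call. = FALSE)
  }
  structure(list(r2_total = r2, f_stat = f, n = n, k = k, weak = weak),
            class = "mr_strength")
}

#' @export
print.mr_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: k = %d, n = %d\n", x$k, x$n))
  cat(sprintf("  total R^2 = %.4g, F = %.2f%s\n", x$r2_total, x$f_stat,
              if (x$weak) "  [weak: F < 10]" else ""))
  invisible(x)
}
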