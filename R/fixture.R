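#' The packaged LTL -> constipation instrument set
#'
#' The published 15-SNP instrument table for leukocyte telomere length
#' (exposure, ENGAGE/EPIC-CVD GWAS, n = 78,592) against constipation
#' (outcome, FinnGen GWAS, 26,919 cases / 282,235 controls), shipped as
#' two tab-separated association tables under `inst/extdata`. The table
#' is published post-harmonization (it includes A/T and C/G SNPs whose
#' orientation is already resolved), so it is loaded with
#' `palindrome_policy = "keep"` and [harmonize()] is a no-op on it
#' (every SNP tagged `kept-as-is`).
#'
#' @return An [mr_instruments] set of 15 SNPs.
#' @examples
#' h <- ltl_constipation()
#' nrow(h)
#' @export
ltl_constipation <- function() {
  exp_tab <- read_association_table(
    system.file("extdata", "ltl_exposure.tsv", package = "mrlite"))
  out_tab <- read_association_table(
    system.file("extdata", "ltl_outcome_constipation.tsv",
                package = "mrlite"))
  harmonize(exp_tab, out_tab, palindrome_policy = "keep")
}
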