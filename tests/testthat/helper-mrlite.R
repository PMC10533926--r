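# shared builders for the test suite; everything is generated in code

# the packaged 15-SNP telomere-length -> constipation instrument set
tbl1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- ltl_constipation()
    cache
  }
})

# a small hand-sized instrument set with known numbers
make_instruments <- function(bx, by, sx = rep(0.01, length(bx)),
                             sy = rep(0.01, length(bx)),
                             snp = sprintf("rs%03d", seq_along(bx))) {
  mr_instruments(data.frame(
    snp = snp,
    beta_exposure = bx, se_exposure = sx,
    pval_exposure = 2 * pnorm(-abs(bx / sx)),
    beta_outcome = by, se_outcome = sy,
    pval_outcome = 2 * pnorm(-abs(by / sy)),
    stringsAsFactors = FALSE))
}

# association tables for a set of SNPs with non-palindromic alleles
make_assoc_pair <- function(k = 8, seed = 101) {
  set.seed(seed)
  pairs <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  al <- pairs[sample(length(pairs), k, replace = TRUE)]
  data_for <- function(beta, se) {
    validate_assoc(data.frame(
      snp = sprintf("rs%04d", seq_len(k)),
      effect_allele = vapply(al, `[`, character(1), 1),
      other_allele = vapply(al, `[`, character(1), 2),
      beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)),
      eaf = runif(k, 0.05, 0.95), stringsAsFactors = FALSE))
  }
  bx <- runif(k, 0.03, 0.1) * sample(c(-1, 1), k, replace = TRUE)
  list(exposure = data_for(bx, runif(k, 0.004, 0.01)),
       outcome = data_for(0.1 * bx + rnorm(k, 0, 0.01),
                          runif(k, 0.008, 0.02)))
}

# flip a row's reported orientation: EA <-> OA, beta -> -beta, eaf -> 1 - eaf
flip_rows <- function(tab, idx) {
  ea <- tab$effect_allele[idx]
  tab$effect_allele[idx] <- tab$other_allele[idx]
  tab$other_allele[idx] <- ea
  tab$beta[idx] <- -tab$beta[idx]
  if ("eaf" %in% names(tab)) tab$eaf[idx] <- 1 - tab$eaf[idx]
  tab
}

# deterministic numeric comparison at printed (3-decimal) precision
expect_printed <- function(value, printed, tol = 1e-3) {
  expect_lt(abs(value - printed), tol + 1e-12)
}
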