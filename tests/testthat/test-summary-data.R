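test_that("association tables round-trip through the TSV dialect", {
  pair <- make_assoc_pair(k = 5, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(pair$exposure, path)
  back <- read_association_table(path)
  for (col in c("snp", "effect_allele", "other_allele")) {
    expect_identical(back[[col]], pair$exposure[[col]])
  }
  for (col in c("beta", "se", "pval", "eaf")) {
    expect_equal(back[[col]], pair$exposure[[col]], tolerance = 1e-12)
  }
})

test_that("the packaged exposure table parses the printed values", {
  exp_tab <- read_association_table(
    system.file("extdata", "ltl_exposure.tsv", package = "mrlite"))
  rec <- exp_tab[exp_tab$snp == "rs10936600", ]
  expect_equal(rec$beta, -0.086)
  expect_equal(rec$se, 0.006)
  expect_equal(rec$pval, 1.35e-46)
  expect_identical(rec$effect_allele, "T")
  expect_equal(nrow(exp_tab), 15L)
})

test_that("reader reports configuration and row-level errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("snp\teffect_allele\tother_allele\tbeta\tse\tpval", path)
  expect_error(read_association_table(path), "empty table")

  writeLines(c("rsid\tea\toa\tbeta\tse\tpval",
               "rs1\tA\tG\t0.1\t0.01\t0.5"), path)
  expect_error(read_association_table(path), "required column 'snp'")
  got <- read_association_table(
    path, column_map = c(snp = "rsid", effect_allele = "ea",
                         other_allele = "oa"))
  expect_equal(got$beta, 0.1)

  writeLines(c("snp\teffect_allele\tother_allele\tbeta\tse\tpval",
               "rs1\tA\tG\t0.1\t0.01\t0.5",
               "rs2\tA\tG\tnot_a_number\t0.01\t0.5"), path)
  expect_error(read_association_table(path), "line 3")

  # invariant violations carry line numbers too
  writeLines(c("snp\teffect_allele\tother_allele\tbeta\tse\tpval",
               "rs1\tA\tA\t0.1\t0.01\t0.5",
               "rs2\tAT\tG\t0.1\t0.01\t0.5",
               "rs3\tA\tG\t0.1\t0\t0.5"), path)
  err <- tryCatch(read_association_table(path), error = conditionMessage)
  expect_match(err, "effect_allele equals other_allele \\(line 2\\)")
  expect_match(err, "not a single base")
  expect_match(err, "se missing or not > 0 \\(line 4\\)")
})

test_that("harmonization aligns, flips, and drops as tagged", {
  pair <- make_assoc_pair(k = 6, seed = 3)
  h0 <- harmonize(pair$exposure, pair$outcome)
  expect_true(all(h0$action == "kept-as-is"))

  # swapped outcome alleles flip the outcome beta back
  flipped <- flip_rows(pair$outcome, 2)
  h1 <- harmonize(pair$exposure, flipped)
  tag <- attr(h1, "actions")
  expect_identical(tag$action[tag$snp == pair$outcome$snp[2]],
                   "outcome-flipped")
  expect_equal(h1$beta_outcome, h0$beta_outcome, tolerance = 0)

  # incompatible allele pair is dropped with its tag
  bad <- pair$outcome
  bad$effect_allele[3] <- setdiff(c("A", "C", "G", "T"),
                                  c(bad$effect_allele[3],
                                    bad$other_allele[3]))[1]
  h2 <- harmonize(pair$exposure, bad)
  tag2 <- attr(h2, "actions")
  expect_identical(tag2$action[tag2$snp == bad$snp[3]],
                   "dropped-incompatible")
  expect_false(bad$snp[3] %in% h2$snp)
  expect_true(any(grepl("dropped-incompatible", audit_log(h2))))

  dup <- rbind(pair$exposure, pair$exposure[1, ])
  expect_error(harmonize(dup, pair$outcome), "duplicate")
})

test_that("palindromic SNPs follow the policy", {
  pair <- make_assoc_pair(k = 4, seed = 11)
  for (tab in c("exposure", "outcome")) {
    pair[[tab]]$effect_allele[1] <- "A"
    pair[[tab]]$other_allele[1] <- "T"
  }
  # default policy: drop
  h <- harmonize(pair$exposure, pair$outcome)
  expect_identical(attr(h, "actions")$action[1], "dropped-palindromic")

  # maximal ambiguity: EAF 0.5 stays dropped under infer_by_eaf
  pair$exposure$eaf[1] <- 0.5
  pair$outcome$eaf[1] <- 0.5
  h <- harmonize(pair$exposure, pair$outcome,
                 palindrome_policy = "infer_by_eaf",
                 eaf_ambiguity_window = 0.08)
  expect_identical(attr(h, "actions")$action[1], "dropped-palindromic")

  # informative frequencies on opposite sides: orientation flipped
  pair$exposure$eaf[1] <- 0.12
  pair$outcome$eaf[1] <- 0.85
  h <- harmonize(pair$exposure, pair$outcome,
                 palindrome_policy = "infer_by_eaf")
  i <- which(h$snp == pair$exposure$snp[1])
  expect_identical(h$action[i], "outcome-flipped")
  expect_equal(h$beta_outcome[i], -pair$outcome$beta[1])

  # agreeing frequencies: kept as written
  pair$outcome$eaf[1] <- 0.15
  h <- harmonize(pair$exposure, pair$outcome,
                 palindrome_policy = "infer_by_eaf")
  expect_identical(h$action[h$snp == pair$exposure$snp[1]], "kept-as-is")

  # missing EAF falls back to drop, with a warning
  pair$exposure$eaf[1] <- NA
  expect_warning(
    h <- harmonize(pair$exposure, pair$outcome,
                   palindrome_policy = "infer_by_eaf"),
    "EAF missing")
  expect_identical(attr(h, "actions")$action[1], "dropped-palindromic")
})

test_that("harmonization is idempotent and orientation-symmetric", {
  pair <- make_assoc_pair(k = 10, seed = 21)
  h <- harmonize(pair$exposure, pair$outcome)
  # feed the harmonized set back in as a pair of tables
  as_exposure <- data.frame(snp = h$snp, effect_allele = h$effect_allele,
                            other_allele = h$other_allele,
                            beta = h$beta_exposure, se = h$se_exposure,
                            pval = h$pval_exposure)
  as_outcome <- data.frame(snp = h$snp, effect_allele = h$effect_allele,
                           other_allele = h$other_allele,
                           beta = h$beta_outcome, se = h$se_outcome,
                           pval = h$pval_outcome)
  h2 <- harmonize(as_exposure, as_outcome)
  for (col in c("snp", "beta_exposure", "beta_outcome", "se_outcome",
                "action")) {
    expect_identical(h2[[col]], h[[col]])
  }

  # flipping the reported orientation of outcome rows changes nothing
  h_flip <- harmonize(pair$exposure, flip_rows(pair$outcome, c(1, 4, 7)))
  expect_identical(h_flip$beta_outcome, h$beta_outcome)
  expect_identical(mr_ivw(h_flip)$beta, mr_ivw(h)$beta)
  expect_identical(mr_egger(h_flip)$se, mr_egger(h)$se)

  # flipping exposure rows leaves every estimator output identical
  h_flip_x <- harmonize(flip_rows(pair$exposure, c(2, 5)), pair$outcome)
  expect_identical(mr_ivw(h_flip_x)$beta, mr_ivw(h)$beta)
  expect_identical(mr_ivw(h_flip_x)$se, mr_ivw(h)$se)
  expect_identical(mr_egger(h_flip_x)$beta, mr_egger(h)$beta)
  wr_a <- wald_ratios(h_flip_x)
  wr_b <- wald_ratios(h)
  expect_identical(wr_a$ratio, wr_b$ratio)
})

test_that("instrument filters apply strict thresholds and exclusions", {
  h <- tbl1()
  # all 15 printed SNPs survive the genome-wide defaults
  kept <- filter_instruments(h)
  expect_equal(nrow(kept), 15L)

  # boundary: exposure p exactly at, or above, the threshold is removed
  h2 <- tbl1()
  h2$pval_exposure[1] <- 1e-7
  expect_equal(nrow(filter_instruments(h2)), 14L)
  h2$pval_exposure[1] <- 5e-8
  expect_equal(nrow(filter_instruments(h2)), 14L)

  # exclusion list removes named SNPs and logs the reason
  kept2 <- filter_instruments(h, exclude = c("rs228595", "rs7705526"))
  expect_equal(nrow(kept2), 13L)
  expect_true(any(grepl("user exclusion", audit_log(kept2))))

  expect_error(filter_instruments(h, p_exposure_max = 1e-60),
               "no instruments survive")
})

test_that("shrinking the exposure threshold or growing the outcome floor never adds SNPs", {
  pair <- make_assoc_pair(k = 30, seed = 33)
  h <- harmonize(pair$exposure, pair$outcome)
  p_exp <- c(1e-4, 1e-6, 5e-8, 1e-10)
  p_out <- c(1e-10, 5e-8, 1e-4, 1e-2)
  prev <- NULL
  for (p in p_exp) {
    snps <- tryCatch(filter_instruments(h, p_exposure_max = p,
                                        p_outcome_min = 1e-10)$snp,
                     error = function(e) character(0))
    if (!is.null(prev)) expect_true(all(snps %in% prev))
    prev <- snps
  }
  prev <- NULL
  for (p in p_out) {
    snps <- tryCatch(filter_instruments(h, p_exposure_max = 1e-4,
                                        p_outcome_min = p)$snp,
                     error = function(e) character(0))
    if (!is.null(prev)) expect_true(all(snps %in% prev))
    prev <- snps
  }
})

test_that("distance pruning matches an all-pairs oracle", {
  # two SNPs 5,000 kb apart: only the smaller p survives a 10,000 kb window
  h <- make_instruments(bx = c(0.1, 0.08), by = c(0.01, 0.008))
  h$chrom <- c("1", "1")
  h$pos <- c(1e6, 1e6 + 5000 * 1000)
  h$pval_exposure <- c(1e-50, 1e-20)
  pruned <- prune_by_distance(h)
  expect_identical(pruned$snp, "rs001")

  # different chromosomes: the window never spans them
  h$chrom <- c("1", "2")
  expect_equal(nrow(prune_by_distance(h)), 2L)

  # positions missing without override is an error pointing at pre-clumped input
  h$pos <- NA_real_
  expect_error(prune_by_distance(h), "pre-clumped")

  # randomized sets against a brute-force pairwise check
  set.seed(99)
  for (rep in 1:5) {
    k <- 30
    hh <- make_instruments(bx = runif(k, 0.02, 0.1),
                           by = rnorm(k, 0, 0.01))
    hh$chrom <- as.character(sample(1:3, k, replace = TRUE))
    hh$pos <- runif(k, 0, 8e7)
    hh$pval_exposure <- runif(k, 1e-30, 1e-8)
    window_kb <- 10000
    pruned <- prune_by_distance(hh, window_kb = window_kb)
    # every accepted pair is far apart
    for (i in seq_len(nrow(pruned))) {
      for (j in seq_len(nrow(pruned))) {
        if (i < j && pruned$chrom[i] == pruned$chrom[j]) {
          expect_gte(abs(pruned$pos[i] - pruned$pos[j]), window_kb * 1000)
        }
      }
    }
    # every rejected SNP clashes with an accepted SNP of smaller p
    rejected <- hh[!hh$snp %in% pruned$snp, ]
    for (i in seq_len(nrow(rejected))) {
      clash <- pruned$chrom == rejected$chrom[i] &
        abs(pruned$pos - rejected$pos[i]) < window_kb * 1000 &
        (pruned$pval_exposure < rejected$pval_exposure[i] |
           (pruned$pval_exposure == rejected$pval_exposure[i] &
              pruned$snp < rejected$snp[i]))
      expect_true(any(clash))
    }
  }
})

test_that("a user LD table removes correlated pairs", {
  h <- make_instruments(bx = c(0.1, 0.08, 0.05), by = c(0.01, 0.008, 0.004))
  h$chrom <- c("1", "2", "3")
  h$pos <- c(1e6, 1e6, 1e6)
  h$pval_exposure <- c(1e-50, 1e-20, 1e-10)
  ld <- data.frame(snp1 = "rs001", snp2 = "rs002", r2 = 0.5)
  pruned <- prune_by_distance(h, ld = ld)
  expect_identical(sort(pruned$snp), c("rs001", "rs003"))
})

test_that("instrument strength follows the stated R2 and F formulas", {
  # null effects
  h <- make_instruments(bx = c(0, 0, 0), by = c(0, 0, 0))
  h$beta_exposure <- c(0, 0, 0)
  st <- suppressWarnings(instrument_strength(h, maf = 0.3, n = 1000))
  expect_equal(st$r2_total, 0)
  expect_equal(st$f_stat, 0)

  # hand calculation: one SNP, MAF 0.5, beta 0.1, n 10,002
  h1 <- make_instruments(bx = 0.1, by = 0.01)
  st1 <- instrument_strength(h1, maf = 0.5, n = 10002)
  expect_equal(st1$r2_total, 0.005)
  expect_equal(st1$f_stat, (0.005 / 0.995) * 10000, tolerance = 1e-12)
  expect_false(st1$weak)

  # formula inversion at the study's scale: k = 15, n = 78,592 and total
  # R2 chosen to give F ~ 200.56
  r2_target <- 0.0368748
  k <- 15
  beta <- sqrt(r2_target / (k * 2 * 0.25 * 0.75))
  hk <- make_instruments(bx = rep(beta, k), by = rep(0.01, k))
  stk <- instrument_strength(hk, maf = rep(0.25, k), n = 78592)
  expect_equal(stk$f_stat, 200.56, tolerance = 0.01)

  expect_warning(instrument_strength(h1, maf = 0.01, n = 10002), "weak")
  expect_error(instrument_strength(h1, maf = 0.6, n = 100), "maf")
  expect_error(instrument_strength(h1, maf = 0.3, n = 2), "exceed")
})
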