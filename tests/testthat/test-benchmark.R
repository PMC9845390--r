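test_that("effective tests: independence and duplicate blocks are exact", {
  expect_equal(effective_tests(diag(10))$meff, 10, tolerance = 1e-12)
  # five independent traits each duplicated: block correlation matrix with
  # eigenvalues five 2s and five 0s
  R <- kronecker(diag(5), matrix(1, 2, 2))
  res <- effective_tests(R)
  expect_equal(res$meff, 5, tolerance = 1e-9)
  expect_equal(res$m_observed, 10L)
  # empirical duplicates land within sampling error of the block answer
  set.seed(501)
  base <- matrix(rnorm(200 * 5), ncol = 5)
  expect_lt(abs(effective_tests(cbind(base, base))$meff - 5), 0.1)
  expect_error(effective_tests(matrix(rnorm(10), ncol = 1)), "2 phenotype")
})

test_that("effective tests match an independently coded evaluation", {
  R <- 0.9^abs(outer(1:20, 1:20, "-"))
  res <- effective_tests(R)
  expect_equal(res$meff, oracle_meff_galwey(R), tolerance = 1e-8)
  # li_ji alternative stays between 1 and m
  lj <- effective_tests(R, method = "li_ji")
  expect_gte(lj$meff, 1); expect_lte(lj$meff, 20)
  # data matrix and its correlation matrix agree
  set.seed(502)
  X <- matrix(rnorm(500 * 6), ncol = 6)
  expect_equal(effective_tests(X)$meff,
               effective_tests(stats::cor(X))$meff, tolerance = 1e-12)
})

test_that("covariate adjustment changes the eigenstructure it should", {
  set.seed(503)
  z <- rnorm(300)
  X <- cbind(a = z + rnorm(300, sd = 0.3), b = z + rnorm(300, sd = 0.3),
             c = rnorm(300), d = rnorm(300))
  raw <- effective_tests(X)$meff
  adj <- effective_tests(X, covariates = cbind(z))$meff
  expect_gt(adj, raw)  # removing the shared factor decorrelates a and b
})

test_that("the published effective count yields the published threshold", {
  expect_equal(signif(significance_threshold(46.1), 3), 0.00108)
})

test_that("significance filtering keeps pairs with one significant version", {
  pairs <- data.frame(
    item = c("a_prop", "b_prop", "c_prop"), class = "proportion",
    crude_h2 = c(0.1, 0.05, 0.2), crude_se = 0.02,
    crude_p = c(0.1, 0.5, 0.0005),
    eb_h2 = c(0.12, 0.04, 0.18), eb_se = 0.02,
    eb_p = c(0.0005, 0.2, 0.5), stringsAsFactors = FALSE)
  kept <- significance_filter(pairs, 46.1)
  expect_setequal(kept$item, c("a_prop", "c_prop"))
  expect_equal(attr(kept, "threshold"), 0.05 / 46.1)
  expect_error(significance_filter(pairs[, -5], 46.1), "both versions")
})

test_that("winners, win rates and quartiles are counted correctly", {
  set.seed(504)
  n <- 8L
  pairs <- data.frame(
    item = paste0("i", 1:n, "_prop"), class = "proportion",
    crude_h2 = rep(0.1, n), crude_se = 0.01, crude_p = 1e-5,
    eb_h2 = c(rep(0.12, 6), rep(0.08, 2)), eb_se = 0.01, eb_p = 1e-5,
    stringsAsFactors = FALSE)
  icc <- data.frame(item = pairs$item, icc = seq(0.1, 0.8, length.out = n),
                    stringsAsFactors = FALSE)
  cmp <- compare_versions(pairs, icc)
  expect_equal(cmp$win_rates$eb_win_rate[cmp$win_rates$stratum == "overall"],
               0.75)
  # quartile counts partition the retained set
  expect_identical(sum(cmp$quartile_rates$n), n)
  expect_true(all(cmp$quartile_rates$n == 2))
  # exact ties are "equal"
  tie <- pairs[1, ]; tie$eb_h2 <- tie$crude_h2
  cmp_tie <- compare_versions(rbind(tie, pairs[2, ]), icc)
  expect_identical(cmp_tie$table$winner[1], "equal")
  expect_error(compare_versions(pairs, icc[-1, ]), "icc missing")
})

test_that("clumping respects window distance and significance", {
  ss <- data.frame(
    SNP = c("s1", "s2", "s3"), CHR = "1",
    BP = c(1e6, 1.1e6, 2e6),
    P = c(1e-10, 1e-9, 0.5), stringsAsFactors = FALSE)
  # two significant SNPs 100 kb apart collapse into one locus
  loci <- clump_loci(ss, p_threshold = 5e-8, window_bp = 5e5)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$lead_snp, "s1")
  # 600 kb apart: two loci
  ss$BP[2] <- 1.6e6
  loci2 <- clump_loci(ss, p_threshold = 5e-8, window_bp = 5e5)
  expect_identical(nrow(loci2), 2L)
  expect_setequal(loci2$lead_snp, c("s1", "s2"))
  # nothing significant: empty result
  expect_identical(nrow(clump_loci(ss, p_threshold = 1e-20)), 0L)
})

test_that("greedy clumping matches the brute-force re-scan oracle", {
  set.seed(505)
  for (rep in 1:5) {
    ss <- data.frame(
      SNP = sprintf("s%03d", 1:50), CHR = sample(c("1", "2"), 50, TRUE),
      BP = sample(1:3000, 50) * 1000,
      P = 10^runif(50, -12, -8), stringsAsFactors = FALSE)
    loci <- clump_loci(ss, p_threshold = 5e-8, window_bp = 5e5)
    expect_identical(loci$lead_snp, oracle_clump(ss, 5e-8, 5e5))
    # row-order invariance
    perm <- ss[sample(50), ]
    expect_identical(clump_loci(perm, 5e-8, 5e5)$lead_snp, loci$lead_snp)
  }
})

test_that("locus concordance counts windows and strata correctly", {
  mk_loci <- function(ph, bp, p) {
    data.frame(lead_snp = paste0(ph, "_", seq_along(bp)), chr = "1", bp = bp,
               p = p, phenotype = ph, version = NA_character_,
               window_start = bp - 5e5, window_end = bp + 5e5,
               stringsAsFactors = FALSE)
  }
  # 4 windows across 2 phenotypes; 3 concordant by construction
  crude <- rbind(mk_loci("a", c(1e6, 5e6), c(1e-10, 1e-9)),
                 mk_loci("b", c(1e6, 5e6), c(1e-9, 1e-11)))
  eb <- rbind(mk_loci("a", c(1e6, 5e6), c(1e-12, 1e-10)),
              mk_loci("b", c(1e6, 5e6), c(1e-10, 1e-9)))
  h2p <- data.frame(item = c("a", "b"), crude_h2 = c(0.1, 0.3),
                    eb_h2 = c(0.2, 0.2), stringsAsFactors = FALSE)
  # phenotype a: eb more heritable, eb stronger in both windows (concordant x2)
  # phenotype b: crude more heritable; window1 eb stronger (discordant),
  # window2 crude stronger (concordant)
  res <- locus_concordance(crude, eb, h2p)
  expect_identical(res$n_windows, 4L)
  expect_equal(res$concordance, 0.75)
  # zero loci: flagged absent, not NaN
  none <- crude[0, ]
  res0 <- locus_concordance(none, none, h2p)
  expect_identical(res0$n_windows, 0L)
  expect_true(is.na(res0$concordance))
})

test_that("percent-difference stratification matches a hand-built table", {
  set.seed(506)
  phs <- sprintf("p%02d", 1:20)
  pdiff_target <- seq(5, 100, length.out = 20)  # percent differences
  crude_h2 <- rep(0.2, 20)
  eb_h2 <- crude_h2 * (200 + pdiff_target) / (200 - pdiff_target)
  crude <- do.call(rbind, lapply(seq_along(phs), function(i) {
    data.frame(lead_snp = paste0("c", i), chr = "1", bp = 1e6, p = 1e-9,
               phenotype = phs[i], version = NA, window_start = 5e5,
               window_end = 1.5e6, stringsAsFactors = FALSE)
  }))
  eb <- crude; eb$lead_snp <- paste0("e", seq_along(phs))
  # eb stronger (hence concordant, since eb h2 is higher) for first 10 only
  eb$p <- c(rep(1e-12, 10), rep(1e-6, 10))
  h2p <- data.frame(item = phs, crude_h2 = crude_h2, eb_h2 = eb_h2,
                    stringsAsFactors = FALSE)
  res <- locus_concordance(crude, eb, h2p)
  expect_identical(res$n_windows, 20L)
  # hand-computed: concordant exactly where eb led (10/20)
  expect_equal(res$concordance, 0.5)
  # verify the symmetric percent difference computation
  got <- res$windows$h2_pct_diff[match(phs, res$windows$phenotype)]
  expect_equal(got, 200 * abs(crude_h2 - eb_h2) / (crude_h2 + eb_h2),
               tolerance = 1e-9)
  # top-25% stratum: the 5 largest percent differences, all discordant here
  expect_equal(res$strata[["top25"]], 0)
})
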