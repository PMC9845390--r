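test_that("crude derivations average over all questionnaires including zeros", {
  expect_equal(derive_crude(c(1, 0, 1, 0))$proportion, 0.5)
  expect_equal(derive_crude(c(1, 0, 0, 1), c(2, 0, 0, 2))$average, 1.0)
  expect_equal(derive_crude(1)$proportion, 1.0)
  expect_error(derive_crude(numeric(0)), "zero questionnaires")
})

test_that("zero-one-inflated beta fit recovers known parameters", {
  set.seed(101)
  x <- c(rbeta(20000, 2, 5), rep(0, 5000))
  p <- fit_zoib(x)
  expect_true(p$converged)
  expect_equal(p$p0, 0.2)
  expect_gt(p$alpha, 1.8); expect_lt(p$alpha, 2.2)
  expect_gt(p$beta, 4.5); expect_lt(p$beta, 5.5)
  # uniform interior values are Beta(1, 1)
  pu <- fit_zoib(runif(20000))
  expect_lt(abs(pu$alpha - 1), 0.1)
  expect_lt(abs(pu$beta - 1), 0.1)
})

test_that("beta fit agrees with a grid-search likelihood oracle", {
  set.seed(102)
  x <- rbeta(5000, 1.7, 3.1)
  p <- fit_zoib(x)
  ref <- oracle_beta_grid(x)
  expect_lt(abs(p$alpha - ref[1]), 1e-3)
  expect_lt(abs(p$beta - ref[2]), 1e-3)
})

test_that("nearly homogeneous items fall back to a donor prior", {
  set.seed(103)
  good <- fit_zoib(rbeta(500, 2, 2), item = "good", min_interior = 50)
  bad <- fit_zoib(c(rep(0, 500), 0.4, 0.5, 0.6), item = "bad")
  expect_false(bad$converged)
  subst <- ebdiet:::substitute_donors(list(good = good, bad = bad))
  expect_true(subst$bad$converged)
  expect_identical(subst$bad$donor_item, "good")
  expect_equal(subst$bad$alpha, good$alpha)
  # without any converged prior the substitution is a hard error
  expect_error(ebdiet:::substitute_donors(list(bad = bad)), "donor")
  expect_error(eb_proportion(1, 2, bad), "donor")
})

test_that("EB proportion matches the posterior-mean formula and its identity", {
  pr <- fit_zoib(rbeta(200, 2, 5))
  pr$alpha <- 2; pr$beta <- 5; pr$converged <- TRUE
  expect_equal(eb_proportion(1, 2, pr), 3 / 9)
  pr11 <- pr; pr11$alpha <- 1; pr11$beta <- 1
  expect_equal(eb_proportion(0, 1, pr11), 1 / 3)
  expect_lt(abs(eb_proportion(5e5, 1e6, pr) - 0.5), 1e-5)
  # convex-combination identity at machine precision
  for (k in 1:5) for (s in 0:k) {
    w <- k / (k + pr$alpha + pr$beta)
    expect_equal(eb_proportion(s, k, pr),
                 w * s / k + (1 - w) * pr$alpha / (pr$alpha + pr$beta),
                 tolerance = 1e-12)
  }
  expect_error(eb_proportion(3, 2, pr), "s <= k")
})

test_that("EB proportion shrinks monotonically and vanishes in k", {
  pr <- fit_zoib(rbeta(200, 2, 5))
  pr$alpha <- 1.4; pr$beta <- 3.3; pr$converged <- TRUE
  # strictly increasing in s at fixed k
  vals <- eb_proportion(0:5, 5, pr)
  expect_true(all(diff(vals) > 0))
  # |EB - crude| halves when k doubles at fixed crude proportion
  ks <- 2^(6:12)
  gap <- abs(eb_proportion(ks / 2, ks, pr) - 0.5)
  ratio <- gap[-1] / gap[-length(gap)]
  expect_true(all(abs(ratio - 0.5) < 0.02))
  # EB lies weakly between crude and the prior mean
  m <- pr$alpha / (pr$alpha + pr$beta)
  for (k in 1:5) for (s in 0:k) {
    e <- eb_proportion(s, k, pr)
    expect_true(e >= min(s / k, m) - 1e-12 && e <= max(s / k, m) + 1e-12)
  }
})

test_that("Dirichlet-multinomial fit recovers known concentrations", {
  set.seed(104)
  n <- 20000
  k <- sample(1:5, n, TRUE)
  cnt <- r_dm_counts(n, c(1, 2, 3), k)
  colnames(cnt) <- 0:2
  f <- fit_dirichlet_multinomial(cnt)
  expect_true(f$converged)
  expect_true(all(abs(f$alpha / c(1, 2, 3) - 1) < 0.10))
  # determinism
  f2 <- fit_dirichlet_multinomial(cnt)
  expect_identical(f$alpha, f2$alpha)
})

test_that("Dirichlet-multinomial fit agrees with a direct optimizer", {
  set.seed(105)
  k <- sample(1:5, 5000, TRUE)
  cnt <- r_dm_counts(5000, c(0.8, 1.5, 2.5), k)
  colnames(cnt) <- 0:2
  f <- fit_dirichlet_multinomial(cnt)
  ref <- oracle_dm_optim(cnt)
  expect_true(all(abs(f$alpha - ref) < 1e-3))
})

test_that("symmetric two-category counts give a symmetric prior", {
  cnt <- matrix(rep(c(2, 3), each = 300), ncol = 2)
  cnt[seq(1, 300, 2), ] <- cnt[seq(1, 300, 2), 2:1]
  colnames(cnt) <- c(0, 1)
  f <- fit_dirichlet_multinomial(cnt)
  expect_lt(abs(f$alpha[1] / f$alpha[2] - 1), 1e-6)
  # single occupied category cannot be fit
  one <- matrix(c(rep(5, 50), rep(0, 50)), ncol = 2)
  colnames(one) <- c(0, 1)
  expect_false(fit_dirichlet_multinomial(one)$converged)
})

test_that("EB average matches the weighted-value formula and its identity", {
  pr <- list(category_values = c(0, 1, 2), alpha = c(1, 1, 1), alpha_sum = 3,
             converged = TRUE, donor_item = NA_character_, item = NA_character_)
  class(pr) <- "dm_prior"
  expect_equal(eb_average(c(2, 0, 0), 2, pr), 0.6)
  expect_equal(eb_average(c(1, 0, 1), 2, pr), 1.0)
  # shrinkage vanishes as k grows
  expect_lt(abs(eb_average(c(0, 0, 1e6), 1e6, pr) - 2), 1e-5)
  # convex-combination identity
  cnt <- c(3, 1, 1); k <- 5
  crude <- sum(pr$category_values * cnt) / k
  pmean <- sum(pr$category_values * pr$alpha) / pr$alpha_sum
  w <- k / (k + pr$alpha_sum)
  expect_equal(eb_average(cnt, k, pr), w * crude + (1 - w) * pmean,
               tolerance = 1e-12)
  expect_error(eb_average(c(1, 1), 2, pr), "mismatch")
})

test_that("phenotype tables have the expected column structure", {
  set.seed(106)
  g <- simulate_genotypes(400, 30, seed = 7)
  # one binary item only: 2 phenotype columns
  ib <- dietary_items("only_b", "binary", 0, icc = 0.4, h2 = 0.3)
  model <- trait_model(ib, seed = 1)
  lat <- simulate_latent_traits(g, model)
  q <- simulate_questionnaires(lat, model, seed = 2,
                               qc_violation_rate = 0)$questionnaires
  pt <- build_phenotype_table(q, ib, min_interior = 20)
  expect_identical(length(phenotype_columns(pt)), 2L)
  # one quantity item only: 4 phenotype columns
  iq <- dietary_items("only_q", "quantity", qlogis(0.6), icc = 0.4, h2 = 0.3)
  model <- trait_model(iq, seed = 3)
  lat <- simulate_latent_traits(g, model)
  q <- simulate_questionnaires(lat, model, seed = 4,
                               qc_violation_rate = 0)$questionnaires
  pt <- build_phenotype_table(q, iq, min_interior = 20)
  expect_identical(length(phenotype_columns(pt)), 4L)
  expect_setequal(phenotype_columns(pt),
                  c("only_q_crude_prop", "only_q_eb_prop",
                    "only_q_crude_avg", "only_q_eb_avg"))
})

test_that("every EB value lies between its crude value and the prior mean", {
  g <- simulate_genotypes(600, 30, seed = 8)
  items <- example_items()
  model <- trait_model(items, seed = 5)
  lat <- simulate_latent_traits(g, model)
  q <- simulate_questionnaires(lat, model, seed = 6,
                               qc_violation_rate = 0)$questionnaires
  pt <- build_phenotype_table(q, items, min_interior = 20)
  ph <- pt$phenotypes
  for (it in items$id) {
    pr <- pt$beta_priors[[it]]
    m <- pr$alpha / (pr$alpha + pr$beta)
    lo <- pmin(ph[[paste0(it, "_crude_prop")]], m) - 1e-12
    hi <- pmax(ph[[paste0(it, "_crude_prop")]], m) + 1e-12
    eb <- ph[[paste0(it, "_eb_prop")]]
    expect_true(all(eb >= lo & eb <= hi))
    expect_true(all(eb >= 0 & eb <= 1))
  }
  for (it in names(pt$dm_priors)) {
    pr <- pt$dm_priors[[it]]
    m <- sum(pr$category_values * pr$alpha) / pr$alpha_sum
    lo <- pmin(ph[[paste0(it, "_crude_avg")]], m) - 1e-9
    hi <- pmax(ph[[paste0(it, "_crude_avg")]], m) + 1e-9
    eb <- ph[[paste0(it, "_eb_avg")]]
    expect_true(all(eb >= lo & eb <= hi))
  }
  # s <= k structurally: crude proportions bounded by 1
  expect_true(all(ph$k %in% 1:5))
})
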