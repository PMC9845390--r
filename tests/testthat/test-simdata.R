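test_that("dosages follow the configured allele frequency", {
  g <- simulate_genotypes(10000, 1, maf_range = c(0.5, 0.5), ld_rho = 0,
                          seed = 11)
  expect_true(all(g$dosages %in% 0:2))
  expect_lt(abs(mean(g$dosages) / 2 - 0.5), 0.02)
})

test_that("unlinked SNPs have null-level adjacent correlation", {
  n <- 5000
  g <- simulate_genotypes(n, 60, ld_rho = 0, recomb_prob = 0, seed = 12)
  r2 <- vapply(seq_len(59), function(j) {
    stats::cor(g$dosages[, j], g$dosages[, j + 1])^2
  }, numeric(1))
  # independent replicate simulation gives the Monte-Carlo null expectation
  g2 <- simulate_genotypes(n, 60, ld_rho = 0, recomb_prob = 0, seed = 999)
  r2_null <- vapply(seq_len(59), function(j) {
    stats::cor(g2$dosages[, j], g2$dosages[, j + 1])^2
  }, numeric(1))
  expect_lt(abs(mean(r2) - mean(r2_null)), 3 / n)
  expect_lt(mean(r2), 4 / n)  # E[r2] under the null is about 1/n
})

test_that("genotype simulation is bit-identical for identical seeds", {
  g1 <- simulate_genotypes(100, 40, seed = 5)
  g2 <- simulate_genotypes(100, 40, seed = 5)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$map, g2$map)
  expect_false(identical(
    g1$dosages, simulate_genotypes(100, 40, seed = 6)$dosages))
})

test_that("parameter validation rejects bad ranges", {
  expect_error(simulate_genotypes(1, 10), "n_individuals")
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)), "maf_range")
  expect_error(simulate_genotypes(10, 5, ld_rho = 1), "ld_rho")
  expect_error(dietary_items("a", "binary", 0, icc = 1.2, h2 = 0.5), "icc")
  expect_error(trait_model(data.frame(id = "a")), "dietary_items")
})

test_that("latent liabilities hit their heritability targets exactly in-sample", {
  g <- simulate_genotypes(500, 200, seed = 21)
  items <- dietary_items(c("full", "null", "half"), "binary", 0,
                         icc = 0.5, h2 = c(1, 0, 0.5))
  lat <- simulate_latent_traits(g, trait_model(items, seed = 3))
  # h2 = 1: liability equals the genetic value, unit variance
  expect_equal(lat$liability[, "full"], lat$genetic[, "full"])
  expect_equal(stats::var(lat$genetic[, "full"]), 1, tolerance = 1e-10)
  # h2 = 0: no genetic component at all
  expect_true(all(lat$genetic[, "null"] == 0))
  # intermediate: genetic sample variance is exactly h2
  expect_equal(stats::var(lat$genetic[, "half"]), 0.5, tolerance = 1e-10)
  expect_equal(stats::var(lat$liability[, "half"]), 1, tolerance = 1e-10)
})

test_that("null liabilities give calibrated association p-values", {
  g <- simulate_genotypes(800, 300, seed = 31)
  items <- dietary_items("nullit", "binary", 0, icc = 0.5, h2 = 0)
  lat <- simulate_latent_traits(g, trait_model(items, seed = 9))
  ss <- run_gwas(lat$liability[, 1], g, maf_min = 0, mac_min = 0)
  expect_lt(abs(mean(ss$P < 0.05) - 0.05), 0.06)
})

test_that("Haseman-Elston recovers the liability heritability", {
  g <- simulate_genotypes(2000, 2000, seed = 41)
  items <- dietary_items("t", "binary", 0, icc = 0.5, h2 = 0.25)
  grm <- make_grm(g)
  est <- vapply(1:5, function(r) {
    lat <- simulate_latent_traits(g, trait_model(items, seed = 100 + r))
    he_regression(lat$liability[, 1], grm = grm)$h2
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.25), 0.1)
})

test_that("questionnaire counts follow the completion distribution", {
  g <- simulate_genotypes(2000, 30, seed = 51)
  items <- example_items()
  lat <- simulate_latent_traits(g, trait_model(items, seed = 1))
  # point mass at five questionnaires
  qs <- simulate_questionnaires(lat, trait_model(items, seed = 1),
                                k_weights = c(0, 0, 0, 0, 1), seed = 2,
                                qc_violation_rate = 0)
  expect_true(all(qs$k == 5L))
  expect_identical(nrow(qs$questionnaires), 10000L)
  expect_true(all(table(qs$questionnaires$id) == 5))
  # default weights reproduce the printed completion-count shape
  qs2 <- simulate_questionnaires(lat, trait_model(items, seed = 1), seed = 3)
  frac <- as.numeric(table(factor(qs2$k, levels = 1:5))) / 2000
  expect_lt(max(abs(frac - completion_counts / sum(completion_counts))), 0.05)
  expect_error(simulate_questionnaires(lat, trait_model(items, seed = 1),
                                       k_weights = c(0, 0)), "k_weights")
})

test_that("quantity is zero exactly when the item was not consumed", {
  g <- simulate_genotypes(500, 30, seed = 61)
  items <- example_items()
  model <- trait_model(items, seed = 4)
  lat <- simulate_latent_traits(g, model)
  q <- simulate_questionnaires(lat, model, seed = 5)$questionnaires
  expect_true(all((q$coffee_cups == 0) == (q$coffee_cups_qty == 0)))
  expect_true(all(q$energy_kj > 0))
})

test_that("a fully reliable quantity item repeats identically within person", {
  g <- simulate_genotypes(300, 30, seed = 71)
  items <- dietary_items("det", "quantity", qlogis(0.9), icc = 1, h2 = 0.5)
  model <- trait_model(items, seed = 6)
  lat <- simulate_latent_traits(g, model)
  q <- simulate_questionnaires(lat, model, k_weights = c(0, 0, 0, 0, 1),
                               seed = 7, qc_violation_rate = 0)$questionnaires
  reps <- tapply(q$det_qty, q$id, function(x) length(unique(x)))
  expect_true(all(reps == 1))
})

test_that("realized item ICC matches its target within 0.05", {
  g <- simulate_genotypes(2000, 30, seed = 81)
  items <- dietary_items(
    id = c("b_half", "q_mid"), kind = c("binary", "quantity"),
    mu = c(qlogis(0.4), qlogis(0.6)), icc = c(0.5, 0.35), h2 = 0.4)
  model <- trait_model(items, seed = 8)
  lat <- simulate_latent_traits(g, model)
  q <- simulate_questionnaires(lat, model, k_weights = c(0, 0, 0, 0, 1),
                               seed = 9, qc_violation_rate = 0)$questionnaires
  q <- q[order(q$id, q$q), ]
  m1 <- matrix(q$b_half, ncol = 5, byrow = TRUE)
  m2 <- matrix(q$q_mid_qty, ncol = 5, byrow = TRUE)
  expect_lt(abs(icc_oneway(m1)$icc - 0.5), 0.05)
  expect_lt(abs(icc_oneway(m2)$icc - 0.35), 0.05)
  # one-way ICC estimate for the binary item sits in the stated band
  expect_gt(icc_oneway(m1)$icc, 0.45)
  expect_lt(icc_oneway(m1)$icc, 0.55)
})

test_that("questionnaire simulation is byte-identical after serialization", {
  g <- simulate_genotypes(200, 20, seed = 91)
  model <- trait_model(example_items(), seed = 10)
  lat <- simulate_latent_traits(g, model)
  q1 <- simulate_questionnaires(lat, model, seed = 11)$questionnaires
  q2 <- simulate_questionnaires(lat, model, seed = 11)$questionnaires
  f1 <- tempfile(); f2 <- tempfile()
  write_tsv(q1, f1); write_tsv(q2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("generator writers emit readable TSV and a truth sidecar", {
  g <- simulate_genotypes(50, 10, seed = 101)
  model <- trait_model(example_items(), seed = 12)
  lat <- simulate_latent_traits(g, model)
  pre <- tempfile()
  paths <- write_genotypes(g, pre)
  expect_true(all(file.exists(paths)))
  dos <- read_tsv(paths[1])
  expect_identical(nrow(dos), 50L)
  truth <- tempfile(fileext = ".yaml")
  write_ground_truth(model, lat, truth)
  parsed <- yaml::read_yaml(truth)
  expect_length(parsed$items, 4L)
  expect_equal(parsed$items[[1]]$h2, 0.5)
  unlink(c(paths, truth))
})
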