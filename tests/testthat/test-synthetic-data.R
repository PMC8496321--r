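test_that("simulated genotypes have the requested geometry and are seed-reproducible", {
  g <- simulate_genotypes(4, 3, maf_range = c(0.5, 0.5), seed = 1)
  expect_equal(dim(g$dosages), c(4L, 3L))
  expect_true(all(g$dosages %in% c(0, 1, 2)))

  # symmetric MAF of 0.5: mean dosage 1 within binomial sampling error
  g2 <- simulate_genotypes(400, 50, maf_range = c(0.5, 0.5), seed = 2)
  expect_lt(abs(mean(g2$dosages) - 1), 0.05)

  # a season-scale panel
  g3 <- simulate_genotypes(1276, 2000, maf_range = c(0.05, 0.5), seed = 7)
  expect_equal(dim(g3$dosages), c(1276L, 2000L))

  expect_identical(simulate_genotypes(20, 30, seed = 3)$dosages,
                   simulate_genotypes(20, 30, seed = 3)$dosages)
  expect_false(identical(simulate_genotypes(20, 30, seed = 3)$dosages,
                         simulate_genotypes(20, 30, seed = 4)$dosages))

  expect_error(simulate_genotypes(1, 5, seed = 1), "n_lines")
  expect_error(simulate_genotypes(5, 5, maf_range = c(0, 0.5), seed = 1), "maf_range")
  expect_error(simulate_genotypes(5, 5, maf_range = c(0.1, 0.6), seed = 1), "maf_range")
})

test_that("noiseless limit: phenotypes equal the line main effects and h2 is 1", {
  cfg <- sim_config(n_train_lines = 30, n_test_lines = 10, n_markers = 150,
                    n_traits = 2, sigma_TE = matrix(0, 2, 2),
                    residual_cov = matrix(0, 2, 2), seed = 5)
  d <- simulate_dataset(cfg)
  Y <- matrix(d$phenotypes$value, ncol = 2)
  expect_equal(unname(Y), unname(d$effects$b1), tolerance = 1e-12)
  expect_equal(unname(d$true_h2), c(1, 1))
})

test_that("phenotypes reconstruct exactly and effect variances match generating values", {
  # sizes chosen so the sampling error of a realized variance (which scales
  # with tr(G^2)/J^2) sits well inside the 10% tolerance
  cfg <- sim_config(n_train_lines = 1200, n_test_lines = 800, n_markers = 2500,
                    n_traits = 2, sigma_T = diag(0.5, 2), sigma_TE = diag(0.2, 2),
                    residual_cov = diag(0.5, 2),
                    env_effects = rbind(c(1, -1), c(2, 0)),
                    grand_means = c(5, 10), seed = 8)
  d <- simulate_dataset(cfg)

  # exact reconstruction Y = mu + beta_E + b1 + b2 + e
  env_i <- match(d$cycles, c("E1", "E2"))
  b2own <- d$effects$b1 * 0
  for (e in c("E1", "E2")) {
    idx <- which(d$cycles == e)
    b2own[idx, ] <- d$effects$b2[[e]][idx, ]
  }
  Yhat <- sweep(d$effects$b1 + b2own + d$effects$e, 2, cfg$grand_means, `+`) +
    cfg$env_effects[env_i, ]
  Y <- matrix(d$phenotypes$value, ncol = 2)
  expect_equal(unname(Y), unname(Yhat), tolerance = 1e-12)

  # realized variance decomposition within 10% of the generating diagonals
  # (averaged over traits / environments to tame quadratic-form noise)
  expect_lt(abs(mean(apply(d$effects$b1, 2, var)) / 0.5 - 1), 0.10)
  expect_lt(abs(mean(apply(d$effects$e, 2, var)) / 0.5 - 1), 0.10)
  b2v <- mean(c(apply(d$effects$b2[["E1"]], 2, var),
                apply(d$effects$b2[["E2"]], 2, var)))
  expect_lt(abs(b2v / 0.2 - 1), 0.10)
  expect_equal(unname(d$true_h2), rep(0.5 / 1.2, 2), tolerance = 1e-12)

  # phenotypic variance matches the law of total variance (h2 = 0.5 setting)
  cfg2 <- sim_config(n_train_lines = 700, n_test_lines = 300, n_markers = 600,
                     n_traits = 1, sigma_T = matrix(0.5, 1, 1),
                     sigma_TE = matrix(0, 1, 1), residual_cov = matrix(0.5, 1, 1),
                     seed = 9)
  d2 <- simulate_dataset(cfg2)
  expect_lt(abs(var(d2$phenotypes$value) - 1), 0.10)
  expect_equal(unname(d2$true_h2), 0.5)
})

test_that("generating genetic correlation is realized in the true genetic values", {
  S_T <- matrix(c(0.5, 0.4, 0.4, 0.5), 2, 2)  # correlation 0.8
  cfg <- sim_config(n_train_lines = 300, n_test_lines = 200, n_markers = 500,
                    n_traits = 2, sigma_T = S_T, sigma_TE = matrix(0, 2, 2),
                    residual_cov = diag(0.5, 2), seed = 10)
  d <- simulate_dataset(cfg)
  g1 <- d$true_g$g[d$true_g$trait == "T01"]
  g2 <- d$true_g$g[d$true_g$trait == "T02"]
  expect_lt(abs(cor(g1, g2) - 0.8), 0.1)
})

test_that("regression of phenotype on true genetic value recovers slope 1 and R2 = h2", {
  cfg <- sim_config(n_train_lines = 700, n_test_lines = 300, n_markers = 600,
                    n_traits = 1, sigma_T = matrix(0.5, 1, 1),
                    sigma_TE = matrix(0, 1, 1), residual_cov = matrix(0.5, 1, 1),
                    seed = 11)
  d <- simulate_dataset(cfg)
  fitlm <- lm(d$phenotypes$value ~ d$true_g$g)
  expect_lt(abs(coef(fitlm)[2] - 1), 0.1)
  expect_lt(abs(summary(fitlm)$r.squared - 0.5), 0.1)
})

test_that("true_accuracy: identity, sign flip, attenuation, and degenerate inputs", {
  d <- small_dataset(seed = 12, n_train = 500, n_test = 500, n_markers = 200,
                     n_traits = 1)
  lines <- d$genotypes$line_ids
  g <- with(d$true_g, stats::setNames(g[trait == "T01"], line[trait == "T01"]))
  expect_equal(true_accuracy(d, g, "T01", lines), 1.0)
  expect_equal(true_accuracy(d, -g, "T01", lines), -1.0)

  # equal-variance independent noise attenuates the correlation to 1/sqrt(2)
  set.seed(99)
  noisy <- g + stats::rnorm(length(g), sd = stats::sd(g))
  names(noisy) <- names(g)
  expect_lt(abs(true_accuracy(d, noisy, "T01", lines) - 1 / sqrt(2)), 0.06)

  expect_error(true_accuracy(d, g, "T01", lines[1:2]), "3 lines")
  const <- g * 0
  expect_error(true_accuracy(d, const, "T01", lines), "zero variance")
})
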