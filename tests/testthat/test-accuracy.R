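make_fit <- function(draws) {
  structure(c(as.list(colMeans(draws)), list(draws = draws, n = 100L,
                                             lines = NULL)),
            class = "bivariate_fit")
}

test_that("PC1 is the sample Pearson correlation with guarded degeneracies", {
  expect_equal(pc1(1:5, 1:5), 1.0)
  expect_equal(pc1(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pc1(c(1, 2, 3, 4), c(1, 1, 2, 2)), 2 / sqrt(5), tolerance = 1e-12)
  expect_error(pc1(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pc1(1:2, 1:2), "3 complete pairs")
  expect_error(pc1(1:4, 1:3), "length mismatch")
})

test_that("PC2 and PC4 apply the sqrt-heritability correction exactly", {
  expect_equal(pc2(0.4, 0.64), 0.5)
  expect_equal(pc2(0.37, 1.0), 0.37)
  expect_equal(pc2(0.5, 0.25), 1.0)
  expect_warning(v <- pc2(0.6, 0.25), "exceeds 1")
  expect_equal(v, 1.2)
  expect_error(pc2(0.4, 0), "h2")
  expect_equal(pc4(0.6, 1.0), 0.6)
  expect_equal(pc4(0.5, 0.25), 0.25)
  expect_error(pc4(0.4, -0.2), "h2")
  # identity: pc4(pc3, h2) / pc3 = sqrt(h2)
  for (h2 in c(0.2, 0.49, 0.81)) expect_equal(pc4(0.73, h2) / 0.73, sqrt(h2))
})

test_that("PC3 is the posterior mean of the attenuated genetic correlation", {
  d1 <- data.frame(sigma_go2 = rep(2, 50), sigma_gp2 = 2, sigma_gop = 2,
                   sigma_eo2 = 1, sigma_ep2 = 0, h2_p = 1)
  expect_equal(pc3(make_fit(d1)), 1.0)
  d2 <- transform(d1, sigma_gop = 0)
  expect_equal(pc3(make_fit(d2)), 0.0)
  # genetic correlation 0.8 with h_p^2 = 0.25 -> 0.4
  d3 <- data.frame(sigma_go2 = 1, sigma_gp2 = 1, sigma_gop = 0.8,
                   sigma_eo2 = 1, sigma_ep2 = 3, h2_p = 0.25)
  expect_equal(pc3(make_fit(d3)), 0.4, tolerance = 1e-12)
  d4 <- data.frame(sigma_go2 = 0, sigma_gp2 = 0, sigma_gop = 0,
                   sigma_eo2 = 1, sigma_ep2 = 1, h2_p = 0)
  expect_error(pc3(make_fit(d4)), "zero genetic variance")
})

test_that("MSEP and MAAPE match their definitions", {
  expect_equal(msep(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(msep(c(1, 2), c(2, 4)), 2.5)
  set.seed(51)
  o <- rnorm(40); p <- rnorm(40)
  loop <- 0
  for (i in seq_along(o)) loop <- loop + (o[i] - p[i])^2
  expect_equal(msep(o, p), loop / 40, tolerance = 1e-12)
  expect_error(msep(1:3, 1:2), "length mismatch")

  expect_equal(maape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(maape(1, 2), pi / 4)
  expect_equal(maape(0, 1), pi / 2)
  expect_equal(maape(c(0, 0), c(0, 5)), pi / 4)  # matching zero contributes 0
  expect_error(maape(1:3, 1:2), "length mismatch")
})

test_that("relative difference reduces to 100 (1/sqrt(h2) - 1) for the PC2/PC1 pair", {
  expect_equal(relative_difference(pc2(0.3, 0.25), 0.3), 100)
  expect_equal(relative_difference(pc2(0.3, 1), 0.3), 0)
  for (h2 in c(0.16, 0.5, 0.9)) {
    v1 <- 0.42
    expect_equal(relative_difference(suppressWarnings(pc2(v1, h2)), v1),
                 100 * (1 / sqrt(h2) - 1), tolerance = 1e-12)
  }
  expect_error(relative_difference(0.5, 0), "zero")
})

test_that("bivariate fit: self-prediction, independence null, and Cauchy-Schwarz", {
  set.seed(52)
  g <- simulate_genotypes(120, 400, seed = 52)
  G <- compute_grm(g)
  eg <- eigen(G$values + diag(1e-6, 120), symmetric = TRUE)
  gval <- as.vector(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(120)))
  obs <- stats::setNames(gval + rnorm(120, sd = 0.7), g$line_ids)

  # self-prediction: genetic correlation near 1; per-draw PC3 quantity <= 1
  bf <- fit_bivariate_accuracy(obs, obs, G, mcmc = mcmc_settings(1500, 500, 2, 53))
  dr <- bf$draws
  per_draw <- dr$sigma_gop / sqrt(dr$sigma_go2 * dr$sigma_gp2) * sqrt(dr$h2_p)
  expect_true(all(per_draw <= 1 + 1e-12))
  expect_gt(pc3(bf), 0.85)
  expect_true(all(abs(dr$sigma_gop) <= sqrt(dr$sigma_go2 * dr$sigma_gp2) + 1e-12))
  expect_true(all(dr$h2_p >= 0 & dr$h2_p <= 1))

  # independent predictions: genetic covariance near zero
  set.seed(54)
  g2 <- simulate_genotypes(300, 500, seed = 54)
  G2 <- compute_grm(g2)
  eg2 <- eigen(G2$values + diag(1e-6, 300), symmetric = TRUE)
  L2 <- eg2$vectors %*% diag(sqrt(pmax(eg2$values, 0)))
  obs2 <- stats::setNames(as.vector(L2 %*% rnorm(300)) + rnorm(300), g2$line_ids)
  pred2 <- stats::setNames(as.vector(L2 %*% rnorm(300)), g2$line_ids)
  bf2 <- fit_bivariate_accuracy(obs2, pred2, G2, mcmc = mcmc_settings(1500, 500, 2, 55))
  expect_lt(abs(bf2$sigma_gop), 0.1)

  expect_error(fit_bivariate_accuracy(obs[1:2], obs[1:2], G), "3 complete pairs")
  expect_warning(
    fit_bivariate_accuracy(obs[1:10], obs[1:10] + rnorm(10), G,
                           mcmc = mcmc_settings(200, 50, 1, 56)),
    "fewer than 30")
})

test_that("PC3 recovers a constructed known accuracy of 0.7", {
  set.seed(57)
  g <- simulate_genotypes(500, 800, seed = 57)
  G <- compute_grm(g)
  eg <- eigen(G$values + diag(1e-6, 500), symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  gval <- as.vector(L %*% rnorm(500))
  # calibrated iid noise so that Cor(g, g_hat) = 0.7
  s2 <- var(gval) * (1 / 0.49 - 1)
  ghat <- gval + rnorm(500, sd = sqrt(s2))
  obs <- stats::setNames(gval + rnorm(500, sd = sd(gval)), g$line_ids)
  ghat <- stats::setNames(ghat, g$line_ids)
  bf <- fit_bivariate_accuracy(obs, ghat, G, mcmc = mcmc_settings(2500, 500, 2, 58))
  expect_lt(abs(pc3(bf) - 0.7), 0.1)
})
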