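test_that("closed-form GBLUP limits and dual-route agreement", {
  set.seed(30)
  g <- simulate_genotypes(30, 120, seed = 30)
  G <- compute_grm(g)
  y <- stats::setNames(rnorm(30), g$line_ids)

  # sigma_e -> 0: BLUPs approach the GLS-centered phenotypes
  b0 <- closed_form_gblup(y, NULL, G, sigma_g2 = 1, sigma_e2 = 1e-10)
  expect_lt(max(abs(b0 - (y - attr(b0, "mu")))), 1e-6)

  # G = I: ridge shrinkage of centered y by sigma_g2 / (sigma_g2 + sigma_e2)
  GI <- grm(diag(1, 30), paste0("L", 1:30))
  yi <- stats::setNames(rnorm(30), paste0("L", 1:30))
  bi <- closed_form_gblup(yi, NULL, GI, 0.5, 0.5)
  expect_equal(unname(bi), unname((yi - mean(yi)) * 0.5), tolerance = 1e-10,
               ignore_attr = TRUE)

  # independent route: mixed-model equations (G^-1 lambda + I) b = y - mu
  b <- closed_form_gblup(y, NULL, G, 0.4, 0.7)
  Gr <- G$values + diag(1e-8, 30)
  C <- solve(Gr) * (0.7 / 0.4) + diag(1, 30)
  b_mme <- solve(C, y - attr(b, "mu"))
  expect_lt(max(abs(b - b_mme)), 1e-6)
})

test_that("noiseless interpolation: posterior mean reproduces the data", {
  n <- 25
  GI <- grm(diag(1, n), paste0("L", 1:n))
  set.seed(31)
  y <- rnorm(n)
  ph <- data.frame(line = paste0("L", 1:n), env = "E1", trait = "y", value = y)
  pri <- prior_spec(1, fixed_Sigma_T = matrix(1, 1, 1),
                    fixed_R = matrix(1e-10, 1, 1))
  spec <- model_spec(GI, include_gxe = FALSE, priors = pri,
                     mcmc = mcmc_settings(2000, 500, 1, 32))
  fit <- fit_multitrait(ph, spec)
  yhat <- fit$mean$mu + fit$mean$b1[, 1]
  expect_lt(max(abs(yhat - y)), 1e-6)
  pred <- predict_lines(fit, paste0("L", 1:n), "E1")
  expect_lt(max(abs(pred$total[, 1] - y)), 1e-6)
})

test_that("Gibbs sampler at fixed variance components matches closed-form GBLUP", {
  # reduced version of the oracle-equivalence check (full run in acceptance)
  set.seed(33)
  g <- simulate_genotypes(40, 150, seed = 33)
  G <- compute_grm(g)
  eg <- eigen(G$values + diag(1e-6, 40), symmetric = TRUE)
  b_true <- sqrt(0.5) * as.vector(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(40)))
  y <- 2 + b_true + rnorm(40, sd = sqrt(0.5))
  ph <- data.frame(line = g$line_ids, env = "E1", trait = "y", value = y)
  pri <- prior_spec(1, fixed_Sigma_T = matrix(0.5, 1, 1), fixed_R = matrix(0.5, 1, 1))
  spec <- model_spec(G, include_gxe = FALSE, priors = pri,
                     mcmc = mcmc_settings(4000, 500, 1, 34))
  fit <- fit_multitrait(ph, spec)
  blup <- closed_form_gblup(ph, "y", G, 0.5, 0.5)
  expect_lt(sqrt(mean((fit$mean$b1[names(blup), 1] - blup)^2)), 0.05)
})

test_that("single-trait fit equals the multi-trait sampler restricted to one trait", {
  d <- small_dataset(seed = 35, n_train = 40, n_test = 20, n_markers = 150,
                     n_traits = 2)
  spec <- model_spec(d$grm, include_gxe = FALSE, mcmc = quick_mcmc(36))
  f1 <- fit_singletrait(d$phenotypes, "T01", spec)
  f2 <- fit_multitrait(d$phenotypes, spec, traits = "T01")
  expect_identical(f1$draws$Sigma_T, f2$draws$Sigma_T)
  expect_identical(f1$mean$b1, f2$mean$b1)
})

test_that("draw streams are seed-deterministic and covariance draws are SPD", {
  d <- small_dataset(seed = 37, n_train = 40, n_test = 20, n_markers = 150,
                     n_traits = 2, gxe_var = 0.1)
  spec <- model_spec(d$grm, include_gxe = TRUE, mcmc = quick_mcmc(38))
  f1 <- fit_multitrait(d$phenotypes, spec)
  f2 <- fit_multitrait(d$phenotypes, spec)
  expect_identical(f1$draws$R, f2$draws$R)
  expect_identical(f1$mean$b2, f2$mean$b2)

  for (nm in c("Sigma_T", "Sigma_TE", "R")) {
    mins <- apply(f1$draws[[nm]], 3, function(S)
      min(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
    expect_gt(min(mins), 0)
  }
})

test_that("stored posterior means equal the average of retained draws", {
  d <- small_dataset(seed = 39, n_train = 30, n_test = 15, n_markers = 100,
                     n_traits = 2)
  spec <- model_spec(d$grm, include_gxe = FALSE, mcmc = quick_mcmc(40),
                     save_effects = TRUE)
  fit <- fit_multitrait(d$phenotypes, spec)
  expect_equal(fit$mean$Sigma_T,
               apply(fit$draws$Sigma_T, c(1, 2), mean),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(fit$mean$b1), apply(fit$draws$b1, c(1, 2), mean),
               tolerance = 1e-12)
  expect_equal(unname(fit$mean$mu), unname(apply(fit$draws$Gamma, c(1, 2), mean)[1, ]),
               tolerance = 1e-12)
})

test_that("inverse-Wishart sampler matches the analytic mean", {
  S <- matrix(c(4, 1, 1, 3), 2, 2)
  nu <- 12
  draws <- riw(nu, S, n = 4000)
  emp <- apply(draws, c(1, 2), mean)
  expect_lt(max(abs(emp / (S / (nu - 2 - 1)) - 1)), 0.1)
})

test_that("heritability estimation recovers generating values", {
  # h2 = 0.5 at n = 500
  d <- small_dataset(seed = 41, n_train = 350, n_test = 150, n_markers = 500,
                     n_traits = 1, h2 = 0.5)
  spec <- model_spec(d$grm, include_gxe = FALSE,
                     mcmc = mcmc_settings(1500, 500, 2, 42))
  h2 <- estimate_heritability(d$phenotypes, "T01", spec)
  expect_lt(abs(as.numeric(h2) - 0.5), 0.1)

  # pure noise: estimate small
  cfg0 <- sim_config(n_train_lines = 500, n_test_lines = 300, n_markers = 400,
                     n_traits = 1, sigma_T = matrix(0, 1, 1),
                     sigma_TE = matrix(0, 1, 1), residual_cov = matrix(1, 1, 1),
                     seed = 43)
  d0 <- simulate_dataset(cfg0)
  spec0 <- model_spec(d0$grm, include_gxe = FALSE,
                      mcmc = mcmc_settings(1500, 500, 2, 44))
  h20 <- estimate_heritability(d0$phenotypes, "T01", spec0)
  expect_lt(as.numeric(h20), 0.15)

  # noiseless data: the estimate rises far above the noisy-data value and
  # matches the exact posterior mean computed by direct numerical integration
  # of the marginal likelihood (independent of the Gibbs sampler). At finite
  # n the posterior does not reach h2 = 1: small eigenvalues of G let genetic
  # signal masquerade as residual, so some mass stays at sigma_e2 > 0.
  cfg1 <- sim_config(n_train_lines = 60, n_test_lines = 30, n_markers = 200,
                     n_traits = 1, sigma_T = matrix(0.5, 1, 1),
                     sigma_TE = matrix(0, 1, 1), residual_cov = matrix(1e-6, 1, 1),
                     seed = 45)
  d1 <- simulate_dataset(cfg1)
  y <- d1$phenotypes$value
  n <- length(y)
  G <- d1$grm$values + diag(1e-6, n)
  logpost <- function(sg2, se2) {
    V <- sg2 * G + diag(se2, n)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    mu <- sum(Vi %*% y) / sum(Vi)
    r <- y - mu
    # flat-mu marginal likelihood + IW(3, 0.5) priors on both variances
    -sum(log(diag(ch))) - 0.5 * log(sum(Vi)) - 0.5 * sum(r * (Vi %*% r)) -
      2.5 * log(sg2) - 0.25 / sg2 - 2.5 * log(se2) - 0.25 / se2
  }
  sg <- exp(seq(log(0.05), log(3), length.out = 25))
  se <- exp(seq(log(1e-4), log(1), length.out = 35))
  L <- exp(outer(sg, se, Vectorize(logpost)) -
             max(outer(sg, se, Vectorize(logpost))))
  W <- L * outer(sg, se)                       # log-grid jacobian
  h2_exact <- sum(W * outer(sg, se, function(a, b) a / (a + b))) / sum(W)

  # the chain mixes slowly between sigma_g2 and sigma_e2 in this corner,
  # hence the long run
  spec1 <- model_spec(d1$grm, include_gxe = FALSE,
                      mcmc = mcmc_settings(8000, 3000, 2, 46))
  h21 <- as.numeric(estimate_heritability(d1$phenotypes, "T01", spec1))
  expect_lt(abs(h21 - h2_exact), 0.05)
  expect_gt(h21, 0.75)
})

test_that("degenerate phenotype inputs are rejected", {
  d <- small_dataset(seed = 47, n_train = 20, n_test = 10, n_markers = 80,
                     n_traits = 1)
  spec <- model_spec(d$grm, include_gxe = FALSE, mcmc = quick_mcmc(48))
  ph <- d$phenotypes
  ph$value <- 1.0
  expect_error(fit_singletrait(ph, "T01", spec), "zero phenotypic variance")
  ph2 <- d$phenotypes
  ph2$value <- NA_real_
  expect_error(fit_singletrait(ph2, "T01", spec), "no observed values")
  expect_error(mcmc_settings(100, 100, 1, 1), "burn_in")
})

test_that("correlation metrics are invariant to the fixed-effect shift in predictions", {
  d <- small_dataset(seed = 49, n_train = 60, n_test = 30, n_markers = 200,
                     n_traits = 1)
  test <- lines_of_cycle(d, "E2")[6:30]
  ph <- d$phenotypes
  ph$value[ph$line %in% test] <- NA
  spec <- model_spec(d$grm, include_gxe = FALSE, mcmc = quick_mcmc(50))
  fit <- fit_multitrait(ph, spec)
  pred <- predict_lines(fit, test, "E2")
  obs <- observed_values(d, "T01", test)
  expect_equal(pc1(obs, pred$total[test, 1]), pc1(obs, pred$genetic[test, 1]),
               tolerance = 1e-12)
  expect_error(predict_lines(fit, "NOPE", "E2"), "not in the fitted model")
  expect_error(predict_lines(fit, test[1:3], "E9"), "unknown environment")
})

test_that("true accuracy of genomic predictions grows with training-set size", {
  wins <- 0L
  n_pairs <- 10L
  for (r in seq_len(n_pairs)) {
    accs <- vapply(c(200L, 800L), function(ntr) {
      cfg <- sim_config(n_train_lines = ntr, n_test_lines = 100L,
                        n_markers = 600L, n_traits = 1,
                        sigma_T = matrix(0.5, 1, 1), sigma_TE = matrix(0, 1, 1),
                        residual_cov = matrix(0.5, 1, 1), seed = 600 + 7 * r)
      d <- simulate_dataset(cfg)
      cur <- lines_of_cycle(d, "E2")
      aug <- cur[1:10]
      test <- setdiff(cur, aug)
      ph <- d$phenotypes
      ph$value[ph$line %in% test] <- NA
      spec <- model_spec(d$grm, include_gxe = FALSE,
                         mcmc = mcmc_settings(800, 300, 2, 700 + r))
      fit <- fit_multitrait(ph, spec)
      pred <- predict_lines(fit, test, "E2")
      true_accuracy(d, pred$genetic, "T01", test)
    }, numeric(1))
    expect_gt(accs[2], -1)  # both computed
    if (accs[2] > accs[1]) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
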