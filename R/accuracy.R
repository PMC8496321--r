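#' PC1: predictive ability (uncorrected Pearson correlation)
#'
#' The standard sample Pearson correlation between observed phenotypes and
#' predicted breeding values of the testing lines. Because the phenotype
#' carries non-genetic noise, PC1 underestimates the accuracy
#' `Cor(g, g_hat)`: under `Y = mu + g + eps` with `Cov(g_hat, eps) = 0`,
#' `Cor(g_hat, Y) = Cor(g_hat, g) * sqrt(h2)`.
#'
#' @param observed,predicted Numeric vectors of equal length `>= 3` with
#'   positive variance.
#' @return Pearson correlation.
#' @export
pc1 <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  ok <- stats::complete.cases(observed, predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("zero variance in observed or predicted values", call. = FALSE)
  }
  stats::cor(observed, predicted)
}

#' PC2: heritability-corrected predictive accuracy
#'
#' `PC2 = PC1 / sqrt(h2)`, the nonparametric estimator of the correlation
#' between true and predicted breeding values. Values above 1 can occur as a
#' finite-sample artifact and are kept (with a warning).
#'
#' @param pc1_value A PC1 correlation.
#' @param h2 Heritability in `(0, 1]`, conventionally estimated once from the
#'   whole (training + testing) data set.
#' @return Corrected correlation.
#' @export
pc2 <- function(pc1_value, h2) {
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1) stop("`h2` must lie in (0, 1]", call. = FALSE)
  out <- pc1_value / sqrt(h2)
  if (any(abs(out) > 1)) {
    warning("corrected correlation exceeds 1 in absolute value (finite-sample artifact)",
            call. = FALSE)
  }
  out
}

#' PC4: accuracy estimate mapped back to the phenotypic scale
#'
#' `PC4 = PC3 * sqrt(h2)`, the uncorrected counterpart of PC3: since
#' `Cor(g_hat, Y) = Cor(g_hat, g) * sqrt(h2)`, multiplying a parametric
#' accuracy estimate by `sqrt(h2)` estimates the phenotypic correlation.
#'
#' @param pc3_value A PC3 correlation.
#' @param h2 Heritability in `(0, 1]`.
#' @return Correlation on the phenotypic scale.
#' @export
pc4 <- function(pc3_value, h2) {
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1) stop("`h2` must lie in (0, 1]", call. = FALSE)
  pc3_value * sqrt(h2)
}

#' Mean squared error of prediction
#' @param observed,predicted Equal-length numeric vectors.
#' @return Mean of squared differences (missing pairs dropped).
#' @export
msep <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  ok <- stats::complete.cases(observed, predicted)
  mean((observed[ok] - predicted[ok])^2)
}

#' Mean arctangent absolute percentage error
#'
#' `MAAPE = mean(arctan(|(obs - pred) / obs|))`, a bounded relative-error
#' metric in `[0, pi/2]` radians. A record with `obs = 0` and `pred != 0`
#' contributes `arctan(Inf) = pi/2`; an exactly matching zero contributes 0.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Radians in `[0, pi/2]`.
#' @export
maape <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  ok <- stats::complete.cases(observed, predicted)
  o <- observed[ok]; p <- predicted[ok]
  ratio <- ifelse(o == 0, ifelse(p == o, 0, Inf), abs((o - p) / o))
  mean(atan(ratio))
}

#' Percentage relative difference between two accuracy estimates
#'
#' `100 * (corrected - uncorrected) / uncorrected`. For the pair
#' (PC2, PC1) this equals `100 * (1 / sqrt(h2) - 1)` identically, since
#' `PC2 = PC1 / sqrt(h2)`.
#'
#' @param corrected,uncorrected Accuracy values; `uncorrected` must be
#'   non-zero.
#' @return Percent difference.
#' @export
relative_difference <- function(corrected, uncorrected) {
  if (any(uncorrected == 0)) stop("zero uncorrected value", call. = FALSE)
  100 * (corrected - uncorrected) / uncorrected
}

#' Bivariate variance-component model behind PC3
#'
#' Treats the observed phenotypes `Y_o` and their predictions `Y_p` for the
#' testing lines as a two-trait system
#' `(Y_o, Y_p) = (mu_o, mu_p) + (g_o, g_p) + (e_o, e_p)` with genetic
#' covariance `Sigma` (2 x 2, unstructured, line covariance `G`) and
#' residual covariance constrained diagonal, `R = diag(sigma_eo2,
#' sigma_ep2)`: the cross term is fixed at zero because predictions obtained
#' from training data share no non-genetic source with the testing
#' phenotypes. Priors: `Sigma ~ IW(3, diag(0.5, 0.5))` (approximately
#' uniform on the genetic correlation) and scaled inverse-chi-squared priors
#' on the residual variances, with a small prediction-side prior scale
#' (0.01) because posterior-mean predictions carry little non-genetic
#' variance of their own.
#'
#' @param observed,predicted Values for the testing lines (named by line, or
#'   aligned with `grm`'s line order).
#' @param grm A [grm()] restricted to (or covering) the testing lines.
#' @param mcmc An [mcmc_settings()].
#' @param ridge Diagonal stabilizer for `G`.
#' @param prior_scale_obs,prior_scale_pred Residual prior scales.
#' @return A `bivariate_fit` object: posterior means `sigma_go2`,
#'   `sigma_gp2`, `sigma_gop`, `sigma_eo2`, `sigma_ep2`, `h2_p`, and a
#'   data frame `draws` with per-draw values.
#' @export
fit_bivariate_accuracy <- function(observed, predicted, grm,
                                   mcmc = mcmc_settings(4000L, 1000L, 3L, 1L),
                                   ridge = 1e-6,
                                   prior_scale_obs = 0.5,
                                   prior_scale_pred = 0.01) {
  stopifnot(inherits(grm, "grm"), inherits(mcmc, "mcmc_settings"))
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (!is.null(names(observed))) {
    lines <- names(observed)
  } else {
    if (length(observed) != length(grm$line_ids)) {
      stop("unnamed values must match the GRM line count", call. = FALSE)
    }
    lines <- grm$line_ids
  }
  ok <- stats::complete.cases(observed, predicted)
  observed <- observed[ok]; predicted <- predicted[ok]; lines <- lines[ok]
  n <- length(observed)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("zero variance in observed or predicted values", call. = FALSE)
  }
  if (n < 30L) warning("fewer than 30 testing lines; PC3 will be unstable", call. = FALSE)

  G <- grm_subset(grm, lines)$values
  eg <- eigen(symmetrize(G) + diag(ridge, n), symmetric = TRUE)
  U <- eg$vectors; d <- pmax(eg$values, ridge * 1e-3)
  Y <- cbind(o = observed, p = predicted)

  nu_g <- 3; S_g <- diag(0.5, 2L)
  nu_e <- 3; s2_e <- c(prior_scale_obs, prior_scale_pred)

  nkeep <- floor((mcmc$n_iter - mcmc$burn_in) / mcmc$thin)
  out <- matrix(NA_real_, nkeep, 6L,
                dimnames = list(NULL, c("sigma_go2", "sigma_gp2", "sigma_gop",
                                        "sigma_eo2", "sigma_ep2", "h2_p")))
  with_seed(mcmc$seed, {
    gs <- matrix(0, n, 2L)                 # genetic effects in the eigenbasis
    Sig <- diag(c(stats::var(observed), stats::var(predicted))) / 2
    sig_e <- pmax(c(stats::var(observed), stats::var(predicted)) / 2, 1e-8)
    mu <- colMeans(Y)
    keep_i <- 0L
    for (it in seq_len(mcmc$n_iter)) {
      gL <- U %*% gs
      # means (flat prior, diagonal R -> independent per channel)
      res <- Y - gL
      mu <- colMeans(res) + rnorm(2L) * sqrt(sig_e / n)
      # genetic effects, trait-wise in the eigenbasis
      W <- sweep(Y, 2L, mu)
      Ws <- crossprod(U, W)
      sinv <- chol2inv(chol(Sig + diag(1e-10, 2L)))
      for (t in 1:2) {
        u <- 3L - t
        h <- Ws[, t] / sig_e[t] - sinv[t, u] * gs[, u] / d
        prec <- sinv[t, t] / d + 1 / sig_e[t]
        gs[, t] <- h / prec + rnorm(n) / sqrt(prec)
      }
      # genetic covariance
      Sig <- riw(nu_g + n, S_g + crossprod(gs / sqrt(d)))
      # residual variances (independent scaled inverse-chi-squared)
      gL <- U %*% gs
      E <- sweep(Y, 2L, mu) - gL
      for (t in 1:2) {
        sig_e[t] <- (nu_e * s2_e[t] + sum(E[, t]^2)) /
          stats::rgamma(1L, shape = (nu_e + n) / 2, rate = 1) / 2
      }
      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
        keep_i <- keep_i + 1L
        out[keep_i, ] <- c(Sig[1L, 1L], Sig[2L, 2L], Sig[1L, 2L],
                           sig_e[1L], sig_e[2L],
                           Sig[2L, 2L] / (Sig[2L, 2L] + sig_e[2L]))
      }
    }
  })
  draws <- as.data.frame(out)
  structure(c(as.list(colMeans(draws)),
              list(draws = draws, n = n, lines = lines)),
            class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("<bivariate_fit> n = %d; genetic correlation %.3f; h2_p %.3f\n",
              x$n, x$sigma_gop / sqrt(x$sigma_go2 * x$sigma_gp2), x$h2_p))
  invisible(x)
}

#' PC3: parametric corrected accuracy from the bivariate model
#'
#' Per retained posterior draw, computes
#' `[sigma_gop / sqrt(sigma_go2 * sigma_gp2)] * sqrt(h2_p)` — the genetic
#' correlation between observed and predicted values, attenuated by the
#' prediction channel's own reliability `h2_p = sigma_gp2 / (sigma_gp2 +
#' sigma_ep2)` — and returns the posterior mean of the per-draw ratio. When
#' `sigma_ep2 = 0` this reduces to the genetic correlation, the parametric
#' estimate of `Cor(g, g_hat)`.
#'
#' @param fit A [fit_bivariate_accuracy()] result.
#' @return Posterior-mean corrected correlation.
#' @export
pc3 <- function(fit) {
  stopifnot(inherits(fit, "bivariate_fit"))
  dr <- fit$draws
  bad <- dr$sigma_go2 <= 0 | dr$sigma_gp2 <= 0
  if (mean(bad) > 0.5) stop("zero genetic variance in most draws", call. = FALSE)
  dr <- dr[!bad, , drop = FALSE]
  mean(dr$sigma_gop / sqrt(dr$sigma_go2 * dr$sigma_gp2) * sqrt(dr$h2_p))
}
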