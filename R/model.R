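#' Prior specification for the multi-trait genomic model
#'
#' Flat priors are used for the grand means and environment effects;
#' independent inverse-Wishart priors for the three trait x trait covariance
#' matrices: `Sigma_T ~ IW(nu_T, S_T)` (line main effects),
#' `Sigma_TE ~ IW(nu_TE, S_TE)` (genotype x environment effects) and
#' `R ~ IW(nu_R, S_R)` (residuals). The defaults `nu = n_traits + 2`,
#' `S = 0.5 I` are weak and center each variance near 0.5, the magnitude of a
#' standardized trait. Passing a `fixed_*` matrix freezes that component (no
#' conjugate update), which is how the sampler is reduced to fixed-variance
#' GBLUP for oracle comparisons.
#'
#' @param n_traits Number of traits.
#' @param nu_T,nu_TE,nu_R Degrees of freedom; must exceed `n_traits - 1`.
#' @param S_T,S_TE,S_R Positive-definite scale matrices.
#' @param fixed_Sigma_T,fixed_Sigma_TE,fixed_R Optional fixed covariance
#'   matrices; when supplied the corresponding component is not sampled.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(n_traits,
                       nu_T = n_traits + 2, S_T = diag(0.5, n_traits),
                       nu_TE = n_traits + 2, S_TE = diag(0.5, n_traits),
                       nu_R = n_traits + 2, S_R = diag(0.5, n_traits),
                       fixed_Sigma_T = NULL, fixed_Sigma_TE = NULL,
                       fixed_R = NULL) {
  n_traits <- as.integer(n_traits)
  for (nm in c("nu_T", "nu_TE", "nu_R")) {
    if (get(nm) <= n_traits - 1) {
      stop(sprintf("`%s` must exceed n_traits - 1", nm), call. = FALSE)
    }
  }
  check_spd(S_T, "S_T"); check_spd(S_TE, "S_TE"); check_spd(S_R, "S_R")
  for (nm in c("fixed_Sigma_T", "fixed_Sigma_TE", "fixed_R")) {
    S <- get(nm)
    if (!is.null(S)) {
      if (length(S) == 1L) S <- diag(as.numeric(S), n_traits)
      if (!is.matrix(S) || nrow(S) != n_traits) {
        stop(sprintf("`%s` must be an n_traits x n_traits matrix", nm), call. = FALSE)
      }
      assign(nm, symmetrize(S))
    }
  }
  structure(list(n_traits = n_traits, nu_T = nu_T, S_T = S_T,
                 nu_TE = nu_TE, S_TE = S_TE, nu_R = nu_R, S_R = S_R,
                 fixed_Sigma_T = fixed_Sigma_T, fixed_Sigma_TE = fixed_Sigma_TE,
                 fixed_R = fixed_R),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param n_iter Total Gibbs sweeps.
#' @param burn_in Discarded initial sweeps (`burn_in < n_iter`).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer seed; the full draw stream is reproducible from it.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_iter = 12000L, burn_in = 2000L, thin = 5L, seed = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("`burn_in` must be smaller than `n_iter`", call. = FALSE)
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  if (floor((n_iter - burn_in) / thin) < 2) stop("fewer than 2 retained draws", call. = FALSE)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Model specification for the multi-trait genomic mixed model
#'
#' Bundles the genomic relationship matrix, the prior and MCMC settings, and
#' structural switches of the model
#' `Y = 1 mu' + X_E beta_E + Z_L b1 + Z_LE b2 + e` with
#' `b1 ~ MN(0, G, Sigma_T)`, `b2 ~ MN(0, I (x) G, Sigma_TE)` and i.i.d.
#' residual rows `e ~ N(0, R)`. Identifiability of `beta_E` with `mu` uses a
#' corner-point constraint: the first environment's effect is zero.
#'
#' @param grm A [grm()] covering every phenotyped line (training and testing
#'   cycles together).
#' @param include_gxe Include the `b2` genotype x environment term.
#' @param priors A [prior_spec()]; built with defaults at fit time if `NULL`.
#' @param mcmc An [mcmc_settings()].
#' @param ridge Diagonal stabilizer added to `G` before eigendecomposition.
#' @param save_effects Store per-draw `b1`/`b2` (memory-heavy); posterior
#'   means are always accumulated over retained draws.
#' @param verbose Log per-1000-sweep timing.
#' @return A `model_spec` list.
#' @export
model_spec <- function(grm, include_gxe = TRUE, priors = NULL,
                       mcmc = mcmc_settings(), ridge = 1e-6,
                       save_effects = FALSE, verbose = FALSE) {
  stopifnot(inherits(grm, "grm"), inherits(mcmc, "mcmc_settings"))
  if (!is.null(priors)) stopifnot(inherits(priors, "prior_spec"))
  structure(list(grm = grm, include_gxe = isTRUE(include_gxe), priors = priors,
                 mcmc = mcmc, ridge = ridge, save_effects = isTRUE(save_effects),
                 verbose = isTRUE(verbose), eigen_cache = NULL),
            class = "model_spec")
}

# Precompute and attach the eigendecomposition of ridge-stabilized G for a
# line set (reused across CV partitions, where the line set is identical).
cache_grm_eigen <- function(spec, lines) {
  G <- grm_subset(spec$grm, lines)$values
  eg <- eigen(symmetrize(G) + diag(spec$ridge, length(lines)), symmetric = TRUE)
  spec$eigen_cache <- list(lines = lines, U = eg$vectors, d = pmax(eg$values, spec$ridge * 1e-3))
  spec
}

#' Fit the Bayesian multi-trait genomic mixed model
#'
#' Gibbs sampler over the full conditionals of
#' `Y = 1 mu' + X_E beta_E + Z_L b1 + Z_LE b2 + e`: (i) fixed effects jointly
#' from their flat-prior matrix-normal conditional; (ii) `b1` trait-wise in
#' the eigenbasis of `G` (decomposed once); (iii) `b2` analogously per
#' environment; (iv) `Sigma_T | b1 ~ IW(nu_T + J, S_T + b1' G^-1 b1)` and
#' `Sigma_TE` analogously; (v) `R | E ~ IW(nu_R + N, S_R + E'E)`. Missing
#' phenotype cells (including fully masked testing lines) are data-augmented
#' from their conditional Gaussian each sweep, so partially observed
#' multi-trait records contribute exactly the information they carry.
#'
#' @param phenotypes Long-format data frame with columns `line`, `env`,
#'   `trait`, `value` (`NA` allowed). One record per (line, env, trait).
#' @param spec A [model_spec()].
#' @param traits Optional subset/ordering of traits to model (default: order
#'   of appearance).
#' @return A `posterior_summary` object; see [predict_lines()].
#' @export
fit_multitrait <- function(phenotypes, spec, traits = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  ph <- validate_phenotypes(phenotypes)
  traits <- traits %||% unique(ph$trait)
  if (!all(traits %in% ph$trait)) stop("requested trait absent from phenotypes", call. = FALSE)
  ph <- ph[ph$trait %in% traits, , drop = FALSE]
  .fit_engine(ph, spec, traits)
}

#' Fit the single-trait genomic mixed model
#'
#' [fit_multitrait()] restricted to one trait; the inverse-Wishart
#' conditionals collapse to scaled inverse-chi-squared updates of the three
#' scalar variances.
#'
#' @inheritParams fit_multitrait
#' @param trait Trait ID.
#' @return A `posterior_summary` object.
#' @export
fit_singletrait <- function(phenotypes, trait, spec) {
  fit_multitrait(phenotypes, spec, traits = trait)
}

.fit_engine <- function(ph, spec, traits) {
  nT <- length(traits)
  key <- paste(ph$line, ph$env, sep = "\r")
  dup <- duplicated(paste(key, ph$trait, sep = "\r"))
  if (any(dup)) {
    stop(sprintf("duplicate (line, env, trait) record: %s / %s / %s",
                 ph$line[dup][1L], ph$env[dup][1L], ph$trait[dup][1L]), call. = FALSE)
  }
  ukey <- !duplicated(key)
  rec_line <- ph$line[ukey]
  rec_env <- ph$env[ukey]
  N <- length(rec_line)
  Y <- matrix(NA_real_, N, nT, dimnames = list(NULL, traits))
  Y[cbind(match(key, key[ukey]), match(ph$trait, traits))] <- ph$value
  miss <- is.na(Y)

  for (t in seq_len(nT)) {
    v <- Y[!miss[, t], t]
    if (length(v) == 0L) {
      stop(sprintf("trait '%s' has no observed values", traits[t]), call. = FALSE)
    }
    if (length(v) > 1L && stats::sd(v) == 0) {
      stop(sprintf("trait '%s' has zero phenotypic variance", traits[t]), call. = FALSE)
    }
  }
  envs <- unique(rec_env)
  for (e in envs) {
    if (all(miss[rec_env == e, , drop = FALSE])) {
      stop(sprintf("environment '%s' has no observed phenotypes; its effect is not estimable", e),
           call. = FALSE)
    }
  }

  lines <- unique(rec_line)
  J <- length(lines)
  if (!is.null(spec$eigen_cache) && identical(spec$eigen_cache$lines, lines)) {
    eigG <- spec$eigen_cache
  } else {
    spec <- cache_grm_eigen(spec, lines)
    eigG <- spec$eigen_cache
  }

  line_idx <- match(rec_line, lines)
  env_idx <- match(rec_env, envs)
  # per-env record blocks for the G x E effect
  env_blocks <- NULL
  if (spec$include_gxe) {
    env_blocks <- lapply(seq_along(envs), function(ei) {
      rows <- which(env_idx == ei)
      lines_e <- rec_line[rows]
      if (anyDuplicated(lines_e)) {
        stop("duplicate (line, env) records are not supported", call. = FALSE)
      }
      li <- match(lines_e, lines)
      Ge <- eigG$U %*% (eigG$d * t(eigG$U))        # reconstruct ridged G
      Ge <- symmetrize(Ge[li, li, drop = FALSE])
      eg <- eigen(Ge, symmetric = TRUE)
      list(rows = rows, lines_e = lines_e,
           U = eg$vectors, d = pmax(eg$values, spec$ridge * 1e-3))
    })
    names(env_blocks) <- envs
  }
  priors <- spec$priors %||% prior_spec(nT)
  if (priors$n_traits != nT) stop("prior dimension does not match the trait count", call. = FALSE)

  .gibbs_mtgp(Y, miss, line_idx, env_idx, lines, envs, traits, eigG, env_blocks,
              priors, spec$mcmc, spec$include_gxe, spec$save_effects, spec$verbose)
}

.gibbs_mtgp <- function(Y, miss, line_idx, env_idx, lines, envs, traits,
                        eigG, env_blocks, priors, mcmc, include_gxe,
                        save_effects, verbose) {
  N <- nrow(Y); nT <- ncol(Y); J <- length(lines); nE <- length(envs)
  U <- eigG$U; d <- eigG$d
  n_per_line <- tabulate(line_idx, J)
  fast_b1 <- all(n_per_line == 1L)
  if (fast_b1) {
    rec_of_line <- match(seq_len(J), line_idx)
  } else {
    Ginv <- U %*% ((1 / d) * t(U))
    line_fac <- factor(line_idx, levels = seq_len(J))
  }

  # fixed-effect design: intercept + corner-constrained environment dummies
  p <- nE
  F <- matrix(0, N, p)
  F[, 1L] <- 1
  if (nE > 1L) for (e in 2:nE) F[env_idx == e, e] <- 1
  XtXinv <- chol2inv(chol(crossprod(F)))
  LA <- t(chol(XtXinv))

  # missingness pattern groups for data augmentation
  pat <- apply(miss, 1L, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(N), pat)
  groups <- groups[names(groups) != ""]

  # initialization
  Yaug <- Y
  tmeans <- vapply(seq_len(nT), function(t) mean(Y[!miss[, t], t]), numeric(1))
  for (t in seq_len(nT)) Yaug[miss[, t], t] <- tmeans[t]
  Gamma <- XtXinv %*% crossprod(F, Yaug)
  b1s <- matrix(0, J, nT)            # b1 in the eigenbasis of G
  b1L <- matrix(0, J, nT)            # b1 in line space
  Zb2 <- matrix(0, N, nT)
  if (include_gxe) {
    b2s <- lapply(env_blocks, function(bl) matrix(0, length(bl$rows), nT))
    b2L <- lapply(env_blocks, function(bl) matrix(0, length(bl$rows), nT))
  }
  Sig_T <- priors$fixed_Sigma_T %||% (priors$S_T / max(priors$nu_T - nT - 1, 1))
  Sig_TE <- priors$fixed_Sigma_TE %||% (priors$S_TE / max(priors$nu_TE - nT - 1, 1))
  Rcur <- priors$fixed_R %||% (priors$S_R / max(priors$nu_R - nT - 1, 1))

  nkeep <- floor((mcmc$n_iter - mcmc$burn_in) / mcmc$thin)
  dr <- list(Sigma_T = array(NA_real_, c(nT, nT, nkeep)),
             Sigma_TE = if (include_gxe) array(NA_real_, c(nT, nT, nkeep)),
             R = array(NA_real_, c(nT, nT, nkeep)),
             Gamma = array(NA_real_, c(p, nT, nkeep)))
  if (save_effects) {
    dr$b1 <- array(NA_real_, c(J, nT, nkeep))
    if (include_gxe) dr$b2 <- lapply(env_blocks, function(bl)
      array(NA_real_, c(length(bl$rows), nT, nkeep)))
  }
  sum_b1 <- matrix(0, J, nT)
  sum_b2 <- if (include_gxe) lapply(env_blocks, function(bl) matrix(0, length(bl$rows), nT))

  keep_i <- 0L
  t0 <- proc.time()[["elapsed"]]
  with_seed(mcmc$seed, {
    for (it in seq_len(mcmc$n_iter)) {
      Zb1 <- b1L[line_idx, , drop = FALSE]
      # --- data augmentation of missing cells
      if (length(groups)) {
        Mu <- F %*% Gamma + Zb1 + Zb2
        for (gi in seq_along(groups)) {
          rows <- groups[[gi]]
          m <- as.integer(strsplit(names(groups)[gi], ",", fixed = TRUE)[[1L]])
          o <- setdiff(seq_len(nT), m)
          if (length(o) == 0L) {
            Yaug[rows, ] <- Mu[rows, , drop = FALSE] +
              matrix(rnorm(length(rows) * nT), ncol = nT) %*% chol(Rcur)
          } else {
            Cm <- Rcur[m, o, drop = FALSE] %*% chol2inv(chol(Rcur[o, o, drop = FALSE]))
            condV <- symmetrize(Rcur[m, m, drop = FALSE] - Cm %*% Rcur[o, m, drop = FALSE])
            Yaug[rows, m] <- Mu[rows, m, drop = FALSE] +
              (Yaug[rows, o, drop = FALSE] - Mu[rows, o, drop = FALSE]) %*% t(Cm) +
              matrix(rnorm(length(rows) * length(m)), ncol = length(m)) %*%
                chol(condV + diag(1e-12, length(m)))
          }
        }
      }
      # --- fixed effects (flat prior, matrix-normal conditional)
      Wf <- Yaug - Zb1 - Zb2
      Gamma <- XtXinv %*% crossprod(F, Wf) +
        LA %*% matrix(rnorm(p * nT), p, nT) %*% chol(Rcur)
      # --- line main effects b1
      rinv <- chol2inv(chol(Rcur))
      sinv_T <- chol2inv(chol(Sig_T + diag(1e-10, nT)))
      W <- Yaug - F %*% Gamma - Zb2
      if (fast_b1) {
        Wstar <- crossprod(U, W[rec_of_line, , drop = FALSE])
        for (t in seq_len(nT)) {
          h <- as.vector(Wstar %*% rinv[, t]) -
            (as.vector(b1s %*% rinv[, t]) - rinv[t, t] * b1s[, t]) -
            (as.vector(b1s %*% sinv_T[, t]) - sinv_T[t, t] * b1s[, t]) / d
          prec <- sinv_T[t, t] / d + rinv[t, t]
          b1s[, t] <- h / prec + rnorm(J) / sqrt(prec)
        }
        b1L <- U %*% b1s
      } else {
        ZtW <- rowsum(W, line_fac)
        for (t in seq_len(nT)) {
          h <- as.vector(ZtW %*% rinv[, t]) -
            n_per_line * (as.vector(b1L %*% rinv[, t]) - rinv[t, t] * b1L[, t]) -
            as.vector(Ginv %*% (b1L %*% sinv_T[, t] - sinv_T[t, t] * b1L[, t]))
          P <- sinv_T[t, t] * Ginv + diag(rinv[t, t] * n_per_line, J)
          Uc <- chol(symmetrize(P))
          mu_t <- backsolve(Uc, forwardsolve(t(Uc), h))
          b1L[, t] <- mu_t + backsolve(Uc, rnorm(J))
        }
        b1s <- crossprod(U, b1L)
      }
      Zb1 <- b1L[line_idx, , drop = FALSE]
      # --- Sigma_T
      if (is.null(priors$fixed_Sigma_T)) {
        Sig_T <- riw(priors$nu_T + J, priors$S_T + crossprod(b1s / sqrt(d)))
        if (nT == 1L) Sig_T <- matrix(Sig_T, 1L, 1L)
      }
      # --- G x E effects b2 (per environment) and Sigma_TE
      if (include_gxe) {
        sinv_E <- chol2inv(chol(Sig_TE + diag(1e-10, nT)))
        W2 <- Yaug - F %*% Gamma - Zb1
        for (ei in seq_along(env_blocks)) {
          bl <- env_blocks[[ei]]
          Ws <- crossprod(bl$U, W2[bl$rows, , drop = FALSE])
          bs <- b2s[[ei]]
          for (t in seq_len(nT)) {
            h <- as.vector(Ws %*% rinv[, t]) -
              (as.vector(bs %*% rinv[, t]) - rinv[t, t] * bs[, t]) -
              (as.vector(bs %*% sinv_E[, t]) - sinv_E[t, t] * bs[, t]) / bl$d
            prec <- sinv_E[t, t] / bl$d + rinv[t, t]
            bs[, t] <- h / prec + rnorm(length(bl$rows)) / sqrt(prec)
          }
          b2s[[ei]] <- bs
          b2L[[ei]] <- bl$U %*% bs
          Zb2[bl$rows, ] <- b2L[[ei]]
        }
        if (is.null(priors$fixed_Sigma_TE)) {
          Scross <- priors$S_TE
          for (ei in seq_along(env_blocks)) {
            Scross <- Scross + crossprod(b2s[[ei]] / sqrt(env_blocks[[ei]]$d))
          }
          Sig_TE <- riw(priors$nu_TE + N, Scross)
          if (nT == 1L) Sig_TE <- matrix(Sig_TE, 1L, 1L)
        }
      }
      # --- residual covariance R
      if (is.null(priors$fixed_R)) {
        E <- Yaug - F %*% Gamma - Zb1 - Zb2
        Rcur <- riw(priors$nu_R + N, priors$S_R + crossprod(E))
        if (nT == 1L) Rcur <- matrix(Rcur, 1L, 1L)
      }
      # --- store retained draw
      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
        keep_i <- keep_i + 1L
        dr$Sigma_T[, , keep_i] <- Sig_T
        if (include_gxe) dr$Sigma_TE[, , keep_i] <- Sig_TE
        dr$R[, , keep_i] <- Rcur
        dr$Gamma[, , keep_i] <- Gamma
        sum_b1 <- sum_b1 + b1L
        if (include_gxe) for (ei in seq_along(env_blocks)) {
          sum_b2[[ei]] <- sum_b2[[ei]] + b2L[[ei]]
        }
        if (save_effects) {
          dr$b1[, , keep_i] <- b1L
          if (include_gxe) for (ei in seq_along(env_blocks)) {
            dr$b2[[ei]][, , keep_i] <- b2L[[ei]]
          }
        }
      }
      if (verbose && it %% 1000L == 0L) {
        message(sprintf("sweep %d/%d (%.1f s elapsed)", it, mcmc$n_iter,
                        proc.time()[["elapsed"]] - t0))
      }
    }
  })

  Gmean <- apply(dr$Gamma, c(1L, 2L), mean)
  beta_E <- matrix(0, nE, nT, dimnames = list(envs, traits))
  if (nE > 1L) beta_E[2:nE, ] <- Gmean[2:nE, , drop = FALSE]
  mean_b1 <- sum_b1 / keep_i
  dimnames(mean_b1) <- list(lines, traits)
  mean_b2 <- NULL
  if (include_gxe) {
    mean_b2 <- lapply(seq_along(env_blocks), function(ei) {
      m <- sum_b2[[ei]] / keep_i
      dimnames(m) <- list(env_blocks[[ei]]$lines_e, traits)
      m
    })
    names(mean_b2) <- envs
  }
  vc_names <- c("Sigma_T", if (include_gxe) "Sigma_TE", "R")
  ess_tab <- do.call(rbind, lapply(vc_names, function(nm) {
    data.frame(component = nm, trait = traits,
               ess = vapply(seq_len(nT), function(t) ess(dr[[nm]][t, t, ]), numeric(1)),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    traits = traits, envs = envs, lines = lines, include_gxe = include_gxe,
    n_records = N, n_draws = keep_i,
    mean = list(mu = setNames(Gmean[1L, ], traits), beta_E = beta_E,
                b1 = mean_b1, b2 = mean_b2,
                Sigma_T = `dimnames<-`(apply(dr$Sigma_T, c(1L, 2L), mean),
                                       list(traits, traits)),
                Sigma_TE = if (include_gxe)
                  `dimnames<-`(apply(dr$Sigma_TE, c(1L, 2L), mean), list(traits, traits)),
                R = `dimnames<-`(apply(dr$R, c(1L, 2L), mean), list(traits, traits))),
    draws = dr, ess = ess_tab, mcmc = mcmc, priors = priors),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> %d trait(s), %d env(s), %d lines, %d retained draws\n",
              length(x$traits), length(x$envs), length(x$lines), x$n_draws))
  cat("  posterior mean genetic variances:",
      paste(sprintf("%.3f", diag(x$mean$Sigma_T)), collapse = " "), "\n")
  cat("  posterior mean residual variances:",
      paste(sprintf("%.3f", diag(x$mean$R)), collapse = " "), "\n")
  invisible(x)
}

#' Predict genetic values and phenotypic means for lines
#'
#' Returns the posterior-mean linear predictor
#' `mu + beta_E[env] + b1 + b2[env]` for the requested lines, together with
#' the breeding-value component `b1 + b2[env]` alone. Prediction of
#' unphenotyped lines flows through `G`'s covariance between phenotyped and
#' unphenotyped lines via the sampled `b1` (and `b2`), so the lines must have
#' been part of the fitted record set (masked, all-missing records count).
#'
#' @param post A `posterior_summary` from [fit_multitrait()].
#' @param lines Line IDs.
#' @param env Environment ID.
#' @return List with matrices `total` and `genetic` (lines x traits).
#' @export
predict_lines <- function(post, lines, env) {
  stopifnot(inherits(post, "posterior_summary"))
  if (!env %in% post$envs) stop(sprintf("unknown environment '%s'", env), call. = FALSE)
  bad <- setdiff(lines, post$lines)
  if (length(bad)) {
    stop(sprintf("line(s) not in the fitted model: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  g <- post$mean$b1[lines, , drop = FALSE]
  if (post$include_gxe) {
    b2e <- post$mean$b2[[env]]
    bad2 <- setdiff(lines, rownames(b2e))
    if (length(bad2)) {
      stop(sprintf("line(s) without a sampled G x E effect in '%s': %s", env,
                   paste(utils::head(bad2, 5L), collapse = ", ")), call. = FALSE)
    }
    g <- g + b2e[lines, , drop = FALSE]
  }
  shift <- post$mean$mu + post$mean$beta_E[env, ]
  total <- sweep(g, 2L, shift, `+`)
  list(total = total, genetic = g)
}

#' Estimate heritability from the whole data set
#'
#' Fits the single-trait model on all records (both cycles) and returns the
#' posterior mean of `sigma_g2 / (sigma_g2 + sigma_ge2 + sigma_e2)`, the line
#' main-effect variance over total phenotypic variance (the ratio is averaged
#' over draws). With `gxe_in_denominator = FALSE` (or a model without the
#' G x E term) the narrower `sigma_g2 / (sigma_g2 + sigma_e2)` is returned.
#'
#' @inheritParams fit_singletrait
#' @param gxe_in_denominator Include the G x E variance in the denominator.
#' @return Heritability in `[0, 1]`, with attributes `sd` (posterior SD) and
#'   `fit` (the `posterior_summary`).
#' @export
estimate_heritability <- function(phenotypes, trait, spec,
                                  gxe_in_denominator = TRUE) {
  fit <- fit_singletrait(phenotypes, trait, spec)
  sg <- fit$draws$Sigma_T[1L, 1L, ]
  se <- fit$draws$R[1L, 1L, ]
  sge <- if (fit$include_gxe && gxe_in_denominator) fit$draws$Sigma_TE[1L, 1L, ] else 0
  h2d <- sg / (sg + sge + se)
  structure(mean(h2d), sd = stats::sd(h2d), fit = fit)
}

#' Closed-form single-trait GBLUP (fixed variance components)
#'
#' Direct mixed-model solution used as the Gibbs sampler's equivalence
#' oracle: with `V = sigma_g2 G + sigma_e2 I`, the GLS mean is
#' `mu = (1' V^-1 1)^-1 1' V^-1 y` and the BLUP of the line effects is
#' `sigma_g2 G V^-1 (y - mu)`. Single environment only.
#'
#' @param phenotypes Long-format phenotypes (one environment, one record per
#'   line) or a named numeric vector of line values.
#' @param trait Trait ID (ignored for a named vector).
#' @param grm A [grm()] covering the lines.
#' @param sigma_g2,sigma_e2 Fixed variance components.
#' @return Named vector of BLUPs, with attribute `mu`.
#' @export
closed_form_gblup <- function(phenotypes, trait, grm, sigma_g2, sigma_e2) {
  stopifnot(inherits(grm, "grm"))
  if (is.numeric(phenotypes) && !is.null(names(phenotypes))) {
    y <- phenotypes
  } else {
    ph <- validate_phenotypes(phenotypes)
    ph <- ph[ph$trait == trait & !is.na(ph$value), , drop = FALSE]
    if (length(unique(ph$env)) > 1L) stop("closed-form GBLUP expects a single environment",
                                          call. = FALSE)
    if (anyDuplicated(ph$line)) stop("one record per line required", call. = FALSE)
    y <- setNames(ph$value, ph$line)
  }
  G <- grm_subset(grm, names(y))$values
  n <- length(y)
  V <- sigma_g2 * G + diag(sigma_e2, n)
  Vi <- tryCatch(chol2inv(chol(symmetrize(V))),
                 error = function(e) stop("singular mixed-model system", call. = FALSE))
  mu <- sum(Vi %*% y) / sum(Vi)
  b <- as.vector(sigma_g2 * G %*% (Vi %*% (y - mu)))
  structure(setNames(b, names(y)), mu = mu)
}
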