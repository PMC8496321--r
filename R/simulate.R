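#' Simulate biallelic marker genotypes
#'
#' Draws, independently for each marker, an allele frequency uniformly from
#' `maf_range` and then line dosages as Binomial(2, p). Markers are in linkage
#' equilibrium: relatedness between the simulated lines arises purely from
#' finite marker sampling, which is all the GBLUP model consumes through the
#' genomic relationship matrix.
#'
#' @param n_lines,n_markers Dimensions (`n_lines >= 2`, `n_markers >= 1`).
#' @param maf_range Pair of allele frequencies in `(0, 0.5]`.
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @param prefix Prefix for generated line IDs.
#' @return A [genotype_matrix()].
#' @examples
#' g <- simulate_genotypes(10, 25, seed = 1)
#' range(g$dosages)
#' @export
simulate_genotypes <- function(n_lines, n_markers, maf_range = c(0.05, 0.5),
                               seed, prefix = "L") {
  if (n_lines < 2 || n_markers < 1) {
    stop("need n_lines >= 2 and n_markers >= 1", call. = FALSE)
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1L] > maf_range[2L]) {
    stop("`maf_range` must be an increasing pair within (0, 0.5]", call. = FALSE)
  }
  with_seed(seed, {
    p <- runif(n_markers, maf_range[1L], maf_range[2L])
    X <- matrix(rbinom(n_lines * n_markers, 2L, rep(p, each = n_lines)),
                nrow = n_lines, ncol = n_markers)
    genotype_matrix(X,
                    line_ids = sprintf("%s%05d", prefix, seq_len(n_lines)),
                    marker_ids = sprintf("M%05d", seq_len(n_markers)))
  })
}

#' Simulation configuration for a two-cycle breeding dataset
#'
#' Defines the generating parameters of the multi-trait genomic mixed model
#' `Y = 1 mu' + X_E beta_E + Z_L b1 + Z_LE b2 + e`, with
#' `b1 ~ MN(0, G, sigma_T)` (line main effects, shared across cycles through
#' the marker-derived `G`), `b2 ~ MN(0, I (x) G, sigma_TE)` (genotype x
#' environment effects, independent across environments) and i.i.d. residual
#' rows `e ~ N(0, residual_cov)`. Cycle-1 lines are phenotyped only in
#' environment 1 and cycle-2 lines only in environment 2, mirroring a
#' first-year yield trial (YT) feeding an elite yield trial (EYT). The
#' default sizes match a representative season of such a program
#' (1,386 training lines, 509 testing lines).
#'
#' @param n_train_lines,n_test_lines Lines in the training (previous) and
#'   testing (current) cycle.
#' @param n_markers Markers used to derive relatedness.
#' @param n_traits Number of traits.
#' @param maf_range Allele-frequency range, see [simulate_genotypes()].
#' @param sigma_T Trait x trait genetic covariance of the line main effect
#'   (default: variance 0.5, compound-symmetric correlation 0.3).
#' @param sigma_TE Trait x trait covariance of the G x E effect (default:
#'   diagonal 0.1).
#' @param residual_cov Trait x trait residual covariance (default: diagonal
#'   0.4, so default heritability is 0.5 per trait).
#' @param env_effects 2 x n_traits matrix of environment means (default 0).
#' @param grand_means Per-trait grand means (default 0).
#' @param seed Integer seed (mandatory).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_train_lines = 1386L, n_test_lines = 509L,
                       n_markers = 2000L, n_traits = 14L,
                       maf_range = c(0.05, 0.5),
                       sigma_T = NULL, sigma_TE = NULL, residual_cov = NULL,
                       env_effects = NULL, grand_means = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_train_lines < 2 || n_test_lines < 2 || n_markers < 1 || n_traits < 1) {
    stop("non-positive or degenerate simulation dimensions", call. = FALSE)
  }
  if (is.null(sigma_T)) {
    sigma_T <- matrix(0.5 * 0.3, n_traits, n_traits)
    diag(sigma_T) <- 0.5
  }
  if (is.null(sigma_TE)) sigma_TE <- diag(0.1, n_traits)
  if (is.null(residual_cov)) residual_cov <- diag(0.4, n_traits)
  for (nm in c("sigma_T", "sigma_TE", "residual_cov")) {
    S <- get(nm)
    if (!is.matrix(S) || nrow(S) != n_traits || ncol(S) != n_traits) {
      stop(sprintf("`%s` must be %d x %d", nm, n_traits, n_traits), call. = FALSE)
    }
    if (max(abs(S - t(S))) > 1e-10) stop(sprintf("`%s` must be symmetric", nm), call. = FALSE)
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    # zero matrices are allowed (noiseless limits); negative eigenvalues are not
    if (ev < -1e-10) stop(sprintf("`%s` must be positive semi-definite", nm), call. = FALSE)
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  }
  if (is.null(env_effects)) env_effects <- matrix(0, 2L, n_traits)
  if (!is.matrix(env_effects) || nrow(env_effects) != 2L || ncol(env_effects) != n_traits) {
    stop("`env_effects` must be a 2 x n_traits matrix", call. = FALSE)
  }
  if (is.null(grand_means)) grand_means <- rep(0, n_traits)
  if (length(grand_means) != n_traits) stop("`grand_means` length must equal n_traits",
                                            call. = FALSE)
  traits <- colnames(sigma_T) %||% sprintf("T%02d", seq_len(n_traits))
  structure(list(n_train_lines = as.integer(n_train_lines),
                 n_test_lines = as.integer(n_test_lines),
                 n_markers = as.integer(n_markers), n_traits = as.integer(n_traits),
                 maf_range = maf_range, sigma_T = sigma_T, sigma_TE = sigma_TE,
                 residual_cov = residual_cov, env_effects = env_effects,
                 grand_means = grand_means, traits = traits, seed = as.integer(seed)),
            class = "sim_config")
}

# Draw a J x nT matrix-normal MN(0, K, S) given the lower Cholesky-type
# factors LK (J x J) and S (nT x nT, possibly PSD).
rmatnorm0 <- function(LK, S) {
  J <- nrow(LK)
  nT <- nrow(S)
  es <- eigen(symmetrize(S), symmetric = TRUE)
  LS <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), nT)
  LK %*% matrix(rnorm(J * nT), J, nT) %*% t(LS)
}

#' Simulate a two-cycle multi-trait breeding dataset
#'
#' Generates genotypes for all lines of both cycles, derives the genomic
#' relationship matrix `G` with [compute_grm()], draws the line main effects
#' `b1 ~ MN(0, G, sigma_T)`, the per-environment interaction effects
#' `b2_i ~ MN(0, G, sigma_TE)`, i.i.d. residuals, and assembles phenotypes
#' `Y = mu + beta_E + b1 + b2 + e`. The true total genetic value of a line in
#' its environment, `g = b1 + b2`, is stored so the unobservable true
#' accuracy `Cor(g, g_hat)` is computable. The implied heritability is
#' `h2_t = sigma_T[t,t] / (sigma_T[t,t] + sigma_TE[t,t] + residual_cov[t,t])`
#' (line main-effect variance over total phenotypic variance).
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list: `genotypes`, `phenotypes` (long data frame
#'   with columns `line`, `env`, `trait`, `value`), `true_g` (long data frame
#'   with column `g`), `effects` (list with `b1`, `b2`, `e` matrices),
#'   `grm`, `true_h2`, `cycles` (named cycle per line), `config`.
#' @examples
#' d <- simulate_dataset(sim_config(n_train_lines = 30, n_test_lines = 10,
#'   n_markers = 100, n_traits = 2, seed = 1))
#' head(d$phenotypes)
#' d$true_h2
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_all <- cfg$n_train_lines + cfg$n_test_lines
  geno <- simulate_genotypes(n_all, cfg$n_markers, cfg$maf_range,
                             seed = derive_seed(cfg$seed, 1L))
  G <- compute_grm(geno)
  envs <- c("E1", "E2")
  cycles <- setNames(rep(envs, c(cfg$n_train_lines, cfg$n_test_lines)), geno$line_ids)
  eg <- eigen(symmetrize(G$values), symmetric = TRUE)
  LG <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n_all)

  nT <- cfg$n_traits
  with_seed(derive_seed(cfg$seed, 2L), {
    b1 <- rmatnorm0(LG, cfg$sigma_T)
    b2 <- lapply(envs, function(e) rmatnorm0(LG, cfg$sigma_TE))
    names(b2) <- envs
    e_mat <- rmatnorm0(diag(1, n_all), cfg$residual_cov)
  })
  dimnames(b1) <- list(geno$line_ids, cfg$traits)
  for (e in envs) dimnames(b2[[e]]) <- list(geno$line_ids, cfg$traits)
  dimnames(e_mat) <- list(geno$line_ids, cfg$traits)

  env_of <- cycles
  b2own <- matrix(0, n_all, nT, dimnames = list(geno$line_ids, cfg$traits))
  for (e in envs) {
    idx <- which(env_of == e)
    b2own[idx, ] <- b2[[e]][idx, , drop = FALSE]
  }
  gmat <- b1 + b2own
  Y <- sweep(gmat + e_mat, 2L, cfg$grand_means, `+`) +
    cfg$env_effects[match(env_of, envs), , drop = FALSE]
  dimnames(Y) <- list(geno$line_ids, cfg$traits)

  phen <- data.frame(line = rep(geno$line_ids, times = nT),
                     env = rep(unname(env_of), times = nT),
                     trait = rep(cfg$traits, each = n_all),
                     value = as.vector(Y),
                     stringsAsFactors = FALSE)
  true_g <- data.frame(line = rep(geno$line_ids, times = nT),
                       env = rep(unname(env_of), times = nT),
                       trait = rep(cfg$traits, each = n_all),
                       g = as.vector(gmat),
                       stringsAsFactors = FALSE)
  h2 <- diag(cfg$sigma_T) /
    (diag(cfg$sigma_T) + diag(cfg$sigma_TE) + diag(cfg$residual_cov))
  h2[!is.finite(h2)] <- 1  # all-zero variance trait: define the limit as 1
  structure(list(genotypes = geno, phenotypes = phen, true_g = true_g,
                 effects = list(b1 = b1, b2 = b2, e = e_mat),
                 grm = G, true_h2 = setNames(h2, cfg$traits),
                 cycles = cycles, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d + %d lines (two cycles), %d markers, %d traits\n",
              x$config$n_train_lines, x$config$n_test_lines,
              x$config$n_markers, x$config$n_traits))
  cat("  true h2:", paste(sprintf("%.2f", x$true_h2), collapse = " "), "\n")
  invisible(x)
}

#' True prediction accuracy on a synthetic dataset
#'
#' Pearson correlation between the simulated true genetic values
#' `g = b1 + b2` (in each line's own environment) and model predictions, over
#' a stated set of lines. This is the unobservable quantity the corrected
#' estimators PC2 and PC3 try to estimate from phenotypes alone.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param predictions Named numeric vector, or a line x trait matrix with
#'   rownames, of predicted genetic values.
#' @param trait Trait ID.
#' @param lines Line IDs (at least 3) present in both truth and predictions.
#' @return Pearson correlation.
#' @export
true_accuracy <- function(dataset, predictions, trait, lines) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (length(lines) < 3L) stop("need at least 3 lines", call. = FALSE)
  if (is.matrix(predictions)) {
    if (!trait %in% colnames(predictions)) stop("trait absent from predictions", call. = FALSE)
    predictions <- predictions[, trait]
  }
  if (is.null(names(predictions))) stop("predictions must be named by line", call. = FALSE)
  if (!all(lines %in% names(predictions))) stop("predictions missing some lines", call. = FALSE)
  tg <- dataset$true_g
  tg <- tg[tg$trait == trait & tg$line %in% lines, ]
  if (nrow(tg) < length(lines)) stop("some lines absent from true_g", call. = FALSE)
  g <- setNames(tg$g, tg$line)[lines]
  p <- predictions[lines]
  if (stats::sd(g) == 0 || stats::sd(p) == 0) {
    stop("zero variance in truth or predictions", call. = FALSE)
  }
  stats::cor(g, p)
}
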