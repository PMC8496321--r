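#' Random 10% augmentation partitions for two-cycle cross-validation
#'
#' The two-cycle scheme trains on all previous-cycle lines plus a random 10%
#' of the current cycle (which makes the current environment's effect
#' estimable) and predicts the remaining 90%. Five independent random
#' selections are drawn (they are not disjoint folds: five 10% draws cannot
#' tile the data), each of size `round-half-up(fraction * n)`.
#'
#' @param current_lines IDs of the current-cycle lines (`>= 10`).
#' @param n_partitions Number of random selections.
#' @param fraction Fraction of current-cycle lines added to training, in
#'   `(0, 1)`.
#' @param seed Integer seed; the plan is fully reproducible from it.
#' @return A `cv_plan`: list with `partitions` (each holding `augment` and
#'   `test` ID vectors), `current_lines`, `n_partitions`, `fraction`, `seed`.
#' @examples
#' plan <- make_partitions(sprintf("L%03d", 1:100), seed = 1)
#' lengths(plan$partitions[[1]])
#' @export
make_partitions <- function(current_lines, n_partitions = 5L, fraction = 0.10,
                            seed) {
  current_lines <- as.character(current_lines)
  n <- length(current_lines)
  if (n < 10L) stop("need at least 10 current-cycle lines", call. = FALSE)
  if (anyDuplicated(current_lines)) stop("duplicate current-cycle line IDs", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1)", call. = FALSE)
  n_aug <- floor(fraction * n + 0.5)
  if (n_aug < 1L || n - n_aug < 1L) {
    stop("fraction leaves an empty training augmentation or testing set", call. = FALSE)
  }
  parts <- with_seed(seed, {
    lapply(seq_len(n_partitions), function(k) {
      aug <- sort(sample(current_lines, n_aug))
      list(augment = aug, test = setdiff(current_lines, aug))
    })
  })
  structure(list(partitions = parts, current_lines = current_lines,
                 n_partitions = as.integer(n_partitions), fraction = fraction,
                 n_augment = n_aug, seed = as.integer(seed)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d partitions: %d augment / %d test of %d current-cycle lines\n",
              x$n_partitions, x$n_augment,
              length(x$current_lines) - x$n_augment, length(x$current_lines)))
  invisible(x)
}

#' Run the two-cycle cross-validation for multi- and single-trait models
#'
#' For each partition: the multi-trait model is fitted on all previous-cycle
#' records plus the augmentation lines, with every trait of the testing lines
#' masked (their records stay in the design and are data-augmented, which is
#' how information flows to them through `G`); the single-trait model is
#' fitted on the focal trait with the same predictors and the same
#' partitions. Testing-line predictions are scored per trait with PC1-PC4,
#' MSEP and MAAPE. Heritabilities for PC2/PC4 are estimated once per trait
#' from the whole two-cycle data set (or injected via `h2`).
#'
#' @param genotypes A [genotype_matrix()] (used only for its line universe;
#'   the model consumes `spec$grm`). May be `NULL`.
#' @param phenotypes Long-format phenotypes for both cycles.
#' @param plan A [make_partitions()] plan over the current-cycle lines.
#' @param spec A [model_spec()] whose GRM covers all lines.
#' @param focal_trait Trait modeled in the single-trait arm.
#' @param compute_pc3 Fit the bivariate model per trait and partition
#'   (the slowest step; disable for quick looks).
#' @param bivariate_mcmc [mcmc_settings()] for the PC3 bivariate fits.
#' @param h2 Optional named per-trait heritabilities to use for PC2/PC4
#'   instead of estimating them.
#' @param traits Optional trait subset for the multi-trait arm.
#' @return An `accuracy_report`: list with `records` (long data frame:
#'   `model`, `trait`, `method`, `partition`, `value`), `summary` (mean, SD,
#'   n over partitions), `h2`, `focal_trait`, `plan`.
#' @export
run_dataset_cv <- function(genotypes, phenotypes, plan, spec,
                           focal_trait = "GY", compute_pc3 = TRUE,
                           bivariate_mcmc = NULL, h2 = NULL, traits = NULL) {
  stopifnot(inherits(plan, "cv_plan"), inherits(spec, "model_spec"))
  ph <- validate_phenotypes(phenotypes)
  traits <- traits %||% unique(ph$trait)
  if (!focal_trait %in% traits) stop(sprintf("focal trait '%s' absent", focal_trait),
                                     call. = FALSE)
  bad <- setdiff(plan$current_lines, ph$line)
  if (length(bad)) stop(sprintf("plan references unknown lines: %s",
                                paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  cur_env <- unique(ph$env[ph$line %in% plan$current_lines])
  if (length(cur_env) != 1L) {
    stop("current-cycle lines must sit in exactly one environment", call. = FALSE)
  }
  if (length(setdiff(unique(ph$env), cur_env)) < 1L) {
    stop("need at least one previous-cycle environment", call. = FALSE)
  }
  bivariate_mcmc <- bivariate_mcmc %||%
    mcmc_settings(4000L, 1000L, 3L, derive_seed(spec$mcmc$seed, 999L))

  # heritability per trait from the whole data set, shared across partitions
  if (is.null(h2)) {
    h2 <- vapply(traits, function(tr) {
      sp <- spec
      sp$mcmc$seed <- derive_seed(spec$mcmc$seed, 500L + match(tr, traits))
      as.numeric(estimate_heritability(ph, tr, sp))
    }, numeric(1))
    names(h2) <- traits
  } else {
    if (is.null(names(h2)) || !all(traits %in% names(h2))) {
      stop("`h2` must be named and cover every trait", call. = FALSE)
    }
    h2 <- h2[traits]
  }
  h2 <- pmin(pmax(h2, 1e-6), 1)

  # observed values of the current cycle, per trait
  cur <- ph[ph$env == cur_env, , drop = FALSE]
  obs_of <- function(tr, lines) {
    v <- cur[cur$trait == tr, , drop = FALSE]
    setNames(v$value, v$line)[lines]
  }

  spec <- cache_grm_eigen(spec, unique(ph$line))
  rows <- list()
  add_row <- function(model, trait, method, partition, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, trait = trait, method = method,
      partition = partition, value = value, stringsAsFactors = FALSE)
  }

  for (k in seq_len(plan$n_partitions)) {
    test <- plan$partitions[[k]]$test
    masked <- ph
    masked$value[masked$line %in% test & masked$env == cur_env] <- NA_real_

    for (arm in c("multi_trait", "single_trait")) {
      arm_traits <- if (arm == "multi_trait") traits else focal_trait
      # a one-trait dataset: the two arms coincide; fit once (single arm)
      if (arm == "multi_trait" && length(traits) == 1L) next
      sp <- spec
      sp$mcmc$seed <- derive_seed(spec$mcmc$seed,
                                  k * 10L + (arm == "single_trait"))
      fit <- fit_multitrait(masked, sp, traits = arm_traits)
      pred <- predict_lines(fit, test, cur_env)
      for (tr in arm_traits) {
        obs <- obs_of(tr, test)
        keep <- !is.na(obs)
        o <- obs[keep]
        gp <- pred$genetic[names(o), tr]
        tp <- pred$total[names(o), tr]
        v1 <- pc1(o, gp)
        v2 <- suppressWarnings(pc2(v1, h2[[tr]]))
        add_row(arm, tr, "PC1", k, v1)
        add_row(arm, tr, "PC2", k, v2)
        if (compute_pc3) {
          bm <- bivariate_mcmc
          bm$seed <- derive_seed(bivariate_mcmc$seed,
                                 k * 100L + match(tr, traits) +
                                   1000L * (arm == "single_trait"))
          bfit <- suppressWarnings(
            fit_bivariate_accuracy(o, gp, spec$grm, mcmc = bm, ridge = spec$ridge))
          v3 <- pc3(bfit)
          add_row(arm, tr, "PC3", k, v3)
          add_row(arm, tr, "PC4", k, pc4(v3, h2[[tr]]))
        }
        add_row(arm, tr, "MSEP", k, msep(o, tp))
        add_row(arm, tr, "MAAPE", k, maape(o, tp))
      }
    }
  }
  records <- do.call(rbind, rows)
  if (length(traits) == 1L) {
    # single-trait dataset: report the same fit under both arm labels
    dup <- records[records$model == "single_trait", , drop = FALSE]
    dup$model <- "multi_trait"
    records <- rbind(records, dup)
  }
  agg <- stats::aggregate(value ~ model + trait + method, data = records,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  summary <- data.frame(model = agg$model, trait = agg$trait, method = agg$method,
                        mean = agg$value[, "mean"],
                        sd = ifelse(is.na(agg$value[, "sd"]), 0, agg$value[, "sd"]),
                        n = agg$value[, "n"], stringsAsFactors = FALSE)
  summary <- summary[order(summary$model, summary$trait,
                           match(summary$method, c("PC1", "PC2", "PC3", "PC4",
                                                   "MSEP", "MAAPE"))), ]
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary, h2 = h2,
                 focal_trait = focal_trait, current_env = cur_env, plan = plan),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d traits x %d partitions; focal trait '%s'\n",
              length(unique(x$records$trait)), x$plan$n_partitions, x$focal_trait))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Aggregate accuracy reports into relative-difference summaries
#'
#' For each report (dataset) and trait: the percentage relative difference of
#' PC2 vs PC1 (identically `100 * (1/sqrt(h2) - 1)`), PC3 vs PC2, PC4 vs PC3
#' where available, and — for the focal trait — multi-trait vs single-trait
#' PC1. Cross-dataset min/max/mean are attached.
#'
#' @param reports A list of `accuracy_report` objects (or a single one).
#' @return List with `per_dataset` (tidy data frame: dataset, model, trait,
#'   comparison, percent) and `summary` (min/max/mean per comparison).
#' @export
aggregate_results <- function(reports) {
  if (inherits(reports, "accuracy_report")) reports <- list(reports)
  if (!length(reports)) stop("need at least one report", call. = FALSE)
  rows <- list()
  for (i in seq_along(reports)) {
    rp <- reports[[i]]
    sm <- rp$summary
    m <- function(model, trait, method) {
      v <- sm$mean[sm$model == model & sm$trait == trait & sm$method == method]
      if (length(v)) v else NA_real_
    }
    for (model in unique(sm$model)) {
      for (tr in unique(sm$trait[sm$model == model])) {
        cmp <- list(
          c("PC2_vs_PC1", m(model, tr, "PC2"), m(model, tr, "PC1")),
          c("PC3_vs_PC2", m(model, tr, "PC3"), m(model, tr, "PC2")),
          c("PC3_vs_PC4", m(model, tr, "PC3"), m(model, tr, "PC4")))
        for (cc in cmp) {
          num <- as.numeric(cc[2L]); den <- as.numeric(cc[3L])
          if (!is.na(num) && !is.na(den) && den != 0) {
            rows[[length(rows) + 1L]] <- data.frame(
              dataset = i, model = model, trait = tr, comparison = cc[1L],
              percent = relative_difference(num, den), stringsAsFactors = FALSE)
          }
        }
      }
    }
    ms <- m("multi_trait", rp$focal_trait, "PC1")
    ss <- m("single_trait", rp$focal_trait, "PC1")
    if (!is.na(ms) && !is.na(ss) && ss != 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = i, model = "multi_vs_single", trait = rp$focal_trait,
        comparison = "PC1_multi_vs_single", percent = relative_difference(ms, ss),
        stringsAsFactors = FALSE)
    }
  }
  per_dataset <- do.call(rbind, rows)
  agg <- stats::aggregate(percent ~ comparison, data = per_dataset,
                          FUN = function(v) c(min = min(v), max = max(v),
                                              mean = mean(v)))
  summary <- data.frame(comparison = agg$comparison,
                        min = agg$percent[, "min"], max = agg$percent[, "max"],
                        mean = agg$percent[, "mean"], stringsAsFactors = FALSE)
  list(per_dataset = per_dataset, summary = summary)
}
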