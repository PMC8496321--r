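#' Per-marker quality-control statistics
#'
#' Computes, for every marker, the minor allele frequency (MAF), the fraction
#' of missing calls and the heterozygote (dosage == 1) fraction. The allele
#' frequency `p` is the mean non-missing dosage divided by 2 and
#' `MAF = min(p, 1 - p)`; a fully missing marker gets `NA` MAF and fails all
#' filters downstream.
#'
#' @param geno A [genotype_matrix()].
#' @return A data frame of class `marker_qc` with one row per marker:
#'   `marker`, `maf`, `missing`, `het`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 0, 1, 2), 4, 1,
#'   dimnames = list(paste0("L", 1:4), "M1")))
#' compute_marker_stats(g)
#' @export
compute_marker_stats <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$dosages
  if (nrow(X) < 1L || ncol(X) < 1L) stop("empty genotype matrix", call. = FALSE)
  nmiss <- colSums(is.na(X))
  nobs <- nrow(X) - nmiss
  p <- ifelse(nobs > 0, colMeans(X, na.rm = TRUE) / 2, NA_real_)
  maf <- pmin(p, 1 - p)
  # het fraction uses all lines in the denominator (missing calls count against
  # the numerator only)
  het <- colSums(X == 1, na.rm = TRUE) / nrow(X)
  het[nmiss == nrow(X)] <- NA_real_
  out <- data.frame(marker = geno$marker_ids,
                    maf = unname(maf),
                    missing = unname(nmiss / nrow(X)),
                    het = unname(het),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("marker_qc", "data.frame")
  out
}

#' Filter markers on MAF, missingness and heterozygosity
#'
#' Retains markers with `MAF > maf_min`, missing fraction `< max_missing` and
#' heterozygote fraction `< max_het` (all strict inequalities). The defaults
#' are the standard GBS panel filters: MAF above 0.05, less than 50% missing
#' calls and less than 5% heterozygous calls (wheat lines are inbred, so
#' residual heterozygosity indicates genotyping error).
#'
#' @param geno A [genotype_matrix()].
#' @param maf_min,max_missing,max_het Thresholds in `[0, 1]`.
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report`, the per-marker QC table augmented with logical columns
#'   `pass_maf`, `pass_missing`, `pass_het`, `retained`, plus attributes
#'   `n_retained` / `n_removed`.
#' @examples
#' g <- simulate_genotypes(20, 50, maf_range = c(0.02, 0.5), seed = 1)
#' qc <- filter_markers(g)
#' attr(qc$report, "n_retained")
#' @export
filter_markers <- function(geno, maf_min = 0.05, max_missing = 0.5, max_het = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  for (th in c(maf_min = maf_min, max_missing = max_missing, max_het = max_het)) {
    if (!is.numeric(th) || th < 0 || th > 1) {
      stop("filter thresholds must lie in [0, 1]", call. = FALSE)
    }
  }
  rep <- compute_marker_stats(geno)
  rep$pass_maf <- !is.na(rep$maf) & rep$maf > maf_min
  rep$pass_missing <- !is.na(rep$missing) & rep$missing < max_missing
  rep$pass_het <- !is.na(rep$het) & rep$het < max_het
  rep$retained <- rep$pass_maf & rep$pass_missing & rep$pass_het
  keep <- which(rep$retained)
  if (length(keep) == 0L) {
    fails <- c(maf = sum(!rep$pass_maf), missing = sum(!rep$pass_missing),
               het = sum(!rep$pass_het))
    stop(sprintf(
      "all %d markers removed; binding filter: %s (failures - maf: %d, missing: %d, het: %d)",
      nrow(rep), names(which.max(fails)), fails[["maf"]], fails[["missing"]], fails[["het"]]),
      call. = FALSE)
  }
  attr(rep, "n_retained") <- length(keep)
  attr(rep, "n_removed") <- nrow(rep) - length(keep)
  out <- genotype_matrix(geno$dosages[, keep, drop = FALSE],
                         line_ids = geno$line_ids,
                         marker_ids = geno$marker_ids[keep],
                         imputed = geno$imputed)
  list(genotypes = out, report = rep)
}

#' Impute missing genotype dosages
#'
#' `"mean"` replaces each missing call by the marker's non-missing mean
#' dosage. `"em"` is a soft-impute-style low-rank EM: starting from mean
#' imputation, it alternates between a rank-`k` truncated SVD fit of the
#' column-centered matrix and refilling only the originally missing cells,
#' until the refilled cells change by less than `tol` (RMS) or `max_iter`
#' sweeps. Imputed dosages are real-valued, clipped to `[0, 2]`.
#'
#' @param geno A [genotype_matrix()]; no marker may be fully missing
#'   (run [filter_markers()] first).
#' @param method `"mean"` or `"em"`.
#' @param max_iter,tol EM controls.
#' @param k Rank of the EM approximation; default `min(10, markers - 1,
#'   lines - 1)`.
#' @return A [genotype_matrix()] with `imputed = TRUE` and no missing values.
#' @examples
#' m <- matrix(c(0, 2, 2, NA), 4, 1, dimnames = list(paste0("L", 1:4), "M1"))
#' impute_missing(genotype_matrix(m))$dosages  # NA -> 4/3
#' @export
impute_missing <- function(geno, method = c("mean", "em"), max_iter = 50L,
                           tol = 1e-4, k = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  method <- match.arg(method)
  X <- geno$dosages
  miss <- is.na(X)
  if (!any(miss)) {
    return(genotype_matrix(X, geno$line_ids, geno$marker_ids, imputed = TRUE))
  }
  if (any(colSums(!miss) == 0L)) {
    stop("fully missing marker(s); filter markers before imputation", call. = FALSE)
  }
  mu <- colMeans(X, na.rm = TRUE)
  Ximp <- X
  Ximp[miss] <- mu[col(X)[miss]]
  if (method == "em") {
    k <- k %||% min(10L, ncol(X) - 1L, nrow(X) - 1L)
    if (k >= min(nrow(X), ncol(X))) {
      stop("EM rank k must be smaller than min(lines, markers)", call. = FALSE)
    }
    k <- max(1L, k)
    for (it in seq_len(max_iter)) {
      cm <- colMeans(Ximp)
      C <- sweep(Ximp, 2L, cm)
      sv <- svd(C, nu = k, nv = k)
      fit <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
      new_vals <- pmin(2, pmax(0, sweep(fit, 2L, cm, `+`)[miss]))
      delta <- sqrt(mean((new_vals - Ximp[miss])^2))
      Ximp[miss] <- new_vals
      if (delta < tol) break
    }
  }
  Ximp[] <- pmin(2, pmax(0, Ximp))
  genotype_matrix(Ximp, geno$line_ids, geno$marker_ids, imputed = TRUE)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' With allele frequencies `p_j` estimated on this panel (column mean dosage
#' over 2) and `W = dosages - 2 p_j`, the genomic relationship matrix is
#' `G = W W' / (2 * sum_j p_j (1 - p_j))`. `G` is a scaled Gram matrix, hence
#' symmetric positive semi-definite by construction; its mean diagonal is
#' near 1 for an outbred panel in equilibrium and near `1 + F` for inbred
#' lines. Frequencies are computed on the panel supplied, so when the model
#' needs one `G` covering training and testing cycles, pass the combined
#' panel.
#'
#' @param geno A complete (imputed) [genotype_matrix()]; at least 2 lines and
#'   one polymorphic marker.
#' @return A `grm` object: list with `values` (line x line matrix) and
#'   `line_ids`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 2, 0, 2), 2, 2,
#'   dimnames = list(c("A", "B"), c("M1", "M2"))))
#' compute_grm(g)$values  # [[2, -2], [-2, 2]] for opposite homozygotes
#' @export
compute_grm <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$dosages
  if (anyNA(X)) stop("genotypes contain missing values; impute first", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 lines", call. = FALSE)
  p <- colMeans(X) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    stop("all markers are monomorphic on this panel (zero VanRaden denominator)",
         call. = FALSE)
  }
  W <- sweep(X, 2L, 2 * p)
  G <- tcrossprod(W) / denom
  G <- symmetrize(G)
  dimnames(G) <- list(geno$line_ids, geno$line_ids)
  new_grm(G, geno$line_ids)
}

new_grm <- function(values, line_ids) {
  structure(list(values = values, line_ids = as.character(line_ids)),
            class = "grm")
}

#' Construct a GRM object from a precomputed matrix
#'
#' @param values Symmetric line x line relationship matrix.
#' @param line_ids Unique line IDs (default rownames).
#' @return A `grm` object.
#' @export
grm <- function(values, line_ids = rownames(values)) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("`values` must be a square matrix", call. = FALSE)
  }
  if (is.null(line_ids)) stop("line IDs are required", call. = FALSE)
  if (anyDuplicated(line_ids)) stop("duplicate line IDs", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values)))) {
    stop("`values` must be symmetric", call. = FALSE)
  }
  values <- symmetrize(values)
  dimnames(values) <- list(line_ids, line_ids)
  new_grm(values, line_ids)
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d lines, mean diagonal %.3f\n",
              length(x$line_ids), mean(diag(x$values))))
  invisible(x)
}

# Sub-GRM for a set of lines (order preserved).
grm_subset <- function(g, lines) {
  miss <- setdiff(lines, g$line_ids)
  if (length(miss)) {
    stop(sprintf("lines absent from GRM: %s", paste(utils::head(miss, 5L), collapse = ", ")),
         call. = FALSE)
  }
  new_grm(g$values[lines, lines, drop = FALSE], lines)
}
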