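#' Construct a genotype matrix
#'
#' A light container for a lines x markers allele-dosage matrix. Dosages count
#' copies of one allele, so non-missing entries are 0, 1 or 2 (`NA` for
#' missing); after imputation dosages may be real-valued in `[0, 2]`, flagged
#' by `imputed = TRUE`.
#'
#' @param dosages Numeric matrix, lines in rows, markers in columns.
#' @param line_ids Unique line identifiers (default: rownames).
#' @param marker_ids Unique marker identifiers (default: colnames).
#' @param imputed Logical; if `TRUE` real-valued dosages in `[0, 2]` are
#'   accepted and missing values are not.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (matrix with dimnames), `line_ids`, `marker_ids`, `imputed`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 2), 2, 2,
#'   dimnames = list(c("L1", "L2"), c("M1", "M2"))))
#' g
#' @export
genotype_matrix <- function(dosages, line_ids = rownames(dosages),
                            marker_ids = colnames(dosages), imputed = FALSE) {
  if (!is.matrix(dosages) || !is.numeric(dosages)) {
    stop("`dosages` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(line_ids)) line_ids <- sprintf("L%04d", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- sprintf("M%05d", seq_len(ncol(dosages)))
  line_ids <- as.character(line_ids)
  marker_ids <- as.character(marker_ids)
  if (length(line_ids) != nrow(dosages)) {
    stop("`line_ids` length must match the number of rows", call. = FALSE)
  }
  if (length(marker_ids) != ncol(dosages)) {
    stop("`marker_ids` length must match the number of columns", call. = FALSE)
  }
  if (anyDuplicated(line_ids)) stop("duplicate line IDs", call. = FALSE)
  if (anyDuplicated(marker_ids)) stop("duplicate marker IDs", call. = FALSE)
  v <- dosages[!is.na(dosages)]
  if (imputed) {
    if (anyNA(dosages)) stop("imputed genotypes cannot contain missing values", call. = FALSE)
    if (length(v) && (min(v) < 0 || max(v) > 2)) {
      stop("imputed dosages must lie in [0, 2]", call. = FALSE)
    }
  } else if (length(v) && !all(v %in% c(0, 1, 2))) {
    bad <- which(!is.na(dosages) & !(dosages %in% c(0, 1, 2)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-{0,1,2} dosage %g at line '%s', marker '%s'",
                 dosages[bad[1L], bad[2L]], line_ids[bad[1L]], marker_ids[bad[2L]]),
         call. = FALSE)
  }
  storage.mode(dosages) <- "double"
  dimnames(dosages) <- list(line_ids, marker_ids)
  structure(list(dosages = dosages, line_ids = line_ids, marker_ids = marker_ids,
                 imputed = imputed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d markers (%s dosages, %.1f%% missing)\n",
              length(x$line_ids), length(x$marker_ids),
              if (x$imputed) "imputed real" else "integer",
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)
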