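validate_phenotypes <- function(df) {
  if (!is.data.frame(df)) stop("phenotypes must be a data frame", call. = FALSE)
  need <- c("line", "env", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("phenotypes missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df <- df[, need]
  df$line <- as.character(df$line)
  df$env <- as.character(df$env)
  df$trait <- as.character(df$trait)
  if (!is.numeric(df$value)) {
    suppressWarnings(v <- as.numeric(df$value))
    if (any(!is.na(df$value) & is.na(v) & df$value != "NA" & df$value != "")) {
      stop("non-numeric phenotype values", call. = FALSE)
    }
    df$value <- v
  }
  df
}

#' Read a genotype matrix from CSV or PLINK .raw
#'
#' The CSV dialect has a header row of marker IDs and line IDs in the first
#' column. The PLINK `.raw` dialect is whitespace-separated with the standard
#' `FID IID PAT MAT SEX PHENOTYPE` leading columns (IID is used as the line
#' ID) followed by marker dosage columns. Missing tokens: `NA`, `.`, empty.
#' Any other non-\{0,1,2\} token is rejected with its location.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"plink_raw"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("csv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  na_tokens <- c("NA", ".", "")
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                          na.strings = na_tokens)
    line_ids <- df[[1L]]
    dat <- df[, -1L, drop = FALSE]
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            colClasses = "character", na.strings = na_tokens)
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    miss <- setdiff(lead[1:2], names(df))
    if (length(miss)) stop("PLINK .raw file must have FID and IID columns", call. = FALSE)
    line_ids <- df[["IID"]]
    dat <- df[, setdiff(names(df), lead), drop = FALSE]
  }
  if (anyDuplicated(line_ids)) {
    stop(sprintf("duplicate line ID '%s'", line_ids[duplicated(line_ids)][1L]),
         call. = FALSE)
  }
  X <- matrix(NA_real_, nrow(dat), ncol(dat))
  for (j in seq_len(ncol(dat))) {
    col <- dat[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & (is.na(num) | !(num %in% c(0, 1, 2))))
    if (length(bad)) {
      stop(sprintf("invalid dosage token '%s' at row %d (line '%s'), column '%s'",
                   col[bad[1L]], bad[1L], line_ids[bad[1L]], names(dat)[j]),
           call. = FALSE)
    }
    X[, j] <- num
  }
  genotype_matrix(X, line_ids = line_ids, marker_ids = names(dat))
}

#' Write a genotype matrix to CSV or PLINK .raw
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @param dialect `"csv"` or `"plink_raw"`.
#' @export
write_genotypes <- function(geno, path, dialect = c("csv", "plink_raw")) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dialect <- match.arg(dialect)
  X <- geno$dosages
  if (dialect == "csv") {
    df <- data.frame(line = geno$line_ids, X, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- "line"
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    df <- data.frame(FID = geno$line_ids, IID = geno$line_ids, PAT = 0L, MAT = 0L,
                     SEX = 0L, PHENOTYPE = -9L, X, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = " ",
                       na = "NA")
  }
  invisible(path)
}

#' Read long-format phenotypes
#'
#' Requires columns `line`, `env`, `trait`, `value`; values are numeric with
#' missing allowed; duplicated (line, env, trait) keys are rejected.
#'
#' @param path CSV path.
#' @return A validated long-format data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("NA", ""))
  df <- validate_phenotypes(df)
  key <- paste(df$line, df$env, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1L, ]
    stop(sprintf("duplicate (line, env, trait) record: %s / %s / %s",
                 d$line, d$env, d$trait), call. = FALSE)
  }
  df
}

#' Convert wide phenotypes (one column per trait) to long format
#'
#' @param wide Data frame with a `line` column and one numeric column per
#'   trait.
#' @param env Environment label applied to every record.
#' @return Long-format data frame with columns `line`, `env`, `trait`,
#'   `value`.
#' @export
pivot_phenotypes <- function(wide, env) {
  if (!"line" %in% names(wide)) stop("wide table needs a `line` column", call. = FALSE)
  traits <- setdiff(names(wide), "line")
  out <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(line = as.character(wide$line), env = env, trait = tr,
               value = as.numeric(wide[[tr]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Registry of standard wheat trait abbreviations
#'
#' The 12 milling/baking quality traits plus grain yield and test weight that
#' a wheat breeding program typically records; `GY` (grain yield) is the
#' conventional focal trait. The registry is informative, not restrictive:
#' arbitrary trait names are accepted everywhere.
#'
#' @return Data frame with `abbrev` and `name`.
#' @export
wheat_traits <- function() {
  data.frame(
    abbrev = c("ALVPL", "ALVW", "FLRPRO", "FLRSDS", "GRNHRD", "GRNPRO", "GY",
               "LOFVOL", "MIXTIM", "MIXTORQ", "TESTWT", "TKW", "L", "P"),
    name = c("Dough tenacity/extensibility ratio", "Dough deformation energy",
             "Flour protein", "SDS sedimentation", "Grain hardness",
             "Grain protein", "Grain yield", "Bread loaf volume",
             "Time to peak mixing strength", "Peak mixing torque",
             "Test weight", "1000-kernel weight", "Dough extensibility",
             "Dough tenacity"),
    stringsAsFactors = FALSE)
}

#' Write/read a genomic relationship matrix as square TSV
#'
#' Line IDs are kept in the header row and the first column.
#'
#' @param g A `grm`.
#' @param path TSV path.
#' @return `read_grm` returns a `grm`.
#' @export
write_grm <- function(g, path) {
  stopifnot(inherits(g, "grm"))
  df <- data.frame(line = g$line_ids, g$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, check.names = FALSE, sep = "\t")
  ids <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!identical(ids, colnames(M))) {
    stop("GRM row and column line IDs disagree", call. = FALSE)
  }
  grm(M, ids)
}

#' Write an accuracy report to disk
#'
#' Writes `accuracy_records.csv` (tidy per-partition values, full precision),
#' `accuracy_summary.csv`, and `accuracy_report.txt`, an aligned
#' "mean (SD)" table per model arm with traits alphabetical and methods in
#' the order PC1-PC4, MSEP, MAAPE. Output is deterministic given an
#' identical report.
#'
#' @param report An `accuracy_report`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "accuracy_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f_rec <- file.path(outdir, "accuracy_records.csv")
  f_sum <- file.path(outdir, "accuracy_summary.csv")
  f_txt <- file.path(outdir, "accuracy_report.txt")
  rec <- report$records[order(report$records$model, report$records$trait,
                              match(report$records$method,
                                    c("PC1", "PC2", "PC3", "PC4", "MSEP", "MAAPE")),
                              report$records$partition), ]
  utils::write.csv(rec, f_rec, row.names = FALSE, quote = FALSE)
  utils::write.csv(report$summary, f_sum, row.names = FALSE, quote = FALSE)

  methods <- intersect(c("PC1", "PC2", "PC3", "PC4", "MSEP", "MAAPE"),
                       unique(report$summary$method))
  con <- file(f_txt, open = "wt")
  on.exit(close(con))
  writeLines("Prediction accuracy by model arm: mean (SD) over partitions", con)
  n1 <- any(report$summary$n == 1)
  for (model in sort(unique(report$summary$model))) {
    writeLines(sprintf("\n== %s ==", model), con)
    sm <- report$summary[report$summary$model == model, ]
    traits <- sort(unique(sm$trait))
    cells <- sapply(methods, function(me) {
      vapply(traits, function(tr) {
        r <- sm[sm$trait == tr & sm$method == me, ]
        if (!nrow(r)) return("-")
        sprintf("%s (%s)", signif(r$mean, 6), signif(r$sd, 6))
      }, character(1))
    })
    cells <- matrix(cells, nrow = length(traits),
                    dimnames = list(traits, methods))
    widths <- pmax(nchar(colnames(cells)),
                   apply(nchar(cells), 2L, max), 8L)
    twidth <- max(nchar(traits), nchar("trait"))
    hdr <- paste0(formatC("trait", width = twidth, flag = "-"), "  ",
                  paste(mapply(formatC, colnames(cells), width = widths,
                               MoreArgs = list(flag = "-")), collapse = "  "))
    writeLines(hdr, con)
    for (i in seq_along(traits)) {
      writeLines(paste0(formatC(traits[i], width = twidth, flag = "-"), "  ",
                        paste(mapply(formatC, cells[i, ], width = widths,
                                     MoreArgs = list(flag = "-")), collapse = "  ")), con)
    }
  }
  if (n1) writeLines("\nnote: SD reported as 0 where only one partition was available (n=1)", con)
  invisible(c(records = f_rec, summary = f_sum, text = f_txt))
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the [sim_config()] fields; covariance matrices may be given
#' as a scalar (diagonal value), a vector (diagonal) or a full matrix (list
#' of rows). The seed must be present in the file unless supplied here.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  n_traits <- as.integer(y$n_traits %||% 14L)
  as_cov <- function(x, n) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) return(do.call(rbind, lapply(x, as.numeric)))
    x <- as.numeric(x)
    if (length(x) == 1L) diag(x, n) else diag(x)
  }
  seed <- seed %||% y$seed
  if (is.null(seed)) stop("a seed is mandatory (config file or argument)", call. = FALSE)
  sim_config(
    n_train_lines = y$n_train_lines %||% 1386L,
    n_test_lines = y$n_test_lines %||% 509L,
    n_markers = y$n_markers %||% 2000L,
    n_traits = n_traits,
    maf_range = as.numeric(y$maf_range %||% c(0.05, 0.5)),
    sigma_T = as_cov(y$sigma_T, n_traits),
    sigma_TE = as_cov(y$sigma_TE, n_traits),
    residual_cov = as_cov(y$residual_cov, n_traits),
    env_effects = if (!is.null(y$env_effects))
      do.call(rbind, lapply(y$env_effects, as.numeric)),
    grand_means = if (!is.null(y$grand_means)) as.numeric(y$grand_means),
    seed = as.integer(seed))
}

#' Write the tables of a synthetic dataset to disk
#'
#' Genotypes as CSV (and optionally PLINK .raw), phenotypes and the truth
#' table as long-format CSV, the GRM as square TSV.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param outdir Output directory.
#' @param plink_raw Also write the PLINK .raw dialect.
#' @return Invisibly, the written paths.
#' @export
write_dataset <- function(dataset, outdir, plink_raw = FALSE) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(outdir, "genotypes.csv"),
             phenotypes = file.path(outdir, "phenotypes.csv"),
             true_g = file.path(outdir, "true_genetic_values.csv"),
             grm = file.path(outdir, "grm.tsv"))
  write_genotypes(dataset$genotypes, paths[["genotypes"]], "csv")
  utils::write.csv(dataset$phenotypes, paths[["phenotypes"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(dataset$true_g, paths[["true_g"]], row.names = FALSE,
                   quote = FALSE)
  write_grm(dataset$grm, paths[["grm"]])
  if (plink_raw) {
    paths <- c(paths, plink = file.path(outdir, "genotypes.raw"))
    write_genotypes(dataset$genotypes, paths[["plink"]], "plink_raw")
  }
  invisible(paths)
}
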