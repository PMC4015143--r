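# Tabular I/O for the three table kinds the package exchanges:
# beta matrices, sample annotation tables and clock coefficient tables.
# Dialect: comma-separated, UTF-8, mandatory header row, "NA"/empty cell =
# missing, lines starting with '#' carry key=value metadata.

INTERCEPT_TOKEN <- "(Intercept)"

#' Load a CpG beta-value matrix from CSV
#'
#' Reads a probes-by-samples (or samples-by-probes) CSV of Illumina-style
#' methylation beta values.  The first column holds row identifiers and the
#' header row holds column identifiers.  Empty cells and the sentinel "NA"
#' become missing values.  Whatever the on-disk orientation, the returned
#' matrix is always probes x samples (the canonical in-memory orientation
#' used throughout the package).
#'
#' @param path Path to a CSV file.
#' @param orientation Either \code{"probes_as_rows"} (default) or
#'   \code{"samples_as_rows"}, declaring the on-disk layout.
#' @return Numeric matrix, probes x samples, with unique row and column
#'   names; every non-missing value lies in \[0, 1\].
#' @export
load_beta_matrix <- function(path,
                             orientation = c("probes_as_rows",
                                             "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                         colClasses = "character", na.strings = c("NA", ""))
  if (ncol(raw) < 2L) format_error("beta matrix CSV needs ids plus >= 1 data column")
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  if (anyDuplicated(row_ids)) {
    format_error(sprintf("duplicate row identifier: %s",
                         row_ids[duplicated(row_ids)][1L]))
  }
  if (anyDuplicated(col_ids)) {
    format_error(sprintf("duplicate column identifier: %s",
                         col_ids[duplicated(col_ids)][1L]))
  }
  m <- matrix(NA_real_, nrow = nrow(raw), ncol = length(col_ids),
              dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      parse_error(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                          cell[bad[1L]], row_ids[bad[1L]], col_ids[j]))
    }
    m[, j] <- num
  }
  if (orientation == "samples_as_rows") m <- t(m)
  check_beta_bounds(m)
  # forgive float dust just outside [0,1]
  m[] <- clamp(m, 0, 1)
  m
}

check_beta_bounds <- function(m, tol = 1e-9) {
  bad <- which(!is.na(m) & (m < -tol | m > 1 + tol), arr.ind = TRUE)
  if (nrow(bad)) {
    bounds_error(sprintf(
      "beta value %g outside [0,1] at probe '%s', sample '%s'",
      m[bad[1L, , drop = FALSE]],
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  invisible(m)
}

#' Per-probe missing-value counts of a beta matrix
#' @param betas Probes x samples beta matrix.
#' @return Named integer vector, one count per probe.
#' @export
probe_missing_counts <- function(betas) {
  rowSums(is.na(betas))
}

#' Write a beta matrix to CSV (probes as rows)
#' @param betas Probes x samples beta matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_beta_matrix <- function(betas, path) {
  df <- data.frame(ProbeID = rownames(betas), betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv_safely(df, path)
}

#' Load a sample annotation table
#'
#' CSV with one row per sample.  Required columns: \code{sample_id} and
#' \code{age} (years, >= 0, missing allowed; 0 is valid for newborns).
#' Recognized optional columns: \code{tissue}, \code{dataset_id},
#' \code{sex}, \code{pair_id}, \code{zygosity} (MZ/DZ),
#' \code{passage_number}; any further columns are preserved untouched.
#' If zygosity is present each non-missing \code{pair_id} must occur
#' exactly twice with matching zygosity.
#'
#' @param path Path to a CSV file.
#' @return A data.frame keyed by unique \code{sample_id}.
#' @export
load_sample_table <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_sample_table(df)
}

#' Validate (and type) a sample annotation table
#' @param df A data.frame in the [load_sample_table()] layout.
#' @return The validated data.frame.
#' @export
validate_sample_table <- function(df) {
  for (col in c("sample_id", "age")) {
    if (!col %in% colnames(df)) {
      format_error(sprintf("sample table lacks required column '%s'", col))
    }
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    format_error(sprintf("duplicated sample_id: %s",
                         df$sample_id[duplicated(df$sample_id)][1L]))
  }
  age <- suppressWarnings(as.numeric(df$age))
  if (any(!is.na(df$age) & is.na(age))) {
    parse_error("non-numeric age value in sample table")
  }
  if (any(age < 0, na.rm = TRUE)) {
    validation_error("negative age in sample table; ages are years >= 0")
  }
  df$age <- age
  if ("passage_number" %in% colnames(df)) {
    pn <- suppressWarnings(as.numeric(df$passage_number))
    if (any(pn < 0 | pn != floor(pn), na.rm = TRUE)) {
      validation_error("passage_number must be a non-negative integer")
    }
    df$passage_number <- pn
  }
  if ("zygosity" %in% colnames(df)) {
    zy <- df$zygosity
    if (any(!is.na(zy) & !zy %in% c("MZ", "DZ"))) {
      validation_error("zygosity must be 'MZ' or 'DZ'")
    }
    if (!"pair_id" %in% colnames(df)) {
      format_error("zygosity column present but pair_id column missing")
    }
    keep <- !is.na(df$pair_id)
    tab <- table(df$pair_id[keep])
    if (any(tab != 2L)) {
      validation_error(sprintf(
        "pair_id '%s' does not occur exactly twice", names(tab)[tab != 2L][1L]))
    }
    nzy <- tapply(zy[keep], df$pair_id[keep],
                  function(z) length(unique(z[!is.na(z)])))
    if (any(nzy > 1L)) {
      validation_error("zygosity differs within a twin pair")
    }
  }
  df
}

#' Load a clock coefficient table
#'
#' Reads a coefficient CSV in the published layout: a probe-id column
#' (default \code{CpGmarker}), a coefficient column (default
#' \code{CoefficientTraining}), one intercept row under the reserved token
#' \code{"(Intercept)"}, and optional extra columns (e.g.
#' \code{CoefficientTrainingShrunk}, \code{medianByCpGYoung},
#' \code{medianByCpGOld}, \code{varByCpG}, \code{GoldStandardMean}).  Row
#' order is irrelevant to all downstream results.  Lines starting with
#' \code{#} may carry \code{key=value} metadata (e.g. \code{adult_age});
#' they are returned in the \code{"metadata"} attribute.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named list remapping this package's column
#'   names onto the file's, e.g.
#'   \code{list(probe_id = "ID", coefficient = "weight")}.
#' @return A data.frame with standardized columns \code{probe_id} and
#'   \code{coefficient} (plus any extras), the intercept row removed into
#'   attribute \code{"intercept"}, rows sorted by \code{probe_id}.
#' @export
load_coefficients <- function(path, column_map = NULL) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  meta <- read_hash_metadata(path)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE, na.strings = c("NA", ""))
  probe_col <- column_map$probe_id %||% "CpGmarker"
  coef_col <- column_map$coefficient %||% "CoefficientTraining"
  for (col in c(probe_col, coef_col)) {
    if (!col %in% colnames(df)) {
      format_error(sprintf("coefficient table lacks column '%s'", col))
    }
  }
  names(df)[match(probe_col, names(df))] <- "probe_id"
  names(df)[match(coef_col, names(df))] <- "coefficient"
  df$probe_id <- as.character(df$probe_id)
  df$coefficient <- as.numeric(df$coefficient)
  n_int <- sum(df$probe_id == INTERCEPT_TOKEN)
  if (n_int != 1L) {
    format_error(sprintf(
      "coefficient table must contain exactly one '%s' row (found %d)",
      INTERCEPT_TOKEN, n_int))
  }
  if (anyDuplicated(df$probe_id)) {
    format_error(sprintf("duplicate probe id: %s",
                         df$probe_id[duplicated(df$probe_id)][1L]))
  }
  if (any(is.na(df$coefficient))) {
    format_error("coefficient column is not fully populated")
  }
  intercept <- df$coefficient[df$probe_id == INTERCEPT_TOKEN]
  out <- df[df$probe_id != INTERCEPT_TOKEN, , drop = FALSE]
  out <- out[order(out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "intercept") <- intercept
  attr(out, "metadata") <- meta
  class(out) <- c("coefficient_table", "data.frame")
  out
}

#' Number of clock CpGs in a coefficient table or clock model
#' @param x A \code{coefficient_table} or \code{dnam_clock} object.
#' @return Integer count of CpGs carrying a (nonzero, for models)
#'   coefficient.
#' @export
clock_size <- function(x) {
  if (inherits(x, "dnam_clock")) return(length(x$coefficients))
  if (inherits(x, "coefficient_table")) return(nrow(x))
  domain_error("clock_size() expects a coefficient_table or dnam_clock")
}

#' Mean absolute young/old methylation difference of clock CpGs
#'
#' For a coefficient table carrying per-CpG median beta values in young
#' (< 35 years) and old (> 55 years) subjects, returns the mean over CpGs
#' of the absolute difference between the two medians -- the standard
#' summary of how small the marginal age effect on individual clock CpGs
#' is.
#'
#' @param tab A \code{coefficient_table} with columns
#'   \code{medianByCpGYoung} and \code{medianByCpGOld}.
#' @return A single non-negative number on the beta scale.
#' @export
clock_cpg_effect_size <- function(tab) {
  for (col in c("medianByCpGYoung", "medianByCpGOld")) {
    if (!col %in% colnames(tab)) {
      format_error(sprintf("coefficient table lacks column '%s'", col))
    }
  }
  mean(abs(tab$medianByCpGYoung - tab$medianByCpGOld), na.rm = TRUE)
}

#' Save per-sample DNAm age predictions to CSV
#'
#' @param pred Data.frame with one row per sample; must contain
#'   \code{sample_id} and \code{dnam_age}; further columns (chronological
#'   age, acceleration measures, imputation counts) are written as-is.
#'   Missing values are written as \code{NA}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_predictions <- function(pred, path) {
  for (col in c("sample_id", "dnam_age")) {
    if (!col %in% colnames(pred)) {
      format_error(sprintf("prediction table lacks column '%s'", col))
    }
  }
  write_csv_safely(pred, path)
}

# write.csv wrapper: >= 15 significant digits, classed I/O error on failure
write_csv_safely <- function(df, path, comments = character()) {
  old <- options(digits = 15)
  on.exit(options(old), add = TRUE)
  tryCatch({
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    if (length(comments)) writeLines(paste0("# ", comments), con)
    utils::write.csv(df, con, row.names = FALSE, na = "NA")
  }, error = function(e) {
    io_error(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  })
  invisible(path)
}

read_hash_metadata <- function(path) {
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(key)]] <- if (is.na(num)) trimws(val) else num
    }
  }
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a
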