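# The penalized-regression clock: elastic-net fit of calibrated age on CpG
# beta values, penalty-path shrinkage, DNAm-age prediction, and age
# acceleration.

#' Fit a DNA methylation age clock
#'
#' Regresses the calibration transform of chronological age on CpG beta
#' values with an elastic net.  The penalty strength lambda is chosen by
#' k-fold cross-validation minimizing mean squared error on the transformed
#' scale (no one-standard-error rule); the mixing parameter alpha defaults
#' to 0.5.  Probes with \code{max_missing} or more missing values among the
#' training samples are excluded; remaining missing entries are imputed
#' with training probe means.  Predictors are standardized internally for
#' fitting and coefficients are reported on the raw beta scale, so the
#' fitted model can be serialized as a coefficient table and used directly
#' for prediction.
#'
#' CpGs whose fitted coefficient is exactly zero are dropped; the retained
#' CpGs are the model's clock CpGs.  The training probe means and the
#' pooled clock-probe beta distribution are stored as the gold standard for
#' test-time imputation and normalization.
#'
#' @param betas Probes x samples beta matrix (training data).
#' @param samples Sample table with \code{sample_id} and \code{age};
#'   \code{dataset_id}, when present, stratifies the CV folds.
#' @param alpha Elastic-net mixing parameter in (0, 1]; default 0.5.
#' @param cv_folds Number of CV folds (>= 3); default 10.
#' @param seed Integer seed controlling fold assignment.
#' @param max_missing Probes with this many or more missing training values
#'   are excluded (default 10).
#' @param adult_age Calibration knot in years (default 20).
#' @return An object of class \code{dnam_clock}: list with
#'   \code{coefficients} (named, nonzero, beta scale), \code{intercept},
#'   \code{adult_age}, \code{alpha}, \code{lambda}, \code{cv_folds},
#'   \code{seed}, \code{n_train_samples}, \code{n_train_probes},
#'   \code{gold_standard}, \code{path} (lambda/df penalty path) and
#'   \code{shrunken}.
#' @export
fit_clock <- function(betas, samples, alpha = 0.5, cv_folds = 10L,
                      seed = 1L, max_missing = 10L, adult_age = 20) {
  samples <- validate_sample_table(samples)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    config_error("'alpha' must lie in (0, 1]")
  }
  if (!is_scalar_number(cv_folds) || cv_folds < 3) {
    config_error("'cv_folds' must be >= 3")
  }
  aged <- samples[!is.na(samples$age) & samples$sample_id %in% colnames(betas), ]
  n <- nrow(aged)
  if (n < cv_folds) {
    config_error(sprintf("only %d usable samples for %d CV folds", n, cv_folds))
  }
  if (n < 20L) {
    data_error(sprintf("need >= 20 samples with non-missing age, got %d", n))
  }
  B <- betas[, aged$sample_id, drop = FALSE]
  keep <- probe_missing_counts(B) < max_missing & rowSums(!is.na(B)) > 0L
  B <- B[keep, , drop = FALSE]
  if (nrow(B) == 0L) data_error("zero usable probes after missing-value filter")
  gs_all <- suppressWarnings(build_gold_standard(B))
  B <- impute_missing(B, gs_all)
  y <- transform_age(aged$age, adult_age)

  variable <- apply(B, 1L, stats::var) > 0
  if (!any(variable)) {
    return(new_dnam_clock(
      coefficients = stats::setNames(numeric(0), character(0)),
      intercept = mean(y), adult_age = adult_age, alpha = alpha,
      lambda = NA_real_, cv_folds = cv_folds, seed = seed,
      n_train_samples = n, n_train_probes = nrow(B),
      gold_standard = gs_all, path = NULL))
  }

  x <- t(B[variable, , drop = FALSE])
  foldid <- make_foldid(aged, cv_folds, seed)
  cvfit <- tryCatch(
    glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                      standardize = TRUE, thresh = 1e-10),
    error = function(e) stop_dnam("dnamclock_numerical_error",
                                  paste("elastic-net fit failed:",
                                        conditionMessage(e))))
  co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[, 1L]
  w <- co[-1L]
  w <- w[w != 0]
  clock_probes <- names(w)
  gs <- if (length(clock_probes)) {
    suppressWarnings(build_gold_standard(
      betas[clock_probes, aged$sample_id, drop = FALSE]))
  } else gs_all
  new_dnam_clock(
    coefficients = w, intercept = unname(co[1L]), adult_age = adult_age,
    alpha = alpha, lambda = cvfit$lambda.min, cv_folds = cv_folds,
    seed = seed, n_train_samples = n, n_train_probes = ncol(x),
    gold_standard = gs,
    path = data.frame(lambda = cvfit$glmnet.fit$lambda,
                      df = cvfit$glmnet.fit$df))
}

new_dnam_clock <- function(coefficients, intercept, adult_age, alpha, lambda,
                           cv_folds, seed, n_train_samples, n_train_probes,
                           gold_standard, path, shrunken = FALSE,
                           shrink_warning = NULL) {
  stopifnot(all(is.finite(coefficients)), is.finite(intercept))
  structure(
    list(coefficients = coefficients, intercept = intercept,
         adult_age = adult_age, alpha = alpha, lambda = lambda,
         cv_folds = cv_folds, seed = seed,
         n_train_samples = n_train_samples, n_train_probes = n_train_probes,
         gold_standard = gold_standard, path = path, shrunken = shrunken,
         shrink_warning = shrink_warning),
    class = "dnam_clock")
}

#' @export
print.dnam_clock <- function(x, ...) {
  cat(sprintf("DNAm age clock: %d CpGs%s\n", clock_size(x),
              if (isTRUE(x$shrunken)) " (shrunken)" else ""))
  cat(sprintf("  intercept %.4f, alpha %.2f, lambda %s, adult_age %g\n",
              x$intercept, x$alpha,
              if (is.na(x$lambda)) "NA" else sprintf("%.5g", x$lambda),
              x$adult_age))
  cat(sprintf("  trained on %d samples x %d probes\n",
              x$n_train_samples, x$n_train_probes))
  if (!is.null(x$shrink_warning)) cat("  warning:", x$shrink_warning, "\n")
  invisible(x)
}

# CV fold ids: stratified by dataset_id when available so every fold sees
# every data set; otherwise a plain random split.  Deterministic in `seed`.
make_foldid <- function(aged, cv_folds, seed) {
  n <- nrow(aged)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  foldid <- integer(n)
  if ("dataset_id" %in% colnames(aged) && !all(is.na(aged$dataset_id))) {
    grp <- as.character(aged$dataset_id)
    grp[is.na(grp)] <- ".na"
    for (g in sort(unique(grp))) {
      idx <- which(grp == g)
      foldid[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
  } else {
    foldid <- sample(rep_len(seq_len(cv_folds), n))
  }
  foldid
}

#' Shrink a clock to fewer CpGs along the penalty path
#'
#' Refits the elastic net restricted to the model's clock CpGs while
#' increasing the penalty until at most \code{target_size} CpGs retain a
#' nonzero coefficient, then returns the least-penalized model meeting the
#' size bound.  The search grid starts at the parent model's lambda, where
#' the restricted fit reproduces the parent coefficients, so shrinking to
#' the current size is a no-op up to solver tolerance.  If even the
#' heaviest penalty on the grid cannot reach the target the closest
#' achievable size is returned and recorded in \code{shrink_warning}.
#'
#' @param model A \code{dnam_clock} with at least one CpG.
#' @param betas Training beta matrix (probes x samples).
#' @param samples Training sample table.
#' @param target_size Desired maximum number of clock CpGs (>= 0).
#' @return A new \code{dnam_clock} flagged \code{shrunken = TRUE}.
#' @export
shrink_clock <- function(model, betas, samples, target_size) {
  stopifnot(inherits(model, "dnam_clock"))
  p <- clock_size(model)
  if (p == 0L) data_error("cannot shrink an intercept-only clock")
  if (!is_scalar_number(target_size) || target_size < 0 || target_size > p) {
    config_error(sprintf("'target_size' must be in [0, %d]", p))
  }
  samples <- validate_sample_table(samples)
  aged <- samples[!is.na(samples$age) & samples$sample_id %in% colnames(betas), ]
  probes <- names(model$coefficients)
  missing_probes <- setdiff(probes, rownames(betas))
  if (length(missing_probes)) {
    data_error(sprintf("%d clock CpGs absent from the beta matrix",
                       length(missing_probes)))
  }
  B <- betas[probes, aged$sample_id, drop = FALSE]
  B <- impute_missing(B, model$gold_standard)
  x <- t(B)
  y <- transform_age(aged$age, model$adult_age)

  lambda0 <- model$lambda
  if (!is.finite(lambda0)) lambda0 <- 1e-4
  # upper end of the grid: the smallest penalty that zeroes every
  # coefficient of the standardized problem, with headroom
  xs <- scale(x, center = TRUE,
              scale = apply(x, 2L, stats::sd) * sqrt((nrow(x) - 1) / nrow(x)))
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / (nrow(x) * model$alpha)
  grid <- exp(seq(log(max(lmax * 1.5, lambda0 * 1.01)), log(lambda0),
                  length.out = 200L))
  fit <- glmnet::glmnet(x, y, alpha = model$alpha, lambda = grid,
                        standardize = TRUE, thresh = 1e-10)
  ok <- which(fit$df <= target_size)
  warn <- NULL
  if (length(ok)) {
    pick <- max(ok)  # smallest qualifying lambda (grid is decreasing)
  } else {
    pick <- which.min(fit$df)
    warn <- sprintf("target size %d unreachable; closest achievable is %d",
                    target_size, fit$df[pick])
  }
  co <- as.matrix(stats::coef(fit, s = fit$lambda[pick], exact = FALSE))[, 1L]
  w <- co[-1L]
  w <- w[w != 0]
  gs <- if (length(w)) {
    suppressWarnings(build_gold_standard(
      betas[names(w), aged$sample_id, drop = FALSE]))
  } else model$gold_standard
  new_dnam_clock(
    coefficients = w, intercept = unname(co[1L]),
    adult_age = model$adult_age, alpha = model$alpha,
    lambda = fit$lambda[pick], cv_folds = model$cv_folds, seed = model$seed,
    n_train_samples = nrow(aged), n_train_probes = length(probes),
    gold_standard = gs,
    path = data.frame(lambda = fit$lambda, df = fit$df),
    shrunken = TRUE, shrink_warning = warn)
}

#' Predict DNAm age from beta values
#'
#' Forms the linear clock score \eqn{intercept + \sum_i w_i \beta_i} per
#' sample and converts it to years with the inverse calibration transform.
#' Clock CpGs missing from the input (absent probes or missing cells) are
#' imputed from the model's gold-standard means and counted per sample.
#' Samples missing more than half of the clock CpGs are flagged; samples
#' missing all of them get no prediction and an error record.
#'
#' @param model A \code{dnam_clock}.
#' @param betas Probes x samples beta matrix (any probe superset or subset
#'   of the clock CpGs).
#' @return Data.frame of class \code{dnam_prediction} with columns
#'   \code{sample_id}, \code{linear_score}, \code{dnam_age},
#'   \code{n_imputed_probes}, \code{warn_high_missing},
#'   \code{error_all_missing}.  \code{dnam_age} is exactly
#'   \code{inverse_transform_age(linear_score)}.
#' @export
predict_dnam_age <- function(model, betas) {
  stopifnot(inherits(model, "dnam_clock"))
  sample_ids <- colnames(betas)
  n <- length(sample_ids)
  probes <- names(model$coefficients)
  p <- length(probes)
  if (p == 0L) {
    score <- rep(model$intercept, n)
    res <- data.frame(sample_id = sample_ids, linear_score = score,
                      dnam_age = inverse_transform_age(score, model$adult_age),
                      n_imputed_probes = 0L, warn_high_missing = FALSE,
                      error_all_missing = FALSE, stringsAsFactors = FALSE)
    class(res) <- c("dnam_prediction", "data.frame")
    return(res)
  }
  mat <- matrix(NA_real_, nrow = p, ncol = n,
                dimnames = list(probes, sample_ids))
  present <- intersect(probes, rownames(betas))
  mat[present, ] <- betas[present, , drop = FALSE]
  n_imputed <- colSums(is.na(mat))
  all_missing <- n_imputed == p
  gs_means <- model$gold_standard$means[probes]
  if (any(is.na(gs_means))) {
    data_error("model gold standard does not cover all clock CpGs")
  }
  fill <- is.na(mat)
  mat[fill] <- gs_means[row(mat)[fill]]
  score <- model$intercept + as.numeric(crossprod(mat, model$coefficients))
  dnam <- rep(NA_real_, n)
  ok <- !all_missing
  dnam[ok] <- inverse_transform_age(score[ok], model$adult_age)
  score[!ok] <- NA_real_
  res <- data.frame(sample_id = sample_ids, linear_score = score,
                    dnam_age = dnam, n_imputed_probes = as.integer(n_imputed),
                    warn_high_missing = n_imputed > p / 2 & !all_missing,
                    error_all_missing = all_missing,
                    stringsAsFactors = FALSE)
  class(res) <- c("dnam_prediction", "data.frame")
  res
}

#' Age acceleration from DNAm age predictions
#'
#' Two standard measures: \code{"difference"} is DNAm age minus
#' chronological age; \code{"residual"} is the residual from an ordinary
#' least-squares regression of DNAm age on age within the provided sample
#' set (mean zero, uncorrelated with age by construction).
#'
#' @param pred A [predict_dnam_age()] result (or any data.frame with
#'   \code{sample_id} and \code{dnam_age}).
#' @param samples Sample table supplying chronological \code{age}.
#' @param method \code{"difference"} or \code{"residual"}.
#' @return \code{pred} with an added column \code{acceleration_diff} or
#'   \code{acceleration_resid} (years; \code{NA} where age or DNAm age is
#'   missing).
#' @export
compute_age_acceleration <- function(pred, samples,
                                     method = c("difference", "residual")) {
  method <- match.arg(method)
  samples <- validate_sample_table(samples)
  age <- samples$age[match(pred$sample_id, samples$sample_id)]
  if (method == "difference") {
    pred$acceleration_diff <- pred$dnam_age - age
    return(pred)
  }
  ok <- !is.na(age) & !is.na(pred$dnam_age)
  if (sum(ok) < 3L) {
    stop_dnam("dnamclock_degenerate_error",
              "residual acceleration needs >= 3 samples with age")
  }
  if (stats::var(age[ok]) == 0) {
    stop_dnam("dnamclock_degenerate_error",
              "residual acceleration undefined for constant age")
  }
  fit <- stats::lm.fit(cbind(1, age[ok]), pred$dnam_age[ok])
  accel <- rep(NA_real_, nrow(pred))
  accel[ok] <- fit$residuals
  pred$acceleration_resid <- accel
  pred
}

#' Serialize a clock model as a coefficient table CSV
#'
#' Writes the published coefficient-file layout: \code{CpGmarker} /
#' \code{CoefficientTraining} columns with one \code{"(Intercept)"} row,
#' plus a \code{GoldStandardMean} column for test-time imputation.  Model
#' metadata (adult_age, alpha, lambda, seed, shrunken) travels in
#' \code{# key=value} header lines.
#'
#' @param model A \code{dnam_clock}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "dnam_clock"))
  probes <- names(model$coefficients)
  df <- data.frame(
    CpGmarker = c(INTERCEPT_TOKEN, probes),
    CoefficientTraining = c(model$intercept, unname(model$coefficients)),
    GoldStandardMean = c(NA_real_,
                         unname(model$gold_standard$means[probes])),
    stringsAsFactors = FALSE)
  write_csv_safely(df, path, comments = c(
    sprintf("adult_age=%.15g", model$adult_age),
    sprintf("alpha=%.15g", model$alpha),
    sprintf("lambda=%.15g", model$lambda),
    sprintf("seed=%d", as.integer(model$seed)),
    sprintf("shrunken=%s", if (isTRUE(model$shrunken)) "1" else "0")))
}

#' Load a clock model from a coefficient table CSV
#'
#' Accepts any coefficient table in the [load_coefficients()] dialect.  If
#' the file carries a \code{GoldStandardMean} column those means are used
#' for imputation and (sorted) as the normalization reference; a model
#' reconstructed from CSV therefore normalizes against the distribution of
#' per-probe gold-standard means rather than the pooled training betas.
#'
#' @param path Path to a coefficient CSV.
#' @param column_map Optional column remapping, see [load_coefficients()].
#' @param adult_age Calibration knot override; defaults to the file's
#'   \code{adult_age} metadata, else 20.
#' @return A \code{dnam_clock}.
#' @export
load_clock_model <- function(path, column_map = NULL, adult_age = NULL) {
  tab <- load_coefficients(path, column_map = column_map)
  meta <- attr(tab, "metadata")
  adult_age <- adult_age %||% meta$adult_age %||% 20
  w <- stats::setNames(tab$coefficient, tab$probe_id)
  w <- w[w != 0]
  gs_means <- if ("GoldStandardMean" %in% colnames(tab)) {
    stats::setNames(tab$GoldStandardMean, tab$probe_id)[names(w)]
  } else {
    stats::setNames(rep(0.5, length(w)), names(w))
  }
  gs_means <- gs_means[!is.na(gs_means)]
  gs <- structure(list(means = gs_means, quantiles = sort(gs_means)),
                  class = "gold_standard")
  new_dnam_clock(
    coefficients = w, intercept = attr(tab, "intercept"),
    adult_age = adult_age, alpha = meta$alpha %||% NA_real_,
    lambda = meta$lambda %||% NA_real_, cv_folds = NA_integer_,
    seed = meta$seed %||% NA_integer_, n_train_samples = NA_integer_,
    n_train_probes = nrow(tab), gold_standard = gs, path = NULL,
    shrunken = identical(meta$shrunken, 1))
}
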