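# Evaluation and downstream statistics: accuracy measures,
# leave-one-data-set-out cross-validation, Falconer twin heritability,
# biweight midcorrelation, Stouffer meta-analysis of within-data-set age
# correlations, tissue-effect F statistics, annotation enrichment, and the
# coefficient of variation.  Sample standard deviations use the n-1
# denominator throughout.

#' Predictive accuracy of DNAm age
#'
#' Three complementary measures: the age correlation (Pearson r between
#' DNAm age and chronological age), the median error (median absolute
#' difference in years -- an error of 3.6 years means DNAm age is within
#' 3.6 years of chronological age for half the subjects), and the average
#' age acceleration (mean of DNAm age minus age, which detects systematic
#' offsets).  The correlation is undefined (NA, never 0) when either
#' vector is constant, e.g. in cohorts of newborns.
#'
#' @param dnam_ages,ages Paired numeric vectors in years; pairs with a
#'   missing value are dropped.
#' @return List of class \code{accuracy_report} with
#'   \code{age_correlation}, \code{median_error},
#'   \code{average_age_acceleration}, \code{n}.
#' @export
accuracy_report <- function(dnam_ages, ages) {
  stopifnot(length(dnam_ages) == length(ages))
  ok <- !is.na(dnam_ages) & !is.na(ages)
  d <- dnam_ages[ok]
  a <- ages[ok]
  n <- length(d)
  if (n < 1L) data_error("no complete (dnam_age, age) pair")
  r <- if (n >= 2L && stats::sd(a) > 0 && stats::sd(d) > 0) {
    stats::cor(d, a)
  } else NA_real_
  structure(list(age_correlation = r,
                 median_error = stats::median(abs(d - a)),
                 average_age_acceleration = mean(d - a),
                 n = n),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("n = %d, age correlation = %s, median error = %.2f y, avg acceleration = %.2f y\n",
              x$n,
              if (is.na(x$age_correlation)) "NA" else sprintf("%.3f", x$age_correlation),
              x$median_error, x$average_age_acceleration))
  invisible(x)
}

#' Leave-one-data-set-out cross-validation of clock accuracy
#'
#' For each data set D, fits a clock on all samples outside D (the held-out
#' set contributes nothing to fitting, fold assignment or gold-standard
#' construction), predicts DNAm age within D, and reports the per-data-set
#' accuracy.  Because whole data sets are held out, the estimates are
#' unbiased by batch; they also reveal that the attainable age correlation
#' in a data set is governed by its age standard deviation, which the
#' summary table reports alongside.
#'
#' @param betas Probes x samples beta matrix.
#' @param samples Sample table with \code{dataset_id} (>= 2 distinct).
#' @param ... Passed to [fit_clock()] (alpha, cv_folds, seed, max_missing,
#'   adult_age).
#' @param return_models If TRUE the per-fold fitted clocks are returned.
#' @return List with \code{summary} (data.frame: dataset, n, age_sd,
#'   age_correlation, median_error, average_age_acceleration),
#'   \code{reports} (named list of \code{accuracy_report}s),
#'   \code{predictions} (named list) and optionally \code{models}.
#' @export
loocv_by_dataset <- function(betas, samples, ..., return_models = FALSE) {
  samples <- validate_sample_table(samples)
  if (!"dataset_id" %in% colnames(samples)) {
    config_error("LOOCV requires a dataset_id column")
  }
  ds <- sort(unique(samples$dataset_id[!is.na(samples$dataset_id)]))
  if (length(ds) < 2L) config_error("LOOCV requires >= 2 distinct data sets")
  reports <- list()
  preds <- list()
  models <- list()
  rows <- list()
  for (d in ds) {
    held <- samples[!is.na(samples$dataset_id) & samples$dataset_id == d, ]
    train <- samples[is.na(samples$dataset_id) | samples$dataset_id != d, ]
    model <- fit_clock(betas[, intersect(colnames(betas), train$sample_id),
                             drop = FALSE],
                       train, ...)
    pred <- predict_dnam_age(
      model, betas[, intersect(colnames(betas), held$sample_id), drop = FALSE])
    age <- held$age[match(pred$sample_id, held$sample_id)]
    rep_d <- accuracy_report(pred$dnam_age, age)
    reports[[as.character(d)]] <- rep_d
    preds[[as.character(d)]] <- pred
    if (return_models) models[[as.character(d)]] <- model
    rows[[as.character(d)]] <- data.frame(
      dataset = as.character(d), n = rep_d$n,
      age_sd = if (sum(!is.na(age)) >= 2L) stats::sd(age, na.rm = TRUE) else NA_real_,
      age_correlation = rep_d$age_correlation,
      median_error = rep_d$median_error,
      average_age_acceleration = rep_d$average_age_acceleration,
      stringsAsFactors = FALSE)
  }
  out <- list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              reports = reports, predictions = preds)
  if (return_models) out$models <- models
  out
}

#' Broad-sense heritability of age acceleration from twin pairs
#'
#' Falconer's formula \eqn{H^2 = 2(cor(MZ) - cor(DZ))}, clamped to
#' \[0, 1\]: within each zygosity the correlation between co-twins' age
#' acceleration is computed, and twice the MZ-DZ difference estimates the
#' broad-sense heritability.  By default the co-twin correlation is the
#' symmetric double-entry correlation (each pair contributes both
#' orderings), which is deterministic and equals the expectation over
#' random within-pair orderings; \code{ordering = "random"} instead draws
#' one random ordering per pair from \code{seed}.
#'
#' @param pairs Data.frame with columns \code{pair_id}, \code{zygosity}
#'   ("MZ"/"DZ") and \code{acceleration} (years), two rows per pair.  Rows
#'   with missing zygosity are excluded and counted.
#' @param ordering \code{"double_entry"} (default) or \code{"random"}.
#' @param seed Seed for \code{ordering = "random"}.
#' @return List of class \code{heritability_estimate}: \code{cor_mz},
#'   \code{cor_dz}, \code{h2} (clamped), \code{h2_unclamped},
#'   \code{n_mz}, \code{n_dz}, \code{n_excluded}.
#' @export
falconer_heritability <- function(pairs, ordering = c("double_entry", "random"),
                                  seed = 1L) {
  ordering <- match.arg(ordering)
  for (col in c("pair_id", "zygosity", "acceleration")) {
    if (!col %in% colnames(pairs)) {
      format_error(sprintf("twin table lacks column '%s'", col))
    }
  }
  n_excluded <- sum(is.na(pairs$zygosity))
  pairs <- pairs[!is.na(pairs$zygosity) & !is.na(pairs$acceleration), ]
  twin_cor <- function(zy) {
    sub <- pairs[pairs$zygosity == zy, ]
    split_acc <- split(sub$acceleration, sub$pair_id)
    split_acc <- split_acc[lengths(split_acc) == 2L]
    k <- length(split_acc)
    if (k < 3L) {
      data_error(sprintf("need >= 3 complete %s pairs, got %d", zy, k))
    }
    t1 <- vapply(split_acc, `[`, numeric(1), 1L)
    t2 <- vapply(split_acc, `[`, numeric(1), 2L)
    if (ordering == "random") {
      set.seed(as.integer(seed) %% .Machine$integer.max)
      swap <- sample(c(TRUE, FALSE), k, replace = TRUE)
      tmp <- t1[swap]; t1[swap] <- t2[swap]; t2[swap] <- tmp
      r <- stats::cor(t1, t2)
    } else {
      r <- stats::cor(c(t1, t2), c(t2, t1))
    }
    list(r = r, k = k)
  }
  mz <- twin_cor("MZ")
  dz <- twin_cor("DZ")
  h2_raw <- 2 * (mz$r - dz$r)
  structure(list(cor_mz = mz$r, cor_dz = dz$r,
                 h2 = clamp(h2_raw, 0, 1), h2_unclamped = h2_raw,
                 n_mz = mz$k, n_dz = dz$k, n_excluded = n_excluded),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("cor(MZ) = %.3f (n = %d), cor(DZ) = %.3f (n = %d), H2 = %.3f\n",
              x$cor_mz, x$n_mz, x$cor_dz, x$n_dz, x$h2))
  invisible(x)
}

#' Biweight midcorrelation
#'
#' Robust correlation: each vector is centered at its median, scaled by
#' nine times its (unscaled) median absolute deviation, and points are
#' down-weighted by \eqn{w_i = (1 - u_i^2)^2} with zero weight beyond nine
#' MADs; the correlation is the normalized weighted cross-product.  If a
#' vector's MAD is zero that vector falls back to Pearson-style
#' mean-centering with unit weights (so with both MADs zero the statistic
#' is exactly the Pearson correlation).
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return Correlation in \[-1, 1\], or NA if all weights vanish.
#' @export
biweight_midcorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) data_error("biweight midcorrelation needs >= 3 pairs")
  wt <- function(v) {
    med <- stats::median(v)
    mad0 <- stats::median(abs(v - med))
    if (mad0 == 0) {
      return(list(centered = v - mean(v), w = rep(1, length(v))))
    }
    u <- (v - med) / (9 * mad0)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    list(centered = v - med, w = w)
  }
  a <- wt(x); b <- wt(y)
  xt <- a$centered * a$w
  yt <- b$centered * b$w
  denom <- sqrt(sum(xt^2)) * sqrt(sum(yt^2))
  if (denom == 0) return(NA_real_)
  sum(xt * yt) / denom
}

#' Meta-analysis of within-data-set age correlations per CpG
#'
#' Measures "pure" age effects, unconfounded by tissue or batch, by
#' computing each probe's Pearson correlation with age within each data
#' set only, Fisher-z transforming, and combining across data sets with
#' the inverse-variance weighted (Stouffer) z:
#' \eqn{Z = \sum_k (n_k - 3) z_k / \sqrt{\sum_k (n_k - 3)}}, which is
#' standard normal under the null since \eqn{var(z_k) = 1/(n_k - 3)}.
#' Equivalently, each data set's unit-variance score
#' \eqn{\sqrt{n_k - 3}\, z_k} enters with weight \eqn{\sqrt{n_k - 3}}.
#' The signed \eqn{\log_{10}} p-value is positive for CpGs that
#' hypermethylate with age.
#'
#' @param betas Probes x samples beta matrix.
#' @param samples Sample table with \code{age} and \code{dataset_id};
#'   normally >= 2 data sets with >= 5 aged samples each (with a single
#'   qualifying data set the combined Z degenerates to that data set's
#'   Fisher-z statistic).
#' @param min_n Minimum complete pairs for a data set to enter a probe's
#'   combination (default 5; must exceed 3 for the Fisher-z weight).
#' @return Data.frame: \code{probe_id}, \code{combined_z},
#'   \code{p_value}, \code{signed_log10_p}, \code{n_datasets}.  The
#'   per-data-set correlations are attached as attribute
#'   \code{"dataset_correlations"} (probes x data sets matrix).
#' @export
meta_analysis_age_correlation <- function(betas, samples, min_n = 5L) {
  samples <- validate_sample_table(samples)
  if (!"dataset_id" %in% colnames(samples)) {
    config_error("meta-analysis requires a dataset_id column")
  }
  if (min_n <= 3L) config_error("'min_n' must exceed 3")
  samples <- samples[!is.na(samples$age) &
                       samples$sample_id %in% colnames(betas), ]
  ds <- sort(unique(samples$dataset_id[!is.na(samples$dataset_id)]))
  ds <- ds[vapply(ds, function(d)
    sum(samples$dataset_id == d, na.rm = TRUE) >= min_n, logical(1))]
  if (length(ds) < 1L) {
    config_error("meta-analysis requires >= 1 data set with enough aged samples")
  }
  probes <- rownames(betas)
  cors <- matrix(NA_real_, length(probes), length(ds),
                 dimnames = list(probes, as.character(ds)))
  ns <- matrix(0L, length(probes), length(ds))
  for (j in seq_along(ds)) {
    sub <- samples[samples$dataset_id == ds[j], ]
    B <- betas[, sub$sample_id, drop = FALSE]
    age <- sub$age
    for (i in seq_along(probes)) {
      v <- B[i, ]
      ok <- !is.na(v)
      if (sum(ok) >= min_n && stats::sd(v[ok]) > 0 && stats::sd(age[ok]) > 0) {
        cors[i, j] <- stats::cor(v[ok], age[ok])
        ns[i, j] <- sum(ok)
      }
    }
  }
  z <- atanh(clamp(cors, -1 + 1e-12, 1 - 1e-12))
  wts <- pmax(ns - 3L, 0L)
  wts[is.na(cors)] <- 0
  num <- rowSums(wts * z, na.rm = TRUE)
  den <- sqrt(rowSums(wts))
  combined_z <- ifelse(den > 0, num / den, NA_real_)
  # two-sided normal tail on the log scale to keep extreme CpGs finite
  log_p <- log(2) + stats::pnorm(abs(combined_z), lower.tail = FALSE,
                                 log.p = TRUE)
  p <- exp(log_p)
  signed_log10_p <- sign(combined_z) * (-log_p / log(10))
  out <- data.frame(probe_id = probes, combined_z = combined_z,
                    p_value = p, signed_log10_p = signed_log10_p,
                    n_datasets = rowSums(wts > 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dataset_correlations") <- cors
  out
}

#' Per-CpG tissue-effect F statistics adjusted for age
#'
#' Regresses each probe's beta values on age plus tissue indicators and
#' reports the ANOVA F statistic for the tissue factor
#' (extra-sum-of-squares against the age-only model).  The F statistic is
#' reported without a p-value.  Probes with a rank-deficient design (e.g.
#' a tissue level lost to missingness) are flagged with a missing F.
#'
#' @param betas Probes x samples beta matrix.
#' @param samples Sample table with \code{age} and \code{tissue}
#'   (>= 2 tissue labels; at least 2 more samples than model parameters).
#' @return Data.frame: \code{probe_id}, \code{f_tissue}, \code{df1},
#'   \code{df2}.
#' @export
tissue_f_statistics <- function(betas, samples) {
  samples <- validate_sample_table(samples)
  if (!"tissue" %in% colnames(samples)) {
    config_error("tissue F statistics require a tissue column")
  }
  samples <- samples[!is.na(samples$age) & !is.na(samples$tissue) &
                       samples$sample_id %in% colnames(betas), ]
  tissues <- unique(samples$tissue)
  if (length(tissues) < 2L) {
    config_error("tissue F statistics require >= 2 tissue labels")
  }
  B <- betas[, samples$sample_id, drop = FALSE]
  tissue <- factor(samples$tissue)
  age <- samples$age
  x_full <- stats::model.matrix(~ age + tissue)
  x_red <- stats::model.matrix(~ age)
  p_full <- ncol(x_full)
  if (nrow(x_full) < p_full + 2L) {
    config_error("need at least 2 more samples than model parameters")
  }
  q_full <- qr(x_full)
  q_red <- qr(x_red)
  probes <- rownames(B)
  f <- df1 <- df2 <- rep(NA_real_, length(probes))
  for (i in seq_along(probes)) {
    yv <- B[i, ]
    ok <- !is.na(yv)
    if (all(ok)) {
      rf <- qr.resid(q_full, yv)
      rr <- qr.resid(q_red, yv)
      n_i <- length(yv); qf <- q_full; pf <- q_full$rank
      q1 <- pf - q_red$rank
    } else {
      xi <- x_full[ok, , drop = FALSE]
      # a tissue level can disappear with missingness: rank-deficient
      if (qr(xi)$rank < ncol(xi)) next
      rf <- qr.resid(qr(xi), yv[ok])
      rr <- qr.resid(qr(x_red[ok, , drop = FALSE]), yv[ok])
      n_i <- sum(ok); pf <- ncol(xi)
      q1 <- pf - ncol(x_red)
    }
    rss_full <- sum(rf^2)
    rss_red <- sum(rr^2)
    d2 <- n_i - pf
    if (d2 <= 0 || rss_full <= 0) next
    f[i] <- ((rss_red - rss_full) / q1) / (rss_full / d2)
    df1[i] <- q1
    df2[i] <- d2
  }
  data.frame(probe_id = probes, f_tissue = f, df1 = df1, df2 = df2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Enrichment of a probe set in annotation categories
#'
#' For each category label, builds the 2x2 table (selected / not selected
#' x in category / not in category) over the probe universe and reports
#' the sample odds ratio and the two-sided Fisher exact p-value.  To test
#' hyper- and hypomethylating clock CpGs separately (e.g. the 193/160
#' split), call once per direction subset.
#'
#' @param selected Character vector of selected probes (subset of
#'   \code{universe}).
#' @param categories Named character vector mapping probe ids to category
#'   labels (probes absent from it count as in no category), or a
#'   data.frame with columns \code{probe_id} and \code{category}.
#' @param universe Character vector of all candidate probes.
#' @return Data.frame: \code{category}, \code{a}, \code{b}, \code{c},
#'   \code{d} (table counts), \code{odds_ratio}, \code{p_value}.
#' @export
category_enrichment <- function(selected, categories, universe) {
  if (length(universe) == 0L) data_error("empty probe universe")
  if (is.data.frame(categories)) {
    categories <- stats::setNames(as.character(categories$category),
                                  categories$probe_id)
  }
  if (!all(selected %in% universe)) {
    validation_error("'selected' must be a subset of 'universe'")
  }
  categories <- categories[names(categories) %in% universe]
  labels <- sort(unique(categories))
  if (length(labels) == 0L) data_error("no category covers the universe")
  sel <- universe %in% selected
  rows <- lapply(labels, function(lab) {
    inc <- universe %in% names(categories)[categories == lab]
    a <- sum(sel & inc); b <- sum(sel & !inc)
    c_ <- sum(!sel & inc); d <- sum(!sel & !inc)
    or <- if (b == 0 && c_ == 0) 1 else (a * d) / (b * c_)
    if (is.nan(or)) or <- 1
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
    data.frame(category = lab, a = a, b = b, c = c_, d = d,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; used to quantify how
#' consistent DNAm age is across multiple tissues of one donor.
#'
#' @param values Numeric vector (>= 2 values, positive mean).
#' @return A non-negative ratio.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) data_error("coefficient of variation needs >= 2 values")
  m <- mean(values)
  if (m <= 0) domain_error("coefficient of variation undefined for mean <= 0")
  stats::sd(values) / m
}
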