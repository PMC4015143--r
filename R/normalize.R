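# Gold-standard construction, quantile normalization toward it, and
# missing-value imputation.  The gold standard is the training cohort's
# reference: per-probe mean betas (for imputation) and the pooled sorted
# beta distribution of the clock probes (for quantile mapping).

#' Build a gold standard from training beta values
#'
#' @param betas Probes x samples beta matrix (>= 2 samples).  Probes whose
#'   values are entirely missing are excluded from the standard with a
#'   warning.
#' @return An object of class \code{gold_standard}: list with
#'   \code{means} (named per-probe mean over non-missing entries) and
#'   \code{quantiles} (sorted vector of all pooled non-missing values).
#' @export
build_gold_standard <- function(betas) {
  if (is.null(dim(betas)) || nrow(betas) == 0L || ncol(betas) == 0L) {
    data_error("cannot build a gold standard from an empty beta matrix")
  }
  if (ncol(betas) < 2L) {
    data_error("gold standard needs >= 2 training samples")
  }
  n_obs <- rowSums(!is.na(betas))
  if (any(n_obs == 0L)) {
    warning(sprintf("%d probe(s) entirely missing; excluded from gold standard",
                    sum(n_obs == 0L)))
    betas <- betas[n_obs > 0L, , drop = FALSE]
  }
  if (nrow(betas) == 0L) data_error("no probe with any observed value")
  structure(
    list(means = rowMeans(betas, na.rm = TRUE),
         quantiles = sort(betas[!is.na(betas)])),
    class = "gold_standard")
}

#' Quantile-normalize test samples toward a gold standard
#'
#' Per sample, the non-missing beta values of probes shared with the
#' standard are mapped onto the reference distribution by empirical-CDF
#' matching with linear interpolation: value i with mid-rank r_i among the
#' sample's n observed values is replaced by the reference quantile at
#' plotting position (r_i - 0.5)/n.  Within-sample rank order is preserved
#' exactly, output stays in \[0, 1\], and a sample whose values already
#' form the reference distribution is unchanged.  The mapping is
#' idempotent.
#'
#' Samples sharing fewer than \code{min_shared} observed probes with the
#' standard are left untouched and recorded in the \code{"norm_errors"}
#' attribute of the result.
#'
#' @param betas Probes x samples beta matrix.
#' @param std A [build_gold_standard()] object.
#' @param min_shared Minimum observed shared probes per sample (default 30).
#' @return Beta matrix of the same shape; attribute \code{"norm_errors"}
#'   names samples that could not be normalized.
#' @export
normalize_to_gold_standard <- function(betas, std, min_shared = 30L) {
  stopifnot(inherits(std, "gold_standard"))
  shared <- intersect(rownames(betas), names(std$means))
  ref <- std$quantiles
  m <- length(ref)
  if (m < 2L) data_error("gold standard has too few reference values")
  ref_pos <- (seq_len(m) - 0.5) / m
  out <- betas
  failed <- character()
  for (s in colnames(betas)) {
    x <- betas[shared, s]
    obs <- which(!is.na(x))
    if (length(obs) < min_shared) {
      failed <- c(failed, s)
      next
    }
    n <- length(obs)
    p <- (rank(x[obs], ties.method = "average") - 0.5) / n
    out[shared[obs], s] <- stats::approx(ref_pos, ref, xout = p,
                                         rule = 2L)$y
  }
  attr(out, "norm_errors") <- failed
  out
}

#' Impute missing beta values from gold-standard probe means
#'
#' Missing entries of probes covered by the standard are replaced by the
#' standard's per-probe mean; observed entries are never altered.  Missing
#' entries of probes absent from the standard stay missing and are flagged.
#'
#' @param betas Probes x samples beta matrix.
#' @param std A [build_gold_standard()] object (or a clock model's
#'   \code{gold_standard} component).
#' @return Beta matrix with attributes \code{"n_imputed"} (named per-sample
#'   imputation counts) and \code{"uncovered_probes"} (probes that had
#'   missing values but no standard mean).
#' @export
impute_missing <- function(betas, std) {
  stopifnot(inherits(std, "gold_standard"))
  out <- betas
  miss <- is.na(out)
  covered <- rownames(out) %in% names(std$means)
  fill <- miss & covered
  if (any(fill)) {
    idx <- which(fill, arr.ind = TRUE)
    out[fill] <- std$means[rownames(out)[idx[, 1L]]]
  }
  uncovered <- rownames(out)[rowSums(miss & !covered) > 0L]
  structure(out,
            n_imputed = colSums(fill),
            uncovered_probes = uncovered)
}
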