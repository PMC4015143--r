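# Synthetic methylome cohorts with the statistical structure the clock
# assumes: age-dependent causal CpGs whose trajectories are linear on the
# calibrated age scale (fast change in development, constant rate in
# adulthood), additive data-set and tissue offsets, Gaussian beta noise,
# and twin cohorts with a chosen broad-sense heritability.  Every run is
# fully determined by its seed and ships its ground truth.

#' Configuration for the synthetic methylome generator
#'
#' Defaults define the package's reference scenario: 400 samples, 2,000
#' probes of which 150 are causal, ages uniform over 0-101 years, a
#' 193:160 split of hyper- vs hypomethylating causal CpGs, per-probe
#' effect sizes averaging a 0.032 absolute beta difference between young
#' (< 35 y) and old (> 55 y) subjects, beta noise SD 0.02, four data sets
#' and three tissue labels with offset SDs of 0.01.
#'
#' @param n_samples,n_probes,n_causal Cohort dimensions.
#' @param frac_positive Fraction of causal CpGs that hypermethylate with
#'   age (default 193/353).
#' @param age_range Two-element range in years; ages are sampled uniformly
#'   over it.
#' @param effect_size_mean Mean per-probe absolute beta difference between
#'   old (> 55 y) and young (< 35 y) subjects (default 0.032).  Per-probe
#'   effects are drawn uniformly within +/- 50% of this mean.
#' @param noise_sd Gaussian noise SD on the beta scale.
#' @param n_datasets Number of data-set labels.
#' @param dataset_sd SD of per-(probe, data set) additive offsets.
#' @param tissue_labels Character vector of tissue labels.
#' @param tissue_sd SD of per-(probe, tissue) additive offsets.
#' @param missing_rate Fraction of cells set missing completely at random.
#' @param adult_age Calibration knot in years.
#' @param seed Integer seed; fully determines the cohort.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_samples = 400L, n_probes = 2000L, n_causal = 150L,
                       frac_positive = 193 / 353, age_range = c(0, 101),
                       effect_size_mean = 0.032, noise_sd = 0.02,
                       n_datasets = 4L, dataset_sd = 0.01,
                       tissue_labels = c("blood", "brain", "liver"),
                       tissue_sd = 0.01, missing_rate = 0,
                       adult_age = 20, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_probes = as.integer(n_probes),
              n_causal = as.integer(n_causal),
              frac_positive = frac_positive, age_range = age_range,
              effect_size_mean = effect_size_mean, noise_sd = noise_sd,
              n_datasets = as.integer(n_datasets), dataset_sd = dataset_sd,
              tissue_labels = tissue_labels, tissue_sd = tissue_sd,
              missing_rate = missing_rate, adult_age = adult_age,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 1L || cfg$n_probes < 1L) {
    validation_error("n_samples and n_probes must be >= 1")
  }
  if (cfg$n_causal < 0L || cfg$n_causal > cfg$n_probes) {
    validation_error("n_causal must lie in [0, n_probes]")
  }
  if (cfg$frac_positive < 0 || cfg$frac_positive > 1) {
    validation_error("frac_positive must lie in [0, 1]")
  }
  if (length(cfg$age_range) != 2L || cfg$age_range[1L] < 0 ||
      diff(cfg$age_range) < 0) {
    validation_error("age_range must be an increasing pair of ages >= 0")
  }
  for (f in c("effect_size_mean", "noise_sd", "dataset_sd", "tissue_sd")) {
    if (cfg[[f]] < 0) validation_error(sprintf("%s must be >= 0", f))
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    validation_error("missing_rate must lie in [0, 1)")
  }
  if (cfg$n_datasets < 1L || length(cfg$tissue_labels) < 1L) {
    validation_error("need >= 1 data set and >= 1 tissue label")
  }
  invisible(cfg)
}

# Normalized calibrated age: F rescaled to [0, 1] over the configured range.
scaled_transform <- function(age, cfg) {
  lo <- transform_age(cfg$age_range[1L], cfg$adult_age)
  hi <- transform_age(cfg$age_range[2L], cfg$adult_age)
  if (hi == lo) return(rep(0.5, length(age)))
  (transform_age(age, cfg$adult_age) - lo) / (hi - lo)
}

# Expected old-young contrast of the scaled transform under uniform age
# sampling: E[Fn | age > 55] - E[Fn | age < 35].  The per-probe effect size
# (configured as a young/old beta gap) is divided by this factor so the
# emitted cohorts realize the configured gap.  If the configured range
# does not span both windows the full-range change (factor 1) is used.
young_old_contrast <- function(cfg, young_max = 35, old_min = 55) {
  lo <- cfg$age_range[1L]; hi <- cfg$age_range[2L]
  if (lo >= young_max || hi <= old_min) return(1)
  grid <- seq(lo, hi, length.out = 4096L)
  fn <- scaled_transform(grid, cfg)
  mean(fn[grid > old_min]) - mean(fn[grid < young_max])
}

#' Simulate a methylome cohort with ground truth
#'
#' Causal probe i of sample j follows
#' \eqn{\beta_{ij} = clamp(b_i + s_i A_i (F_n(age_j) - \bar F_n) +
#' \delta_{i,d(j)} + \tau_{i,t(j)} + \epsilon_{ij},\ 0,\ 1)} where
#' \eqn{F_n} is the calibration transform rescaled to \[0, 1\] over the age
#' range (so the true signal is linear on the transformed scale),
#' \eqn{s_i \in \{+1, -1\}}, and the amplitude \eqn{A_i} is the configured
#' young/old effect size rescaled by the expected young/old contrast of
#' \eqn{F_n}.  Non-causal probes carry baseline, offsets and noise only.
#'
#' @param config A [sim_config()] list.
#' @return List with \code{betas} (probes x samples matrix),
#'   \code{samples} (annotation data.frame) and \code{truth} (list:
#'   \code{ages}, \code{causal_probes}, \code{signs}, \code{baselines},
#'   \code{amplitudes}, \code{dataset_offsets}, \code{tissue_offsets},
#'   \code{config}).
#' @export
simulate_methylome <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  p <- cfg$n_probes
  probe_ids <- sprintf("cg%08d", seq_len(p))
  sample_ids <- sprintf("s%04d", seq_len(n))
  ages <- stats::runif(n, cfg$age_range[1L], cfg$age_range[2L])
  dataset_id <- sample(rep_len(sprintf("d%02d", seq_len(cfg$n_datasets)), n))
  tissue <- sample(rep_len(cfg$tissue_labels, n))
  sex <- sample(c("F", "M"), n, replace = TRUE)

  baselines <- stats::runif(p, 0.15, 0.85)
  causal_idx <- sort(sample.int(p, cfg$n_causal))
  n_pos <- round(cfg$frac_positive * cfg$n_causal)
  signs <- rep(-1, cfg$n_causal)
  if (n_pos > 0L) signs[sample.int(cfg$n_causal, n_pos)] <- 1
  gaps <- cfg$effect_size_mean * stats::runif(cfg$n_causal, 0.5, 1.5)
  amplitudes <- gaps / young_old_contrast(cfg)

  dataset_offsets <- matrix(stats::rnorm(p * cfg$n_datasets, 0, cfg$dataset_sd),
                            p, cfg$n_datasets,
                            dimnames = list(probe_ids,
                                            sprintf("d%02d",
                                                    seq_len(cfg$n_datasets))))
  tissue_offsets <- matrix(stats::rnorm(p * length(cfg$tissue_labels), 0,
                                        cfg$tissue_sd),
                           p, length(cfg$tissue_labels),
                           dimnames = list(probe_ids, cfg$tissue_labels))

  fn <- scaled_transform(ages, cfg)
  fn_centered <- fn - mean(scaled_transform(
    seq(cfg$age_range[1L], cfg$age_range[2L], length.out = 4096L), cfg))

  m <- matrix(baselines, p, n) +
    dataset_offsets[, dataset_id, drop = FALSE] +
    tissue_offsets[, tissue, drop = FALSE]
  if (cfg$n_causal > 0L) {
    m[causal_idx, ] <- m[causal_idx, ] +
      (signs * amplitudes) %o% fn_centered
  }
  if (cfg$noise_sd > 0) m <- m + stats::rnorm(p * n, 0, cfg$noise_sd)
  m <- clamp(m, 0, 1)
  dimnames(m) <- list(probe_ids, sample_ids)
  if (cfg$missing_rate > 0) {
    m[stats::runif(p * n) < cfg$missing_rate] <- NA_real_
  }

  samples <- data.frame(sample_id = sample_ids, age = ages, tissue = tissue,
                        dataset_id = dataset_id, sex = sex,
                        stringsAsFactors = FALSE)
  truth <- list(ages = stats::setNames(ages, sample_ids),
                causal_probes = probe_ids[causal_idx],
                signs = stats::setNames(signs, probe_ids[causal_idx]),
                baselines = stats::setNames(baselines, probe_ids),
                amplitudes = stats::setNames(gaps, probe_ids[causal_idx]),
                dataset_offsets = dataset_offsets,
                tissue_offsets = tissue_offsets,
                config = cfg)
  list(betas = m, samples = samples, truth = truth)
}

#' Simulate a twin cohort with known heritability of age acceleration
#'
#' Each twin's age acceleration is \eqn{g + e} with
#' \eqn{var(g) = h^2 \sigma^2} and \eqn{var(e) = (1 - h^2) \sigma^2};
#' monozygotic co-twins share \eqn{g} fully, dizygotic co-twins share it
#' with correlation 0.5, so Falconer's \eqn{2(r_{MZ} - r_{DZ})} has
#' expectation \eqn{h^2}.
#'
#' @param n_mz,n_dz Numbers of MZ and DZ pairs (>= 1).
#' @param h2 Target broad-sense heritability in \[0, 1\].
#' @param total_sd Total SD of age acceleration in years (default 5).
#' @param seed Integer seed.
#' @return Data.frame with \code{sample_id}, \code{pair_id},
#'   \code{zygosity}, \code{acceleration}.
#' @export
simulate_twin_cohort <- function(n_mz, n_dz, h2, total_sd = 5, seed = 1L) {
  if (!is_scalar_number(h2) || h2 < 0 || h2 > 1) {
    validation_error("h2 must lie in [0, 1]")
  }
  if (n_mz < 1L || n_dz < 1L) validation_error("need >= 1 pair per zygosity")
  if (total_sd < 0) validation_error("total_sd must be >= 0")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sd_g <- total_sd * sqrt(h2)
  sd_e <- total_sd * sqrt(1 - h2)
  mz_g <- stats::rnorm(n_mz, 0, sd_g)
  mz <- data.frame(
    pair_id = rep(sprintf("MZ%04d", seq_len(n_mz)), each = 2L),
    zygosity = "MZ",
    acceleration = rep(mz_g, each = 2L) + stats::rnorm(2L * n_mz, 0, sd_e),
    stringsAsFactors = FALSE)
  dz_shared <- stats::rnorm(n_dz, 0, sd_g * sqrt(0.5))
  dz_own <- stats::rnorm(2L * n_dz, 0, sd_g * sqrt(0.5))
  dz <- data.frame(
    pair_id = rep(sprintf("DZ%04d", seq_len(n_dz)), each = 2L),
    zygosity = "DZ",
    acceleration = rep(dz_shared, each = 2L) + dz_own +
      stats::rnorm(2L * n_dz, 0, sd_e),
    stringsAsFactors = FALSE)
  out <- rbind(mz, dz)
  out$sample_id <- paste0(out$pair_id, "_", rep(c(1L, 2L),
                                                times = n_mz + n_dz))
  out[, c("sample_id", "pair_id", "zygosity", "acceleration")]
}
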