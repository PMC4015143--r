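test_that("accuracy report computes the three measures as defined", {
  perfect <- accuracy_report(c(10, 20, 30), c(10, 20, 30))
  expect_equal(perfect$age_correlation, 1)
  expect_equal(perfect$median_error, 0)
  expect_equal(perfect$average_age_acceleration, 0)

  r <- accuracy_report(c(5, 10, 20), c(6, 12, 18))
  expect_equal(r$median_error, 2)                       # median of {1,2,2}
  expect_equal(r$average_age_acceleration, -1 / 3)
  expect_identical(r$n, 3L)

  # constant age: correlation undefined, never zero
  const <- accuracy_report(c(1, 2, 3), c(5, 5, 5))
  expect_true(is.na(const$age_correlation))
  expect_false(identical(const$age_correlation, 0))

  # even n: median error is the mean of the middle two
  even <- accuracy_report(c(1, 2, 3, 10), c(0, 0, 0, 0))
  expect_equal(even$median_error, 2.5)
})

test_that("a median error of E means half the subjects are within E years", {
  set.seed(4)
  for (i in 1:5) {
    age <- runif(60, 0, 90)
    dnam <- age + rnorm(60, 0, 6)
    rep <- accuracy_report(dnam, age)
    expect_gte(mean(abs(dnam - age) <= rep$median_error), 0.5)
    # median error invariant under a shared constant shift
    shifted <- accuracy_report(dnam + 7, age + 7)
    expect_equal(shifted$median_error, rep$median_error)
  }
})

test_that("Falconer heritability reproduces constructed twin correlations", {
  tw <- make_twin_table(r_mz = 0.6, r_dz = 0.25, n_pairs = 40)
  est <- falconer_heritability(tw)
  expect_equal(est$cor_mz, 0.6, tolerance = 1e-12)
  expect_equal(est$cor_dz, 0.25, tolerance = 1e-12)
  expect_equal(est$h2, 0.7, tolerance = 1e-12)

  # equal correlations give zero heritability
  same <- make_twin_table(0.5, 0.5, 30)
  expect_equal(falconer_heritability(same)$h2, 0)

  # clamping keeps the estimate in [0,1] for any correlations
  for (rs in list(c(0.9, -0.9), c(-0.5, 0.8), c(0.1, 0.05))) {
    est_i <- falconer_heritability(make_twin_table(rs[1], rs[2], 25))
    expect_gte(est_i$h2, 0)
    expect_lte(est_i$h2, 1)
  }

  # rows with missing zygosity are excluded and counted
  tw$zygosity[1:2] <- NA
  est2 <- falconer_heritability(tw)
  expect_identical(est2$n_excluded, 2L)
  expect_identical(est2$n_mz, 39L)

  few <- make_twin_table(0.5, 0.2, 2)
  expect_error(falconer_heritability(few), class = "dnamclock_data_error")
})

test_that("biweight midcorrelation is robust and falls back to Pearson on zero MAD", {
  x <- c(1, 3, 2, 5, 4, 7, 6)
  expect_equal(biweight_midcorrelation(x, x), 1)
  expect_equal(biweight_midcorrelation(x, -x), -1)

  set.seed(8)
  n <- 1000
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  expect_lt(abs(biweight_midcorrelation(a, b) - cor(a, b)), 0.05)

  # gross outliers wreck Pearson but barely move bicor
  a2 <- a; b2 <- b
  idx <- sample(n, 20)
  a2[idx] <- a2[idx] + 50
  b2[idx] <- b2[idx] - 50
  expect_lt(abs(biweight_midcorrelation(a2, b2) - 0.5),
            abs(cor(a2, b2) - 0.5))

  # when both vectors hit the zero-MAD fallback the statistic is exactly
  # Pearson; with one degenerate vector it is still finite and in range
  spike_x <- c(rep(0.3, 15), 0.9)
  spike_y <- c(0.8, rep(0.1, 15))
  expect_equal(biweight_midcorrelation(spike_x, spike_y),
               cor(spike_x, spike_y), tolerance = 1e-12)
  mixed <- biweight_midcorrelation(spike_x, rnorm(16))
  expect_true(is.finite(mixed) && abs(mixed) <= 1)

  expect_error(biweight_midcorrelation(1:2, 1:2),
               class = "dnamclock_data_error")
})

test_that("meta-analysis combines within-data-set correlations by weighted Z", {
  set.seed(31)
  n <- 40
  age <- runif(n, 0, 80)
  betas <- rbind(cg01 = clampv <- pmin(pmax(0.3 + 0.004 * age + rnorm(n, 0, 0.02), 0), 1),
                 cg02 = runif(n, 0.2, 0.8))
  colnames(betas) <- sprintf("s%02d", 1:n)
  samples <- data.frame(sample_id = colnames(betas), age = age,
                        dataset_id = "d1")
  res <- meta_analysis_age_correlation(betas, samples)
  # single data set: combined Z is that data set's Fisher-z statistic
  r1 <- cor(betas["cg01", ], age)
  expect_equal(res$combined_z[res$probe_id == "cg01"],
               sqrt(n - 3) * atanh(r1), tolerance = 1e-9)
  # positive age slope gives a positive signed log10 p
  expect_gt(res$signed_log10_p[res$probe_id == "cg01"], 0)
  expect_equal(sign(res$signed_log10_p), sign(res$combined_z))

  # conditioning on data set: a probe tracking only the data-set mean ages
  # (constant within each data set) contributes no within-set correlation
  s2 <- data.frame(sample_id = colnames(betas), age = age,
                   dataset_id = rep(c("d1", "d2"), each = n / 2))
  confounded <- rbind(cgC = rep(c(0.3, 0.7), each = n / 2))
  colnames(confounded) <- colnames(betas)
  res2 <- meta_analysis_age_correlation(confounded, s2)
  expect_true(is.na(res2$combined_z[1]))
})

test_that("meta-analysis p-values are calibrated under the null", {
  hits <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    n_probes <- 200
    n <- 90
    betas <- matrix(runif(n_probes * n, 0.2, 0.8), n_probes, n,
                    dimnames = list(sprintf("cg%04d", 1:n_probes),
                                    sprintf("s%03d", 1:n)))
    samples <- data.frame(sample_id = colnames(betas),
                          age = runif(n, 0, 90),
                          dataset_id = rep(c("d1", "d2", "d3"), each = n / 3))
    res <- meta_analysis_age_correlation(betas, samples)
    hits[s] <- mean(res$p_value < 0.05)
  }
  expect_lt(abs(mean(hits) - 0.05), 0.01)
})

test_that("tissue F statistics separate true tissue effects from age confounding", {
  set.seed(41)
  n <- 90
  tissue <- rep(c("blood", "brain", "liver"), each = n / 3)
  # tissues with different age distributions but no direct tissue effect
  age <- c(runif(n / 3, 0, 30), runif(n / 3, 20, 60), runif(n / 3, 50, 90))
  n_probes <- 150
  null_betas <- matrix(0.4 + 0.003 * rep(age, each = n_probes) +
                         rnorm(n_probes * n, 0, 0.03),
                       n_probes, n,
                       dimnames = list(sprintf("cg%04d", 1:n_probes),
                                       sprintf("s%03d", 1:n)))
  null_betas <- pmin(pmax(null_betas, 0), 1)
  samples <- data.frame(sample_id = colnames(null_betas), age = age,
                        tissue = tissue)
  res_null <- tissue_f_statistics(null_betas, samples)
  expect_lte(median(res_null$f_tissue, na.rm = TRUE),
             qf(0.95, res_null$df1[1], res_null$df2[1]))

  # a probe with +/-0.2 tissue offsets lands in the extreme upper tail
  shifted <- null_betas
  shifted[1, tissue == "blood"] <- shifted[1, tissue == "blood"] + 0.2
  shifted[1, tissue == "liver"] <- shifted[1, tissue == "liver"] - 0.2
  shifted <- pmin(pmax(shifted, 0), 1)
  res_shift <- tissue_f_statistics(shifted, samples)
  expect_gte(res_shift$f_tissue[1],
             quantile(res_null$f_tissue, 0.99, na.rm = TRUE))

  one_tissue <- samples
  one_tissue$tissue <- "blood"
  expect_error(tissue_f_statistics(null_betas, one_tissue),
               class = "dnamclock_config_error")
})

test_that("category enrichment matches the hypergeometric enumeration oracle", {
  # fixed worked table
  res <- category_enrichment(
    selected = sprintf("p%02d", 1:10),
    categories = setNames(rep("shore", 9), sprintf("p%02d", c(1:8, 11))),
    universe = sprintf("p%02d", 1:20))
  expect_identical(c(res$a, res$b, res$c, res$d), c(8L, 2L, 1L, 9L))
  expect_equal(res$p_value, fisher_enum_p(8, 2, 1, 9), tolerance = 1e-12)
  expect_equal(res$odds_ratio, (8 * 9) / (2 * 1))

  # random small tables against the enumeration oracle
  set.seed(12)
  for (i in 1:20) {
    counts <- as.vector(rmultinom(1, sample(10:30, 1), rep(0.25, 4)))
    a <- counts[1]; b <- counts[2]; c_ <- counts[3]; d <- counts[4]
    uni <- sprintf("q%03d", seq_len(a + b + c_ + d))
    sel <- uni[seq_len(a + b)]
    cats <- setNames(rep("k", a + c_), uni[c(seq_len(a), a + b + seq_len(c_))])
    if (length(cats) == 0) next
    res_i <- category_enrichment(sel, cats, uni)
    expect_equal(res_i$p_value, fisher_enum_p(a, b, c_, d), tolerance = 1e-9)
  }

  # degenerate conventions
  uni <- sprintf("p%02d", 1:10)
  all_sel <- category_enrichment(uni, setNames(rep("k", 4), uni[1:4]), uni)
  expect_equal(all_sel$p_value, 1)
  expect_equal(all_sel$odds_ratio, 1)
  disjoint <- category_enrichment(uni[1:3], setNames(rep("k", 3), uni[8:10]),
                                  uni)
  expect_equal(disjoint$odds_ratio, 0)
  expect_error(category_enrichment("p01", setNames("k", "p01"), character(0)),
               class = "dnamclock_data_error")
})

test_that("coefficient of variation is sd over mean and scale invariant", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(30, 40, 50)), 0.25)
  v <- c(12, 30, 44, 61)
  expect_equal(coefficient_of_variation(v * 3.7), coefficient_of_variation(v),
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-5, 1)),
               class = "dnamclock_domain_error")
  expect_error(coefficient_of_variation(3), class = "dnamclock_data_error")
})
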