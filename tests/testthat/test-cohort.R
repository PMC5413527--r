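test_that("wilcoxon p-values match exact enumeration on small groups", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  # enumeration oracle: all C(6, 3) assignments of the pooled values
  pool <- c(x, y)
  rank_sum <- sum(rank(pool)[1:3])
  combos <- combn(6, 3)
  sums <- apply(combos, 2, function(i) sum(rank(pool)[i]))
  p_oracle <- mean(sums <= rank_sum)
  expect_equal(p_oracle, 1 / 20)
  res <- wilcoxon_groups(x, y = y, alternative = "less")
  expect_equal(res$p, p_oracle, tolerance = 1e-12)

  tied <- wilcoxon_groups(rep(5, 4), y = rep(5, 4))
  expect_equal(tied$p, 1)
  expect_equal(tied$flag, "all tied")
  expect_error(wilcoxon_groups(numeric(0), y = 1:3), "empty group")
})

test_that("anova sex comparison behaves on degenerate and null data", {
  tab <- data.frame(sex = rep(c("M", "F"), each = 3),
                    v = c(1, 2, 3, 1, 2, 3))
  cs <- compare_sexes(tab, "v")
  expect_equal(cs$f, 0)
  expect_equal(cs$p, 1)
  expect_error(compare_sexes(data.frame(sex = "M", v = 1), "v"), "n >= 2")
})

test_that("correlation returns Fisher-z intervals and flags degeneracy", {
  x <- 1:20
  co <- correlate(x, 2 * x + 1)
  expect_equal(co$r, 1)
  flat <- correlate(rep(1, 10), rnorm(10))
  expect_true(is.na(flat$r))
  expect_equal(flat$flag, "undefined")

  # Fisher z against the direct formula
  ci <- spectsync:::fisher_ci(0.5, 50)
  z <- atanh(0.5); se <- 1 / sqrt(47)
  expect_equal(ci, tanh(c(z - 1.96 * se, z + 1.96 * se)), tolerance = 1e-3)

  # near-zero mean correlation under independence
  set.seed(71)
  rs <- replicate(200, correlate(rnorm(69), rnorm(69))$r)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("regression matches exact lines and a grid-search oracle", {
  x <- 1:10
  r1 <- regress(x, 3 * x - 2)
  expect_equal(r1$slope, 3, tolerance = 1e-12)
  expect_equal(r1$intercept, -2, tolerance = 1e-12)
  expect_equal(r1$r_squared, 1, tolerance = 1e-12)

  set.seed(77)
  y <- 2.5 * x + rnorm(10)
  fit <- regress(x, y)
  # brute-force grid around the closed-form optimum
  grid_s <- seq(fit$slope - 0.5, fit$slope + 0.5, length.out = 201)
  grid_i <- seq(fit$intercept - 2, fit$intercept + 2, length.out = 201)
  sse <- outer(grid_s, grid_i,
               Vectorize(function(s, i) sum((y - s * x - i)^2)))
  best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  expect_equal(grid_s[best[1]], fit$slope, tolerance = 0.01)
  expect_equal(grid_i[best[2]], fit$intercept, tolerance = 0.05)
  expect_error(regress(rep(1, 5), rnorm(5)), "zero x-variance")
})

test_that("run_cohort handles the empty cohort and is deterministic", {
  empty <- run_cohort(cohort_spec(n_male = 0, n_female = 0))
  expect_s3_class(empty, "cohort_table")
  expect_equal(nrow(empty), 0)

  co <- cohort_spec(n_male = 1, n_female = 1, seed = 12,
                    phantom = list(matrix_size = 32, n_slices = 14),
                    edv_mean_ml = c(65, 55), edv_sd_ml = c(4, 4))
  t1 <- run_cohort(co)
  t2 <- run_cohort(co)
  expect_identical(t1$psd_deg, t2$psd_deg)
  expect_identical(t1$ef_pct, t2$ef_pct)
  expect_true(all(t1$ok))
  expect_equal(t1$sex, c("M", "F"))
})

test_that("a synchronous noise-free subject shows no dyssynchrony", {
  co <- cohort_spec(n_male = 1, n_female = 0, delay_jitter_deg = 0,
                    poisson = FALSE, edv_sd_ml = c(0, 0), ef_sd = c(0, 0),
                    seed = 3)
  tab <- run_cohort(co)
  expect_lt(tab$psd_deg, 2)
  expect_lt(tab$bandwidth_deg, 5)
})

test_that("truth-mode volumes bypass the estimator", {
  co <- cohort_spec(n_male = 1, n_female = 0, seed = 8,
                    phantom = list(matrix_size = 32, n_slices = 14),
                    edv_mean_ml = c(70, 55), edv_sd_ml = c(0, 0),
                    ef_mean = c(0.6, 0.7), ef_sd = c(0, 0))
  tab <- run_cohort(co, dyssync_config(volumes = "truth"))
  expect_equal(tab$edv_ml, 70)
  expect_equal(tab$ef_pct, 60)
})

test_that("volume-matched contrast reports balance first and validates", {
  set.seed(13)
  tab <- data.frame(
    sex = rep(c("M", "F"), c(20, 20)),
    edv_ml = c(rnorm(20, 85, 10), rnorm(20, 65, 10)),
    psd_deg = rnorm(40, 8, 2), bandwidth_deg = rnorm(40, 30, 5),
    entropy_pct = rnorm(40, 40, 5))
  vm <- volume_matched_contrast(tab)
  expect_true(all(c("edv_balance", "psd_deg") %in% names(vm)))
  expect_true(vm$n["male"] > 0 && vm$n["female"] > 0)
  expect_true(vm$edv_balance$p >= 0 && vm$edv_balance$p <= 1)
  expect_error(volume_matched_contrast(tab, male_max_edv = 0),
               "empty volume-matched subgroup")
})

test_that("report renders without error and handles empty tables", {
  co <- cohort_spec(n_male = 2, n_female = 2, seed = 21,
                    phantom = list(matrix_size = 32, n_slices = 14),
                    edv_mean_ml = c(65, 55), edv_sd_ml = c(4, 4))
  tab <- run_cohort(co)
  out <- capture.output(res <- report_cohort(tab))
  expect_gt(length(out), 3)
  expect_equal(res$n, 4)
  empty <- run_cohort(cohort_spec(n_male = 0, n_female = 0))
  expect_output(report_cohort(empty), "no subjects")
})
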