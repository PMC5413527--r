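# Exhaustive shortest-arc oracle: try every sorted sample as the arc start.
bw_oracle <- function(phases, coverage = 0.95) {
  x <- sort(phases %% 360)
  n <- length(x)
  m <- ceiling(coverage * n)
  ext <- c(x, x + 360)
  min(vapply(seq_len(n), function(i) ext[i + m - 1] - ext[i], numeric(1)))
}

test_that("histogram binning follows the half-open bin convention", {
  h <- build_histogram(rep(50.2, 100), bin_deg = 1)
  expect_equal(sum(h$freq > 0), 1)
  expect_equal(max(h$freq), 1)
  expect_equal(h$n_samples, 100)

  h2 <- build_histogram(0:359, bin_deg = 1)
  expect_true(all(abs(h2$freq - 1 / 360) < 1e-12))
  expect_equal(sum(h2$freq), 1, tolerance = 1e-12)

  # a value exactly on a bin edge belongs to the bin it opens
  h3 <- build_histogram(c(10), bin_deg = 5)
  expect_equal(which(h3$freq > 0), 3)  # [10, 15)

  expect_error(build_histogram(numeric(0)), "no phase samples")
  expect_error(build_histogram(10, bin_deg = 7), "divide 360")
})

test_that("entropy spans 0 (order) to 1 (disorder) and matches closed forms", {
  expect_equal(phase_entropy(build_histogram(rep(123.4, 50))), 0)
  expect_equal(phase_entropy(build_histogram(0:359)), 1, tolerance = 1e-12)
  # half/half in two bins of a 360-bin histogram
  h <- build_histogram(c(rep(10.5, 5), rep(200.5, 5)))
  expect_equal(phase_entropy(h), log(2) / log(360), tolerance = 1e-12)
})

test_that("entropy is maximized by the uniform histogram", {
  set.seed(23)
  for (i in 1:200) {
    h <- build_histogram(runif(80, 0, 360), bin_deg = 10)
    expect_lte(phase_entropy(h), 1 + 1e-12)
    expect_gte(phase_entropy(h), 0)
  }
})

test_that("psd is wrap-safe and matches the plain SD on wrap-free data", {
  expect_equal(psd(c(100, 110, 120)), sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(psd(c(350, 10)), 10, tolerance = 1e-12)
  expect_equal(psd(rep(42, 5)), 0)
  set.seed(31)
  for (i in 1:20) {
    x <- runif(50, 100, 250)  # range < 180: no wrap involved
    plain <- sqrt(mean((x - mean(x))^2))
    expect_equal(psd(x), plain, tolerance = 1e-9)
  }
  expect_error(psd(1), ">= 2")
})

test_that("bandwidth95 equals the exhaustive shortest-arc oracle", {
  expect_equal(as.numeric(bandwidth95(rep(77, 30))), 0)
  expect_equal(as.numeric(bandwidth95(1:100)), 94)
  expect_equal(as.numeric(bandwidth95(c(rep(180, 95), rep(0, 5)))), 0)
  set.seed(41)
  for (i in 1:30) {
    x <- runif(sample(20:300, 1), 0, 360)
    expect_equal(as.numeric(bandwidth95(x)), bw_oracle(x), tolerance = 1e-9)
  }
  # under 20 samples: full circular range, flagged
  bw <- bandwidth95(c(10, 20, 350))
  expect_true(attr(bw, "insufficient"))
  expect_equal(as.numeric(bw), 30)
})

test_that("phase indices are invariant under global rotation", {
  set.seed(43)
  x <- runif(200, 120, 260)
  for (delta in c(37, 181, 300)) {
    y <- (x + delta) %% 360
    expect_equal(psd(y), psd(x), tolerance = 1e-9)
    expect_equal(as.numeric(bandwidth95(y)), as.numeric(bandwidth95(x)),
                 tolerance = 1e-9)
    # entropy: rotation by a whole number of bins
    y2 <- (x + 40) %% 360
    expect_equal(phase_entropy(build_histogram(y2)),
                 phase_entropy(build_histogram(x)), tolerance = 1e-12)
  }
})

test_that("tes metrics match hand-computed cases", {
  tes <- rep(90, 17)
  m <- tes_metrics(tes)
  expect_equal(c(m$mdtes_pct, m$sdtes_pct, m$dtes_ls_pct), c(0, 0, 0))

  tes2 <- rep(90, 17); tes2[5] <- 126
  expect_equal(tes_metrics(tes2)$mdtes_pct, 10, tolerance = 1e-9)

  tes3 <- rep(90, 17); tes3[c(5, 6, 11, 12)] <- 100.8
  expect_equal(tes_metrics(tes3)$dtes_ls_pct, 3, tolerance = 1e-9)

  # wrap pair must not read as a 358-degree spread
  tes4 <- rep(0, 17); tes4[1] <- 359; tes4[4] <- 1
  expect_lt(tes_metrics(tes4)$mdtes_pct, 1)
})

test_that("tes metrics are label-invariant and sign-flip on set swap", {
  set.seed(47)
  tes <- runif(17, 150, 210)
  m <- tes_metrics(tes)
  perm <- sample(17)
  m2 <- tes_metrics(tes[perm])
  expect_equal(m2$mdtes_pct, m$mdtes_pct, tolerance = 1e-12)
  expect_equal(m2$sdtes_pct, m$sdtes_pct, tolerance = 1e-12)
  swapped <- tes_metrics(tes, lateral = aha_septal_default(),
                         septal = aha_lateral_default())
  expect_equal(swapped$dtes_ls_pct, -m$dtes_ls_pct, tolerance = 1e-12)
  expect_error(tes_metrics(c(tes[-1], NA)), "missing segment")
})

test_that("normal limits are mean +/- 2 sample SD, unrounded", {
  # two values constructed to have mean 24.0 and sample SD 8.3
  v <- 24 + c(-1, 1) * 8.3 / sqrt(2)
  nl <- normal_limits(v)
  expect_equal(nl$mean, 24)
  expect_equal(nl$sd, 8.3, tolerance = 1e-12)
  expect_equal(round(c(nl$lower, nl$upper), 1), c(7.4, 40.6))

  nl2 <- normal_limits(c(0, 4))
  expect_equal(nl2$mean, 2)
  expect_equal(nl2$sd, sqrt(8), tolerance = 1e-12)
  expect_equal(nl2$lower, 2 - 2 * sqrt(8), tolerance = 1e-12)

  nl3 <- normal_limits(rep(3, 5))
  expect_equal(c(nl3$lower, nl3$upper), c(3, 3))
  expect_error(normal_limits(1), ">= 2")
})
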