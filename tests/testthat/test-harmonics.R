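# DFT-based oracle for harmonic fits on uniformly sampled cycles: the
# h-th Fourier coefficient of v gives amplitude 2|X_h|/N and phase
# -Arg(X_h). Kept independent of the least-squares implementation.
dft_oracle <- function(v, h) {
  n <- length(v)
  X <- sum(v * exp(-2i * pi * h * (seq_len(n) - 1) / n))
  list(amp = 2 * Mod(X) / n, phase = (-Arg(X) * 180 / pi) %% 360)
}

test_that("known cosine curves are recovered exactly", {
  k <- 0:15
  v <- 100 + 50 * cos(2 * pi * k / 16 - 60 * pi / 180)
  fit <- fit_harmonics(v)
  expect_equal(fit$a0, 100, tolerance = 1e-12)
  expect_equal(fit$a1, 50, tolerance = 1e-12)
  expect_equal(fit$phi1_deg, 60, tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
  expect_equal(phase_deg(fit), 60, tolerance = 1e-9)

  v2 <- 100 + 30 * cos(2 * pi * k / 16 - 45 * pi / 180) +
    10 * cos(4 * pi * k / 16 - 200 * pi / 180)
  fit2 <- fit_harmonics(v2, order = 2)
  expect_equal(c(fit2$a1, fit2$phi1_deg, fit2$a2, fit2$phi2_deg),
               c(30, 45, 10, 200), tolerance = 1e-9)
})

test_that("constant curves yield zero amplitude and an undefined phase", {
  fit <- fit_harmonics(rep(7, 16))
  expect_equal(fit$a0, 7)
  expect_equal(fit$a1, 0, tolerance = 1e-12)
  expect_false(fit$phase_defined)
  expect_true(is.na(phase_deg(fit)))
  expect_true(is.na(tes_deg(fit_harmonics(rep(7, 16), order = 2))))
})

test_that("fits match the DFT oracle on random curves", {
  set.seed(11)
  for (i in 1:50) {
    v <- rnorm(16, 100, 20)
    fit <- fit_harmonics(v, order = 2)
    for (h in 1:2) {
      o <- dft_oracle(v, h)
      amp <- if (h == 1) fit$a1 else fit$a2
      ph <- if (h == 1) fit$phi1_deg else fit$phi2_deg
      expect_equal(amp, o$amp, tolerance = 1e-9)
      expect_equal(ph, o$phase, tolerance = 1e-9)
    }
  }
})

test_that("vectorized fitting agrees with the scalar path", {
  set.seed(3)
  V <- matrix(rnorm(20 * 16, 50, 10), 20, 16)
  mf <- spectsync:::fit_harmonics_mat(V, order = 2)
  for (i in c(1, 7, 20)) {
    f <- fit_harmonics(V[i, ], order = 2)
    expect_equal(mf$a1[i], f$a1, tolerance = 1e-12)
    expect_equal(mf$phi1_deg[i], f$phi1_deg, tolerance = 1e-12)
    expect_equal(mf$a2[i], f$a2, tolerance = 1e-12)
  }
})

test_that("phases near the wrap point stay in [0, 360)", {
  k <- 0:15
  v <- 10 + 5 * cos(2 * pi * k / 16 - 359.5 * pi / 180)
  fit <- fit_harmonics(v)
  expect_equal(fit$phi1_deg, 359.5, tolerance = 1e-9)
})

test_that("circularly shifting a TAC shifts phase and TES by one frame", {
  set.seed(5)
  v <- as.vector(50 + 20 * cos(2 * pi * (0:15) / 16 - 1) +
                 5 * cos(4 * pi * (0:15) / 16 - 2))
  shifted <- v[c(16, 1:15)]  # v(k) -> v(k - 1)
  f1 <- fit_harmonics(v, order = 2)
  f2 <- fit_harmonics(shifted, order = 2)
  step <- 360 / 16
  expect_equal((f2$phi1_deg - f1$phi1_deg) %% 360, step, tolerance = 1e-9)
  expect_equal((as.numeric(tes_deg(f2)) - as.numeric(tes_deg(f1))) %% 360,
               step, tolerance = 0.05)
})

test_that("TES equals the dense-grid argmax of the fitted curve", {
  fit <- fit_harmonics(rep(1, 16), order = 2)
  fit$a0 <- 100; fit$a1 <- 30; fit$phi1_deg <- 45
  fit$a2 <- 10; fit$phi2_deg <- 200; fit$phase_defined <- TRUE
  th <- seq(0, 360, by = 0.001)
  oracle <- th[which.max(predict(fit, th))]
  expect_equal(as.numeric(tes_deg(fit)), oracle %% 360, tolerance = 0.05)

  # pure first harmonic peaks at its phase
  f1 <- fit_harmonics(100 + 20 * cos(2 * pi * (0:15) / 16 - pi / 2),
                      order = 2)
  expect_equal(as.numeric(tes_deg(f1)), 90, tolerance = 0.05)
})

test_that("the amplitude floor suppresses near-flat samples", {
  k <- 0:15
  v <- 100 + 1 * cos(2 * pi * k / 16)  # 1% of a0, below the 2% floor
  expect_true(is.na(phase_deg(fit_harmonics(v))))
  expect_false(is.na(phase_deg(fit_harmonics(v, amplitude_floor = 0.005))))
})

test_that("white noise leaves the mean phase unbiased at high SNR", {
  set.seed(17)
  k <- 0:15
  clean <- 100 + 50 * cos(2 * pi * k / 16 - 120 * pi / 180)
  errs <- replicate(2000, {
    fit <- fit_harmonics(clean + rnorm(16, 0, 5))  # a1 / sigma = 10
    ((fit$phi1_deg - 120 + 180) %% 360) - 180
  })
  expect_lt(abs(mean(errs)), 1)
})
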