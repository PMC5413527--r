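test_that("centers sit on the geometric axis of a symmetric phantom", {
  st <- small_study()
  ctr <- find_center(st)
  axis <- (st$counts |> dim())[3] / 2 + 0.5
  ok <- ctr$valid
  expect_true(all(abs(ctr$row[ok] - axis) <= 0.5))
  expect_true(all(abs(ctr$col[ok] - axis) <= 0.5))
})

test_that("all-zero slices are excluded from centers and sampling", {
  s <- random_study(n_slices = 4)
  s$counts[, 2, , ] <- 0
  ctr <- find_center(s)
  expect_false(ctr$valid[2])
  rays <- spectsync:::ray_profiles(s, sampling_grid(n_angles = 8))
  expect_false(2 %in% rays$slices)
})

test_that("sampling is equivariant under in-plane integer translation", {
  st <- small_study()
  sh <- st
  M <- dim(st$counts)[3]
  shifted <- array(0, dim(st$counts))
  shifted[, , 4:M, ] <- st$counts[, , 1:(M - 3), ]  # +3 rows
  sh$counts <- shifted
  s1 <- sample_profiles(st)
  s2 <- sample_profiles(sh)
  expect_equal(s2$tac, s1$tac, tolerance = 1e-8)
  c1 <- find_center(st); c2 <- find_center(sh)
  ok <- c1$valid
  expect_equal(c2$row[ok], c1$row[ok] + 3, tolerance = 1e-6)
})

test_that("sample counts follow the grid arithmetic", {
  st <- small_study()
  grid <- sampling_grid(n_angles = 36)
  s <- sample_profiles(st, grid)
  expect_equal(nrow(s$tac), length(s$slices) * 36)
  expect_equal(s$n_frames, 16)
  expect_true(all(s$tac >= 0))
})

test_that("reduced uptake in one sector halves its sampled counts", {
  u <- rep(1, 17); u[c(4, 10)] <- 0.5  # inferior wall, basal + mid
  st <- small_study(uptake = u)
  s <- sample_profiles(st)
  mid_slices <- s$slices[6:8]  # mid band for 12 used slices
  sel <- s$slice %in% mid_slices
  inf <- sel & abs(s$angle_deg - 180) < 20   # inferior sector interior
  ant <- sel & (s$angle_deg < 20 | s$angle_deg > 340)  # anterior
  ratio <- mean(s$tac[inf, ]) / mean(s$tac[ant, ])
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
})

test_that("base cut removes only what it should", {
  st <- small_study()
  # clean base: restrict to fully myocardial slices -> nothing removed
  s_clean <- sample_profiles(st, sampling_grid(slice_range = c(2, 11)))
  expect_identical(base_cut(s_clean, "auto")$slices, s_clean$slices)
  # with the automatic range, at most the supra-basal tail slice goes
  s <- sample_profiles(st)
  auto <- base_cut(s, "auto")
  expect_true(all(setdiff(s$slices, auto$slices) >= max(s$slices) - 1))

  rm2 <- s$slices[(length(s$slices) - 1):length(s$slices)]
  cut <- base_cut(s, "manual", manual_slices = rm2)
  expect_equal(nrow(cut$tac), nrow(s$tac) - 2 * s$n_angles)
  expect_error(base_cut(s, "manual", manual_slices = c(999)),
               "manual slices")

  # weak membranous base: basal segments at low uptake
  u <- rep(1, 17); u[1:6] <- 0.2
  st2 <- small_study(uptake = u)
  s2 <- sample_profiles(st2)
  cut2 <- base_cut(s2, "auto")
  removed <- setdiff(s2$slices, cut2$slices)
  expect_gt(length(removed), 0)
  basal_flagged <- unique(s2$slice[s2$basal])
  expect_true(all(removed %in% basal_flagged))
  # never removes more than 40% of slices
  expect_lte(length(removed), floor(0.4 * length(s2$slices)))
})

test_that("phase-map smoothing is circular-aware and contractive", {
  ph <- matrix(200, 5, 12)
  expect_identical(smooth_phases(ph, 0, 0), ph)
  expect_equal(smooth_phases(ph, 40, 1), ph, tolerance = 1e-9)
  expect_error(smooth_phases(ph, -1), "negative kernel")

  set.seed(9)
  base <- matrix(180 + rnorm(60, 0, 3), 5, 12)
  out <- base
  out[3, 6] <- out[3, 6] + 90
  sm <- smooth_phases(out, 60, 1)
  expect_lt(abs(sm[3, 6] - 180), abs(out[3, 6] - 180))  # outlier pulled in
  expect_lt(psd(as.vector(sm)), psd(as.vector(out)))    # dispersion shrinks
  # range never widens on wrap-free fields
  expect_gte(min(sm), min(out) - 1e-9)
  expect_lte(max(sm), max(out) + 1e-9)

  # wrap pair: smoothing values around 0/360 must not tear to 180
  wr <- matrix(c(rep(350, 30), rep(10, 30)), 5, 12)
  smw <- smooth_phases(wr, 80, 2)
  d <- pmin(smw %% 360, 360 - smw %% 360)  # distance to 0
  expect_true(all(d < 30))
})

test_that("17-segment aggregation is complete, symmetric and conservative", {
  st <- small_study()
  s <- sample_profiles(st)
  segs <- aggregate_17seg(s)
  expect_true(all(segs$present))
  expect_equal(sum(segs$n_members), nrow(s$tac))

  # count-weighted segment mean equals the overall sample mean
  w_mean <- sum(segs$n_members * rowMeans(segs$tac)) / sum(segs$n_members)
  expect_equal(w_mean, mean(s$tac), tolerance = 1e-9)

  # rotational symmetry: within one ring, all sectors carry the same curve
  for (ring in list(1:6, 7:12, 13:16)) {
    ref <- segs$tac[ring[1], ]
    for (g in ring[-1])
      expect_equal(segs$tac[g, ], ref, tolerance = 0.02 * mean(ref))
  }
})

test_that("a painted lateral delay appears only in lateral segments", {
  d <- rep(0, 17); d[c(5, 6, 11, 12)] <- 36
  st <- small_study(delay_deg = d)
  segs <- aggregate_17seg(sample_profiles(st))
  tes <- vapply(1:17, function(g)
    as.numeric(tes_deg(fit_harmonics(segs$tac[g, ], order = 2))),
    numeric(1))
  baseline <- median(tes[-c(5, 6, 11, 12)])
  expect_true(all(tes[c(5, 6, 11, 12)] > baseline + 20))
  expect_true(all(abs(tes[-c(5, 6, 11, 12)] - baseline) < 15))
})
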