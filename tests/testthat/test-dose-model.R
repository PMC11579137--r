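test_that("PDD reconstruction is the normalized fluence-weighted superposition", {
  fl <- toy_fanline()
  b <- toy_binning()
  # delta spectrum reproduces the normalized mono-energy curve exactly
  for (k in 1:3) {
    p <- numeric(3); p[k] <- 1
    recon <- reconstruct_pdd(spectrum(p, b), fl, norm_depth = 10)
    ref <- 100 * fl$dose[, k] / fl$dose[fl$depths == 10, k]
    expect_equal(recon$values, ref, tolerance = 1e-12)
  }
  # value at the normalization depth is 100 for any spectrum
  set.seed(5)
  for (i in 1:10) {
    recon <- reconstruct_pdd(spectrum(rexp(3), b), fl, norm_depth = 10)
    expect_equal(recon$values[recon$depths == 10], 100)
  }
})

test_that("two-bin hand oracle: equal fluences mix the curves before normalizing", {
  # D1 = (2, 1), D2 = (4, 1) at depths (norm, d2):
  # value(d2) = 100 * (0.5*1 + 0.5*1) / (0.5*2 + 0.5*4) = 100/3
  b2 <- energy_binning(c(0.5, 1.5, 2.5))
  g <- beam_geometry(depth_grid = c(5, 10))
  dose <- array(0, c(2, length(g$radial_grid), 2))
  dose[1, , ] <- matrix(rep(c(2, 1), each = length(g$radial_grid)), ncol = 2)
  dose[2, , ] <- matrix(rep(c(4, 1), each = length(g$radial_grid)), ncol = 2)
  basis <- mdd_basis(c(1, 2), g, dose, binning = NULL)
  fl <- resample_to_fanline(basis, 0, g)
  recon <- reconstruct_pdd(spectrum(c(0.5, 0.5), basis$binning), fl,
                           norm_depth = 5)
  expect_equal(recon$values, c(100, 100 / 3), tolerance = 1e-12)
})

test_that("reconstruction is linear in the unnormalized superposition and scale-free in p", {
  fl <- toy_fanline()
  b <- toy_binning()
  p <- c(0.2, 0.5, 0.3); q <- c(0.6, 0.3, 0.1); a <- 0.35
  num <- function(w) as.numeric(fl$dose %*% w)
  expect_equal(num(a * p + (1 - a) * q), a * num(p) + (1 - a) * num(q),
               tolerance = 1e-12)
  # rescaling all p by a constant leaves the PDD unchanged
  r1 <- reconstruct_pdd(spectrum(p, b), fl, 10)
  r2 <- reconstruct_pdd(spectrum(5 * p, b), fl, 10)
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("hardening a spectrum never lowers the PDD beyond the normalization depth", {
  fl <- toy_fanline(depths = seq(1, 25, 1))
  b <- toy_binning()
  soft <- c(0.5, 0.3, 0.2)
  hard <- c(0.2, 0.3, 0.5)  # mass moved to higher bins
  rs <- reconstruct_pdd(spectrum(soft, b), fl, 10)
  rh <- reconstruct_pdd(spectrum(hard, b), fl, 10)
  deep <- rs$depths > 10
  expect_true(all(rh$values[deep] >= rs$values[deep] - 1e-12))
})

test_that("relative difference and sigma^2 follow their definitions", {
  d <- seq(2, 25, 0.5)
  mk <- function(v) depth_dose_curve(d, v, norm_depth = 10,
                                     renormalize = TRUE)
  base <- 100 * exp(-0.05 * (d - 10))
  m <- mk(base)
  expect_equal(unname(relative_difference(m, m)), rep(0, length(d)))
  expect_equal(objective_sigma2(m, m), 0)
  # a uniform +0.5% offset away from the normalization pivot
  r <- mk(base * 1.005)
  expect_equal(unname(relative_difference(r, m)), rep(0, length(d)),
               tolerance = 1e-12)  # renormalization cancels a pure scale
  # explicit deltas: mean of squares, reorder invariance, quadratic scaling
  delta <- c(1, -1, 0, 0)
  meas <- depth_dose_curve(c(4, 8, 10, 12), c(90, 95, 100, 90),
                           norm_depth = 10)
  recon <- depth_dose_curve(c(4, 8, 10, 12),
                            c(90, 95, 100, 90) * (1 + delta / 100),
                            norm_depth = 10, renormalize = TRUE)
  expect_equal(unname(relative_difference(recon, meas, c(2, 25))), delta,
               tolerance = 1e-9)
  expect_equal(objective_sigma2(recon, meas, c(2, 25)), 0.5)
  # sigma^2 scales quadratically when deltas are scaled
  recon3 <- depth_dose_curve(c(4, 8, 10, 12),
                             c(90, 95, 100, 90) * (1 + 3 * delta / 100),
                             norm_depth = 10, renormalize = TRUE)
  expect_equal(objective_sigma2(recon3, meas, c(2, 25)), 4.5,
               tolerance = 1e-9)
  expect_error(relative_difference(m, meas), "share depth nodes")
})

test_that("depth-dose and lateral-profile containers enforce their normalizations", {
  d <- seq(1, 25, 1)
  v <- 100 * exp(-0.05 * (d - 10))
  expect_error(depth_dose_curve(d, v * 1.02, norm_depth = 10), "not 100")
  ok <- depth_dose_curve(d, v * 1.02, norm_depth = 10, renormalize = TRUE)
  expect_equal(ok$values[d == 10], 100)
  expect_error(depth_dose_curve(rev(d), v, norm_depth = 10),
               "strictly increasing")
  expect_error(lateral_profile(c(0, 5, 10), c(101, 99, 98), 10), "not 100")
  prof <- lateral_profile(c(0, 5, 10), c(101, 99, 98), 10,
                          renormalize = TRUE)
  expect_equal(prof$values[1], 100)
})

test_that("OAR computation self-normalizes and is linear in the fluence ratios", {
  g <- small_geometry()
  b <- default_binning()
  basis <- generate_basis(g, b, radial_tilt = 0)  # radially uniform
  s <- spectrum(rep(1, 13) / 13, b)
  fam <- spectrum_family(lapply(c(0, 4, 8), function(r)
    spectrum(s$p, b, r0 = r)))
  flat <- compute_oar(fam, c(1, 1, 1), basis, depth = 10, g)
  expect_equal(flat$values, c(100, 100, 100), tolerance = 1e-9)
  horned <- compute_oar(fam, c(1, 2, 1.5), basis, depth = 10, g)
  expect_equal(horned$values, c(100, 200, 150), tolerance = 1e-9)
  expect_equal(compute_oar(fam, c(1, 0.9, 1.1), basis, 5, g)$values[1], 100)
  expect_error(compute_oar(fam, c(1, 1), basis, 10, g), "one fluence ratio")
  expect_error(compute_oar(fam, c(1, 1, 1), basis, 40, g), "depth outside")
})

test_that("fluence-ratio fitting recovers known ratios and has the closed form", {
  g <- small_geometry()
  b <- default_binning()
  basis <- generate_basis(g, b, radial_tilt = 0.02)
  fam <- spectrum_family(lapply(c(0, 6, 12), function(r)
    spectrum(dlnorm(b$mid, log(1.8), 0.6) * b$width, b, r0 = r)))
  w_true <- c(1, 1.04, 0.97)
  # zero-noise consistency at several depths
  meas <- lapply(c(5, 10, 20), function(dep)
    compute_oar(fam, w_true, basis, dep, g))
  w_fit <- fit_fluence_ratios(fam, basis, meas, g)
  expect_equal(w_fit, w_true, tolerance = 1e-10)
  # single depth, single ratio: w = meas/calc at that radius
  one <- compute_oar(fam, c(1, 1, 1), basis, 10, g)
  meas1 <- lateral_profile(one$radii, c(100, one$values[2] * 100 / 95,
                                        one$values[3]), 10)
  w1 <- fit_fluence_ratios(fam, basis, list(meas1), g)
  expect_equal(w1[2], (one$values[2] * 100 / 95) / one$values[2],
               tolerance = 1e-10)
  # per-depth variant returns a matrix matching each depth exactly
  wpd <- fit_fluence_ratios(fam, basis, meas, g, per_depth = TRUE)
  expect_equal(dim(wpd), c(3L, 3L))
  expect_equal(unname(wpd[, 1]), w_true, tolerance = 1e-10)
})
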