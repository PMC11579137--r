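test_that("constraint builder transcribes simplex, unimodality and ordering", {
  # n = 3, peak at bin 2: p1 <= p2 and p2 >= p3
  cons <- build_constraints(3, 2)
  expect_equal(nrow(cons$A), 2L)
  expect_equal(unname(cons$A %*% c(0.2, 0.5, 0.3)), cbind(c(-0.3, -0.2)))
  expect_true(constraints_satisfied(cons, c(0.2, 0.5, 0.3)))
  expect_false(constraints_satisfied(cons, c(0.5, 0.2, 0.3)))
  expect_false(constraints_satisfied(cons, c(0.2, 0.6, 0.3)))  # sum != 1

  # with an inner spectrum the feasible set always contains the inner
  # spectrum itself (at its own peak)
  inner <- c(0.1, 0.3, 0.4, 0.2)
  cons4 <- build_constraints(4, 3, inner_spectrum = inner)
  expect_true(constraints_satisfied(cons4, inner))
  # ordering binds: below-peak bins must dominate the inner values
  expect_false(constraints_satisfied(cons4, c(0.05, 0.35, 0.4, 0.2)))
  expect_true(constraints_satisfied(cons4, c(0.15, 0.32, 0.38, 0.15)))
  expect_error(build_constraints(3, 5), "out of range")
})

test_that("single-fan-line unfolding reproduces a constraint-satisfying truth", {
  fl <- toy_fanline(depths = seq(1, 25, 2))
  b <- toy_binning()
  truth <- spectrum(c(0.2, 0.5, 0.3), b)
  meas <- reconstruct_pdd(truth, fl, 10)
  cfg <- unfold_config(peak_scan = 1:3)
  fit <- unfold_single(meas, fl, cfg)
  # objective at the fit cannot exceed the objective at the truth (zero)
  expect_lt(fit$sigma2, 1e-10)
  recon <- reconstruct_pdd(fit$spectrum, fl, 10)
  expect_equal(recon$values, meas$values, tolerance = 1e-5)
  expect_true(check_unimodal(fit$spectrum$p, fit$peak_index))
})

test_that("degenerate single-energy basis returns the trivial spectrum", {
  b1 <- energy_binning(c(1, 2))
  g <- beam_geometry(depth_grid = seq(1, 25, 1))
  basis <- generate_basis(g, b1, radial_tilt = 0)
  fl <- resample_to_fanline(basis, 0, g)
  meas <- reconstruct_pdd(spectrum(1, b1), fl, 10)
  fit <- unfold_single(meas, fl, unfold_config(peak_scan = 1))
  expect_equal(fit$spectrum$p, 1)
  expect_equal(fit$sigma2, 0, tolerance = 1e-18)
})

test_that("QP solution matches the brute-force simplex grid oracle", {
  # >= 20 random 3-bin toys, <= 6 depths; the oracle enumerates the 0.01
  # simplex grid restricted to unimodal vectors. The pinned mode minimizes
  # exactly the oracle's objective; the profiled default is checked on
  # model-consistent curves where both coincide at sigma^2 ~ 0.
  fl <- toy_fanline(depths = seq(5, 25, by = 4))
  b <- toy_binning()
  set.seed(101)
  for (rep in 1:22) {
    truth <- spectrum(rexp(3) + 0.05, b)
    base <- reconstruct_pdd(truth, fl, 10)
    noisy <- base$values * (1 + rnorm(6, sd = 0.004))
    meas <- depth_dose_curve(base$depths, noisy, norm_depth = 10,
                             renormalize = TRUE)
    fit <- unfold_single(meas, fl, unfold_config(peak_scan = 1:3,
                                                 scale = "pinned"))
    oracle <- grid_search_sigma2(fl, meas$values, h = 0.01, norm_depth = 10)
    expect_lte(fit$sigma2, oracle + 1e-6)
  }
  # zero-noise: solution within one grid step of the enumerated optimum
  truth <- spectrum(c(0.25, 0.45, 0.3), b)
  meas <- reconstruct_pdd(truth, fl, 10)
  fit <- unfold_single(meas, fl, unfold_config(peak_scan = 1:3))
  expect_lt(max(abs(fit$spectrum$p - truth$p)), 0.02)
})

test_that("family unfolding enforces the softening chain sequentially and jointly", {
  spec <- synthetic_beam_spec(radii = seq(0, 18, 6), noise_sd = 0, seed = 2)
  g <- beam_geometry()
  basis <- generate_basis(g, spec$binning, radial_tilt = spec$radial_tilt)
  truth <- generate_true_family(spec)
  scans <- suppressWarnings(synth_measured(spec, truth$family, basis, g))
  for (mode in c("sequential", "joint")) {
    cfg <- unfold_config(mode = mode)
    res <- suppressWarnings(
      unfold_family(scans$pdd_measured, basis, g, cfg))
    expect_s3_class(res$family, "spectrum_family")
    expect_true(all(res$per_radius$converged))
    # feasibility of every returned member
    P <- sapply(res$family$members, function(s) s$p)
    expect_true(all(abs(colSums(P) - 1) <= 1e-9))
    for (k in seq_along(res$family$members)) {
      expect_true(check_unimodal(P[, k], res$per_radius$peak_index[k],
                                 tol = 1e-8))
    }
    expect_true(check_softening(res$family, res$per_radius$peak_index,
                                tol = 1e-8))
    # noise-free closed loop: reconstruction matches the targets on the
    # fit window for both modes (solutions need not coincide in p)
    for (k in seq_along(scans$pdd_true)) {
      fl <- suppressWarnings(resample_to_fanline(basis, res$family$r0[k], g))
      recon <- reconstruct_pdd(res$family$members[[k]], fl, cfg$norm_depth)
      expect_lt(max(abs(relative_difference(recon, scans$pdd_true[[k]],
                                            cfg$fit_window))), 0.5)
    }
  }
})

test_that("single-radius family unfolding equals unfold_single", {
  spec <- synthetic_beam_spec(radii = 0, noise_sd = 0.2, seed = 9)
  g <- beam_geometry()
  basis <- generate_basis(g, spec$binning, radial_tilt = spec$radial_tilt)
  truth <- generate_true_family(spec)
  scans <- synth_measured(spec, truth$family, basis, g)
  res <- unfold_family(scans$pdd_measured, basis, g, unfold_config())
  fl <- resample_to_fanline(basis, 0, g)
  fit <- unfold_single(scans$pdd_measured[[1]], fl, unfold_config())
  expect_equal(res$family$members[[1]]$p, fit$spectrum$p, tolerance = 1e-12)
  expect_equal(res$per_radius$sigma2[1], fit$sigma2, tolerance = 1e-12)
})

test_that("unfolding is deterministic: identical inputs give identical results", {
  spec <- synthetic_beam_spec(radii = c(0, 6, 12), noise_sd = 0.2, seed = 4)
  g <- beam_geometry()
  basis <- generate_basis(g, spec$binning, radial_tilt = spec$radial_tilt)
  truth <- generate_true_family(spec)
  scans <- synth_measured(spec, truth$family, basis, g)
  r1 <- unfold_family(scans$pdd_measured, basis, g, unfold_config())
  r2 <- unfold_family(scans$pdd_measured, basis, g, unfold_config())
  for (k in 1:3) {
    expect_identical(r1$family$members[[k]]$p, r2$family$members[[k]]$p)
  }
  expect_identical(r1$per_radius$sigma2, r2$per_radius$sigma2)
})

test_that("contradictory inner spectrum raises an infeasibility error", {
  fl <- toy_fanline(depths = seq(1, 25, 2))
  b <- toy_binning()
  meas <- reconstruct_pdd(spectrum(c(0.1, 0.3, 0.6), b), fl, 10)
  # inner already saturates the simplex below the peak: forcing the outer
  # fit to dominate (1, 0, 0) below any scanned peak > 1 while staying
  # unimodal and summing to 1 clashes with the measured curve's hardness
  inner <- spectrum(c(1, 0, 0), b)
  cfg <- unfold_config(peak_scan = 3, tol_feasibility = 1e-10)
  fit <- tryCatch(unfold_single(meas, fl, cfg, inner_spectrum = inner),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    expect_match(conditionMessage(fit), "infeasible")
  } else {
    # if a solution exists it must genuinely satisfy the constraints
    cons <- build_constraints(3, fit$peak_index, inner)
    expect_true(constraints_satisfied(cons, fit$spectrum$p, 1e-8))
  }
})
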