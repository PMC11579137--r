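# shared in-code fixtures: everything is generated, nothing read from disk
# except the packaged reference spectrum table

# small geometry for fast tests: coarse depth grid, few radii
small_geometry <- function() {
  beam_geometry(radial_grid = c(0, seq(1.5, 21.5, by = 2)),
                depth_grid = seq(0.5, 25, by = 0.5))
}

# a 3-bin toy problem: analytic basis on a handful of depths, used for
# hand-checkable oracles and the brute-force grid search
toy_binning <- function() energy_binning(c(0.3, 0.9, 2.1, 4.5))

toy_fanline <- function(depths = seq(2.5, 25, by = 2.5),
                        geometry = beam_geometry(depth_grid = depths)) {
  basis <- generate_basis(geometry, toy_binning(), radial_tilt = 0)
  resample_to_fanline(basis, 0, geometry)
}

# direct sigma^2 of relative fluences p against a measured curve, computed
# from first principles (no package fitting code): forward superposition,
# normalization at norm_depth, relative differences - the oracle the QP
# route is compared with
sigma2_direct <- function(p, fanline, meas_values, norm_depth = 10,
                          scale = NULL) {
  num <- as.numeric(fanline$dose %*% p)
  if (is.null(scale)) {
    denom <- stats::approx(fanline$depths, num, xout = norm_depth)$y
    recon <- 100 * num / denom
  } else {
    recon <- scale * num
  }
  mean(((recon - meas_values) / meas_values * 100)^2)
}

# exhaustive simplex grid search (step h) over all fluence vectors that are
# unimodal about some scanned peak; independent of the package optimizer
grid_search_sigma2 <- function(fanline, meas_values, h = 0.01,
                               norm_depth = 10) {
  best <- Inf
  steps <- round(1 / h)
  for (i in 0:steps) {
    for (j in 0:(steps - i)) {
      p <- c(i, j, steps - i - j) * h
      if (!any(vapply(1:3, function(k) check_unimodal(p, k), logical(1)))) next
      s2 <- sigma2_direct(p, fanline, meas_values, norm_depth)
      if (s2 < best) best <- s2
    }
  }
  best
}

# a quick full synthetic closed-loop with few radii for property tests
quick_loop <- function(seed = 1, noise_sd = 0.2, radii = seq(0, 18, by = 6)) {
  spec <- synthetic_beam_spec(radii = radii, noise_sd = noise_sd, seed = seed)
  suppressWarnings(closed_loop(spec, beam_geometry(), unfold_config()))
}
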