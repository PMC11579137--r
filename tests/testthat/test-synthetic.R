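test_that("analytic MDD has buildup, attenuation and hardness ordering", {
  g <- beam_geometry()
  m <- attenuation_model()
  expect_equal(analytic_mdd(1.2, 0, g, m), 0)   # no dose at zero depth
  d <- seq(0.2, 25, 0.2)
  for (E in c(0.1, 1.2, 6.075)) {
    v <- analytic_mdd(E, d, g, m)
    expect_true(all(v > 0))
  }
  # normalized-to-d10 value at 25 cm grows with energy (harder penetrates)
  norm25 <- vapply(default_binning()$mid, function(E) {
    v <- analytic_mdd(E, d, g, m)
    v[d == 25] / v[d == 10]
  }, numeric(1))
  expect_true(all(diff(norm25) > 0))
  # attenuation-free, divergence-free limit: constant beyond buildup
  free <- attenuation_model("parametric")
  free$mu <- function(E) 0
  gfar <- beam_geometry(ssd = 1e8)
  v <- analytic_mdd(4, c(10, 20, 25), gfar, free)
  expect_equal(v / v[1], rep(1, 3), tolerance = 1e-6)
  expect_error(analytic_mdd(9, 5, g, m), "outside")
})

test_that("attenuation models are positive and strictly decreasing in energy", {
  E <- default_binning()$mid
  for (src in c("table", "parametric")) {
    m <- attenuation_model(src)
    mu <- m$mu(E)
    expect_true(all(mu > 0))
    expect_true(all(diff(mu) < 0))
  }
})

test_that("generated basis has the full grid shape and valid columns", {
  basis <- generate_basis(beam_geometry(), default_binning())
  expect_equal(dim(basis$dose), c(13L, 22L, 125L))
  expect_true(all(basis$dose[, , -1] > 0))
  # zero tilt: all radial columns identical
  flat <- generate_basis(small_geometry(), default_binning(),
                         radial_tilt = 0)
  for (i in c(1L, 13L)) {
    expect_equal(flat$dose[i, , ], flat$dose[i, , ][rep(1, 12), ],
                 ignore_attr = TRUE)
  }
})

test_that("ground-truth families are unimodal, softening-ordered and deterministic", {
  spec <- synthetic_beam_spec(seed = 5)
  tf <- generate_true_family(spec)
  expect_length(tf$family$members, 10L)
  for (k in seq_along(tf$family$members)) {
    expect_true(check_unimodal(tf$family$members[[k]]$p,
                               tf$peak_indices[k]))
  }
  expect_true(check_softening(tf$family, tf$peak_indices, tol = 1e-12))
  # the projection is idempotent on generator output
  proj <- project_softening(tf$family, tf$peak_indices)
  for (k in seq_along(tf$family$members)) {
    expect_equal(proj$members[[k]]$p, tf$family$members[[k]]$p,
                 tolerance = 1e-12)
  }
  # zero softening: all members identical
  same <- generate_true_family(synthetic_beam_spec(softening_rate = 0))
  expect_equal(same$family$members[[1]]$p, same$family$members[[10]]$p)
  # single radius: one unimodal simplex point
  one <- generate_true_family(synthetic_beam_spec(radii = 0))
  expect_length(one$family$members, 1L)
  expect_equal(sum(one$family$members[[1]]$p), 1)
})

test_that("mean energy decreases with radius for generated families", {
  # the softening construction must lower the mean energy monotonically;
  # checked over 100 seeded parameter draws
  set.seed(2024)
  for (i in 1:100) {
    spec <- synthetic_beam_spec(
      radii = seq(0, 18, length.out = sample(3:8, 1)),
      softening_rate = runif(1, 0.01, 0.12),
      peak_energy = runif(1, 1.2, 2.6),
      peak_width = runif(1, 0.4, 0.8),
      seed = i)
    fam <- generate_true_family(spec)$family
    me <- vapply(fam$members, mean_energy, numeric(1))
    expect_true(all(diff(me) <= 1e-12))
  }
})

test_that("synthetic measurements are seeded, normalized and have noise-free twins", {
  spec <- synthetic_beam_spec(radii = c(0, 6, 12), seed = 3)
  g <- beam_geometry()
  basis <- generate_basis(g, spec$binning, radial_tilt = spec$radial_tilt)
  tf <- generate_true_family(spec)
  s1 <- synth_measured(spec, tf$family, basis, g)
  s2 <- synth_measured(spec, tf$family, basis, g)
  # determinism under the same seed
  for (k in 1:3) {
    expect_identical(s1$pdd_measured[[k]]$values, s2$pdd_measured[[k]]$values)
  }
  # noise-free twins pass through 100 at d10 exactly
  for (k in 1:3) {
    expect_equal(s1$pdd_true[[k]]$values[s1$pdd_true[[k]]$depths == 10], 100)
  }
  # zero noise: measured equals the twin
  s0 <- synth_measured(synthetic_beam_spec(radii = c(0, 6, 12),
                                           noise_sd = 0, seed = 3),
                       tf$family, basis, g)
  for (k in 1:3) {
    expect_equal(s0$pdd_measured[[k]]$values, s0$pdd_true[[k]]$values,
                 tolerance = 1e-12)
    expect_equal(s0$oar_measured[[k]]$values, s0$oar_true[[k]]$values,
                 tolerance = 1e-12)
  }
  # OAR truth reflects the horn fluence profile
  expect_equal(s1$fluence_ratios[1], 1)
})
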