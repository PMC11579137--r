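#' Water attenuation model for the analytic MDD generator
#'
#' Per-energy linear attenuation coefficient \eqn{\mu(E)} (cm^-1) and
#' energy-absorption weight \eqn{\kappa(E)} (relative) for water. The
#' `"table"` source interpolates (log-log) a built-in table of approximate
#' water coefficients at megavoltage energies; the `"parametric"` fallback
#' uses the smooth power law \eqn{\mu(E) = 0.0707 E^{-0.35}} cm^-1
#' (anchored near 0.07 cm^-1 at 1 MeV) with \eqn{\kappa \propto E^{0.7}}.
#' Physical exactness is not required anywhere downstream — the unfolding
#' only exercises a smooth, strictly decreasing \eqn{\mu} over
#' 0.05-7 MeV — so the table values are a convenience, not dosimetry data.
#'
#' @param source `"table"` (default) or `"parametric"`.
#' @return Object of class `attenuation_model` with functions `mu(E)` and
#'   `kappa(E)` and the support range.
#' @export
attenuation_model <- function(source = c("table", "parametric")) {
  source <- match.arg(source)
  support <- c(0.05, 7.0)
  if (source == "table") {
    # approximate water coefficients: E (MeV), linear attenuation mu (1/cm),
    # mass energy-absorption coefficient mu_en/rho (cm^2/g)
    tab <- data.frame(
      E     = c(0.05, 0.08, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50, 0.60,
                0.80, 1.00, 1.25, 1.50, 2.00, 3.00, 4.00, 5.00, 6.00, 7.00),
      mu    = c(0.2269, 0.1837, 0.1707, 0.1505, 0.1370, 0.1186, 0.1061,
                0.0969, 0.0896, 0.0786, 0.0707, 0.0632, 0.0575, 0.0494,
                0.0397, 0.0340, 0.0303, 0.0277, 0.0257),
      mu_en = c(0.0422, 0.0262, 0.0255, 0.0277, 0.0297, 0.0319, 0.0328,
                0.0330, 0.0329, 0.0321, 0.0310, 0.0296, 0.0283, 0.0260,
                0.0227, 0.0206, 0.0191, 0.0180, 0.0170)
    )
    mu_f <- function(E) {
      exp(stats::approx(log(tab$E), log(tab$mu), xout = log(E), rule = 2)$y)
    }
    kappa_f <- function(E) {
      E * exp(stats::approx(log(tab$E), log(tab$mu_en), xout = log(E),
                            rule = 2)$y)
    }
  } else {
    mu_f <- function(E) 0.0707 * E^(-0.35)
    kappa_f <- function(E) E^0.7
  }
  structure(list(mu = mu_f, kappa = kappa_f, support = support,
                 source = source),
            class = "attenuation_model")
}

#' Synthetic beam definition
#'
#' Parameters of the synthetic linac beam that stands in for Monte Carlo
#' transport and water-phantom scans in the closed-loop experiments: the
#' energy binning, the measured radii, how fast the spectrum softens
#' off-axis, the lateral fluence horn profile, and the measurement noise.
#'
#' Defaults emulate a flattened 6 MV beam: radii 0-18 cm in 2 cm steps,
#' softening that lowers the mean energy by roughly a quarter from center
#' to 18 cm, gentle horns (`w = 1 + a (r/20)^2 - b (r/20)^6` with
#' `a = 0.03`, `b = 0.02`), and 0.2% multiplicative Gaussian noise
#' (typical scanning-chamber repeatability).
#'
#' @param binning An [energy_binning()] (default [default_binning()]).
#' @param radii Radial distances r0 (cm), increasing from 0
#'   (default `seq(0, 18, 2)`).
#' @param softening_rate Per-cm downward fluence-transport rate (>= 0)
#'   controlling how fast the spectral mode shifts to lower energies with
#'   radius (default 0.05).
#' @param horn_a,horn_b Horn-profile coefficients (default 0.03, 0.02).
#' @param noise_sd Multiplicative Gaussian 1-sigma noise on measured
#'   curves, in percent (default 0.2).
#' @param peak_energy Mode (MeV) of the central-axis fluence bump
#'   (default 1.8).
#' @param peak_width Log-scale width of the bump (default 0.55).
#' @param radial_tilt Relative radial tilt of the MDD basis (default 0.02).
#' @param seed Integer seed for the noise draws (default 1).
#' @return Object of class `synthetic_beam_spec`.
#' @export
synthetic_beam_spec <- function(binning = default_binning(),
                                radii = seq(0, 18, by = 2),
                                softening_rate = 0.05,
                                horn_a = 0.03, horn_b = 0.02,
                                noise_sd = 0.2,
                                peak_energy = 1.8, peak_width = 0.55,
                                radial_tilt = 0.02,
                                seed = 1L) {
  stopifnot(inherits(binning, "energy_binning"))
  radii <- as.numeric(radii)
  if (radii[1L] != 0 || any(diff(radii) <= 0)) {
    stop("radii must increase strictly from 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (softening_rate < 0) stop("softening_rate must be >= 0", call. = FALSE)
  structure(list(binning = binning, radii = radii,
                 softening_rate = softening_rate,
                 horn_a = horn_a, horn_b = horn_b, noise_sd = noise_sd,
                 peak_energy = peak_energy, peak_width = peak_width,
                 radial_tilt = radial_tilt, seed = as.integer(seed)),
            class = "synthetic_beam_spec")
}

#' Analytic monoenergetic depth dose
#'
#' A smooth stand-in for a Monte Carlo monoenergetic depth-dose curve:
#' \deqn{D(E, d) = \kappa(E)\, e^{-\mu(E) d}\, (1 - e^{-\beta(E) d})\,
#'   \left(\frac{SSD + 10}{SSD + d}\right)^2}
#' with buildup rate \eqn{\beta(E) = \ln(20)/d_b(E)},
#' \eqn{d_b(E) = \max(0.05, 0.25 E)} cm — a deliberate cartoon of
#' electron-range growth that reproduces the qualitative behaviour the
#' unfolding exercises: deeper dose maximum and slower falloff at higher
#' energy (because \eqn{\mu} decreases with \eqn{E}), plus inverse-square
#' divergence. Deterministic and strictly positive for `d > 0`.
#'
#' @param E Photon energy (MeV), inside the model support.
#' @param d Depth(s) in cm, >= 0.
#' @param geometry A [beam_geometry()] (supplies the SSD).
#' @param model An [attenuation_model()].
#' @return Dose per incident fluence (relative), same length as `d`.
#' @export
analytic_mdd <- function(E, d, geometry = beam_geometry(),
                         model = attenuation_model()) {
  if (E < model$support[1L] - 1e-9 || E > model$support[2L] + 1e-9) {
    stop("energy ", E, " MeV outside the attenuation model support",
         call. = FALSE)
  }
  if (any(d < 0)) stop("depth must be non-negative", call. = FALSE)
  beta <- log(20) / max(0.05, 0.25 * E)
  model$kappa(E) * exp(-model$mu(E) * d) * (1 - exp(-beta * d)) *
    ((geometry$ssd + 10) / (geometry$ssd + d))^2
}

#' Generate a full analytic MDD basis
#'
#' Fills the (energy x radius x depth) dose table with [analytic_mdd()]
#' values, optionally modulated by a smooth radial multiplier
#' \eqn{1 + t (r/r_{max})^2} that emulates mild radial variation of the
#' scored dose. The statistical-uncertainty table is filled with a
#' constant placeholder (0.3%).
#'
#' @param geometry A [beam_geometry()].
#' @param binning An [energy_binning()]; the basis energies are its
#'   mid-energies.
#' @param model An [attenuation_model()].
#' @param radial_tilt Relative amplitude of the radial multiplier
#'   (default 0.02; 0 makes all radial columns identical).
#' @return An [mdd_basis()].
#' @export
generate_basis <- function(geometry = beam_geometry(),
                           binning = default_binning(),
                           model = attenuation_model(),
                           radial_tilt = 0.02) {
  ne <- binning$n
  nr <- length(geometry$radial_grid)
  nd <- length(geometry$depth_grid)
  rmax <- max(geometry$radial_grid)
  rmult <- 1 + radial_tilt * (geometry$radial_grid / rmax)^2
  dose <- array(0, dim = c(ne, nr, nd))
  for (i in seq_len(ne)) {
    curve <- analytic_mdd(binning$mid[i], geometry$depth_grid, geometry, model)
    dose[i, , ] <- outer(rmult, curve)
  }
  mdd_basis(binning$mid, geometry, dose,
            sd_percent = array(0.3, dim = c(ne, nr, nd)),
            binning = binning)
}

# one softening step: move fraction alpha of each bin's fluence one bin
# down in energy (mass-conserving transport). Preserves unimodality (the
# peak stays or shifts down one bin) and dominates the previous vector
# below the new peak while being dominated above it, so families built by
# iterating this kernel satisfy the softening ordering by construction.
soften_step <- function(p, alpha) {
  n <- length(p)
  if (alpha <= 0) return(p)
  q <- (1 - alpha) * p
  q[seq_len(n - 1L)] <- q[seq_len(n - 1L)] + alpha * p[-1L]
  q[1L] <- q[1L] + alpha * p[1L]  # mass leaving bin 1 stays in bin 1
  q
}

#' Generate a ground-truth spectrum family
#'
#' Constructs the known-truth per-radius spectra of a synthetic beam. The
#' central-axis spectrum is a discretized log-normal fluence bump over the
#' mid-energies (mode `peak_energy`, width `peak_width`); each step
#' outward applies a mass-conserving downward-transport kernel with
#' per-step rate `softening_rate * dr`, so the family is unimodal at every
#' radius and satisfies the off-axis softening ordering exactly by
#' construction (no projection needed; [project_softening()] is the
#' identity on the output).
#'
#' @param spec A [synthetic_beam_spec()].
#' @return List with `family` (a [spectrum_family()]) and `peak_indices`
#'   (integer vector of per-member fluence maxima).
#' @export
generate_true_family <- function(spec) {
  stopifnot(inherits(spec, "synthetic_beam_spec"))
  b <- spec$binning
  p0 <- stats::dlnorm(b$mid, meanlog = log(spec$peak_energy),
                      sdlog = spec$peak_width) * b$width
  p0 <- p0 / sum(p0)
  if (!check_unimodal(p0, find_peak(p0))) {
    stop("generation error: the central-axis bump is not unimodal on this ",
         "binning; adjust peak_energy/peak_width", call. = FALSE)
  }
  members <- vector("list", length(spec$radii))
  members[[1L]] <- spectrum(p0, b, r0 = spec$radii[1L])
  p <- p0
  if (length(spec$radii) > 1L) {
    for (k in 2:length(spec$radii)) {
      dr <- spec$radii[k] - spec$radii[k - 1L]
      alpha <- min(spec$softening_rate * dr, 0.5)
      p <- soften_step(p, alpha)
      members[[k]] <- spectrum(p, b, r0 = spec$radii[k])
    }
  }
  family <- spectrum_family(members)
  peaks <- vapply(members, find_peak, integer(1))
  if (!check_softening(family, peaks, tol = 1e-12)) {
    stop("generation error: softening ordering violated; ",
         "use a smaller softening_rate", call. = FALSE)
  }
  list(family = family, peak_indices = peaks)
}

horn_profile <- function(spec, r0) {
  1 + spec$horn_a * (r0 / 20)^2 - spec$horn_b * (r0 / 20)^6
}

apply_noise <- function(values, noise_sd) {
  values * (1 + stats::rnorm(length(values), sd = noise_sd / 100))
}

#' Synthesize measured PDD and OAR scans from a known beam
#'
#' Produces everything a water-phantom commissioning session would: per
#' radius, the PDD along the fan line (forward model of the true spectrum,
#' d10-normalized) and, at depths 5, 10 and 20 cm, OAR profiles with the
#' spec's horn fluence profile. Multiplicative Gaussian noise
#' (`spec$noise_sd` %, seeded with `spec$seed`) is applied to the
#' "measured" outputs, which are then renormalized to their reference
#' point; noise-free twins are returned alongside for closed-loop checks.
#'
#' @param spec A [synthetic_beam_spec()].
#' @param family Ground-truth [spectrum_family()] (e.g. from
#'   [generate_true_family()]).
#' @param basis An [mdd_basis()] on the same binning.
#' @param geometry A [beam_geometry()]; defaults to the basis geometry.
#' @param oar_depths Depths of the lateral profiles (cm), default
#'   `c(5, 10, 20)`.
#' @return List with `pdd_measured`, `pdd_true` (lists of
#'   [depth_dose_curve()]), `oar_measured`, `oar_true` (lists of
#'   [lateral_profile()]), and `fluence_ratios` (the true horn profile at
#'   the spec radii).
#' @export
synth_measured <- function(spec, family, basis,
                           geometry = basis$geometry,
                           oar_depths = c(5, 10, 20)) {
  stopifnot(inherits(spec, "synthetic_beam_spec"),
            inherits(family, "spectrum_family"),
            inherits(basis, "mdd_basis"))
  set.seed(spec$seed)
  w <- horn_profile(spec, family$r0)
  w <- w / w[1L]

  pdd_true <- vector("list", length(family$members))
  pdd_meas <- vector("list", length(family$members))
  for (k in seq_along(family$members)) {
    fl <- resample_to_fanline(basis, family$r0[k], geometry)
    truth <- reconstruct_pdd(family$members[[k]], fl, norm_depth = 10)
    pdd_true[[k]] <- truth
    noisy <- apply_noise(truth$values, spec$noise_sd)
    pdd_meas[[k]] <- depth_dose_curve(truth$depths, noisy, r0 = truth$r0,
                                      norm_depth = 10, ssd = geometry$ssd,
                                      renormalize = TRUE)
  }

  oar_true <- vector("list", length(oar_depths))
  oar_meas <- vector("list", length(oar_depths))
  for (j in seq_along(oar_depths)) {
    truth <- compute_oar(family, w, basis, oar_depths[j], geometry)
    oar_true[[j]] <- truth
    noisy <- apply_noise(truth$values, spec$noise_sd)
    oar_meas[[j]] <- lateral_profile(truth$radii, noisy, truth$depth,
                                     renormalize = TRUE)
  }

  list(pdd_measured = pdd_meas, pdd_true = pdd_true,
       oar_measured = oar_meas, oar_true = oar_true,
       fluence_ratios = w)
}

#' Run one full closed-loop synthetic experiment
#'
#' Convenience wrapper chaining the whole pipeline on synthetic data:
#' generate the basis and ground truth, synthesize noisy scans, unfold the
#' spectra, reconstruct the PDDs, fit fluence ratios and recompute OARs,
#' and report the maximum absolute relative differences against the
#' noise-free twins.
#'
#' @param spec A [synthetic_beam_spec()].
#' @param geometry A [beam_geometry()].
#' @param config An [unfold_config()].
#' @return List with `result` (the [unfold_family()] output), `scans`,
#'   `basis`, `truth`, `fitted_ratios`, `max_abs_delta_pdd` and
#'   `max_abs_delta_oar` (both in %).
#' @export
closed_loop <- function(spec = synthetic_beam_spec(),
                        geometry = beam_geometry(),
                        config = unfold_config()) {
  basis <- generate_basis(geometry, spec$binning,
                          radial_tilt = spec$radial_tilt)
  truth <- generate_true_family(spec)
  scans <- synth_measured(spec, truth$family, basis, geometry)
  res <- unfold_family(scans$pdd_measured, basis, geometry, config)

  d_pdd <- vapply(seq_along(scans$pdd_true), function(k) {
    fl <- resample_to_fanline(basis, res$family$r0[k], geometry)
    recon <- reconstruct_pdd(res$family$members[[k]], fl, config$norm_depth)
    max(abs(relative_difference(recon, scans$pdd_true[[k]],
                                config$fit_window)))
  }, numeric(1))

  w_fit <- fit_fluence_ratios(res$family, basis, scans$oar_measured, geometry)
  d_oar <- vapply(seq_along(scans$oar_true), function(j) {
    calc <- compute_oar(res$family, w_fit, basis, scans$oar_true[[j]]$depth,
                        geometry)
    max(abs((calc$values - scans$oar_true[[j]]$values) /
              scans$oar_true[[j]]$values * 100))
  }, numeric(1))

  list(result = res, scans = scans, basis = basis, truth = truth,
       fitted_ratios = w_fit,
       max_abs_delta_pdd = max(d_pdd),
       max_abs_delta_oar = max(d_oar))
}
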