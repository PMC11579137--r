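#' Monoenergetic depth-dose basis
#'
#' Absorbed dose per incident photon fluence on a grid of
#' (mono-energy x radial position x depth) — the basis functions of the
#' spectral unfolding. Doses are relative (any common scale cancels in
#' PDD and OAR ratios); an optional same-shaped table of 1-sigma
#' statistical uncertainties (%) can be attached as a diagnostic.
#'
#' @param energies Mono-energies \eqn{E_i} in MeV, strictly increasing.
#' @param geometry A [beam_geometry()] providing the radial and depth grids.
#' @param dose 3-D array `(energy, radius, depth)` of dose per fluence,
#'   non-negative, positive beyond the first depth node.
#' @param sd_percent Optional array of the same shape: 1-sigma statistical
#'   uncertainty in percent.
#' @param binning Optional [energy_binning()] whose mid-energies are the
#'   basis energies; recovered from `energies` when omitted.
#' @return Object of class `mdd_basis`.
#' @export
mdd_basis <- function(energies, geometry, dose, sd_percent = NULL,
                      binning = NULL) {
  stopifnot(inherits(geometry, "beam_geometry"))
  energies <- as.numeric(energies)
  if (any(diff(energies) <= 0)) {
    stop("energies must be strictly increasing", call. = FALSE)
  }
  dm <- dim(dose)
  want <- c(length(energies), length(geometry$radial_grid),
            length(geometry$depth_grid))
  if (is.null(dm) || length(dm) != 3L || any(dm != want)) {
    stop("dose must be a (energy x radius x depth) array of dim ",
         paste(want, collapse = " x "), call. = FALSE)
  }
  if (anyNA(dose) || any(dose < 0)) {
    stop("dose values must be non-negative and free of NA", call. = FALSE)
  }
  if (any(dose[, , -1L] <= 0)) {
    stop("dose must be positive beyond the first depth node for every (energy, radius)",
         call. = FALSE)
  }
  if (!is.null(sd_percent) && !identical(dim(sd_percent), dm)) {
    stop("sd_percent must have the same shape as dose", call. = FALSE)
  }
  if (is.null(binning)) {
    binning <- binning_from_energies(energies)
  } else {
    stopifnot(inherits(binning, "energy_binning"))
    if (binning$n != length(energies) ||
        max(abs(binning$mid - energies)) > 1e-9) {
      stop("binning mid-energies do not match the basis energies",
           call. = FALSE)
    }
  }
  structure(list(energies = energies, geometry = geometry,
                 dose = dose, sd_percent = sd_percent, binning = binning),
            class = "mdd_basis")
}

#' @export
print.mdd_basis <- function(x, ...) {
  cat(sprintf("MDD basis: %d energies (%.3g-%.3g MeV) x %d radii x %d depths\n",
              length(x$energies), min(x$energies), max(x$energies),
              length(x$geometry$radial_grid), length(x$geometry$depth_grid)))
  invisible(x)
}

#' Percentage depth-dose curve along one fan line
#'
#' Relative dose (%) versus depth, normalized to 100 at `norm_depth`
#' (default convention: 10 cm, which avoids both charged-particle
#' contamination near the surface and the positional uncertainty of the
#' dose maximum).
#'
#' @param depths Depths in cm, strictly increasing.
#' @param values Relative dose in percent.
#' @param r0 Radial distance of the fan line on the SSD plane (cm).
#' @param norm_depth Normalization depth (cm); the curve must read 100
#'   there (linear interpolation if it is not a grid node).
#' @param ssd Source-surface distance used to derive the angle (cm).
#' @param renormalize If `TRUE`, rescale `values` so the curve reads 100
#'   at `norm_depth`; if `FALSE` (default), a deviation beyond 1e-9 errors.
#' @return Object of class `depth_dose_curve`.
#' @export
depth_dose_curve <- function(depths, values, r0 = 0, norm_depth = 10,
                             ssd = 100, renormalize = FALSE) {
  depths <- as.numeric(depths)
  values <- as.numeric(values)
  if (length(depths) != length(values) || length(depths) < 2L) {
    stop("depths and values must match in length (>= 2)", call. = FALSE)
  }
  if (any(diff(depths) <= 0)) {
    stop("depths must be strictly increasing", call. = FALSE)
  }
  if (norm_depth < min(depths) || norm_depth > max(depths)) {
    stop("norm_depth must lie inside the depth range", call. = FALSE)
  }
  at_norm <- stats::approx(depths, values, xout = norm_depth)$y
  if (renormalize) {
    if (at_norm <= 0) stop("degenerate normalization: value at norm_depth <= 0",
                           call. = FALSE)
    values <- values * 100 / at_norm
  } else if (abs(at_norm - 100) > 1e-9) {
    stop("curve reads ", format(at_norm), " (not 100) at norm_depth = ",
         norm_depth, " cm; pass renormalize = TRUE to rescale", call. = FALSE)
  }
  structure(list(depths = depths, values = values, r0 = r0,
                 theta = off_axis_angle(r0, ssd), norm_depth = norm_depth),
            class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf("PDD at r0 = %g cm: %d depths %g-%g cm, 100%% at d = %g cm\n",
              x$r0, length(x$depths), min(x$depths), max(x$depths),
              x$norm_depth))
  invisible(x)
}

#' Lateral dose profile (off-axis ratio) at fixed depth
#'
#' Relative dose (%) versus radial position at the SSD plane, normalized
#' to 100 on the central axis.
#'
#' @param radii Radial positions at the SSD plane (cm), non-negative,
#'   strictly increasing, starting at 0.
#' @param values Relative dose in percent; must read 100 at radius 0.
#' @param depth Depth of the profile (cm).
#' @param renormalize If `TRUE`, rescale so the central-axis value is 100.
#' @return Object of class `lateral_profile`.
#' @export
lateral_profile <- function(radii, values, depth, renormalize = FALSE) {
  radii <- as.numeric(radii)
  values <- as.numeric(values)
  if (length(radii) != length(values) || length(radii) < 1L) {
    stop("radii and values must match in length", call. = FALSE)
  }
  if (radii[1L] != 0 || any(diff(radii) <= 0)) {
    stop("radii must start at 0 and increase strictly", call. = FALSE)
  }
  if (renormalize) {
    if (values[1L] <= 0) stop("degenerate normalization: central-axis value <= 0",
                              call. = FALSE)
    values <- values * 100 / values[1L]
  } else if (abs(values[1L] - 100) > 1e-9) {
    stop("profile reads ", format(values[1L]),
         " (not 100) on the central axis; pass renormalize = TRUE",
         call. = FALSE)
  }
  structure(list(radii = radii, values = values, depth = depth),
            class = "lateral_profile")
}

#' @export
print.lateral_profile <- function(x, ...) {
  cat(sprintf("OAR at d = %g cm: %d radii 0-%g cm\n",
              x$depth, length(x$radii), max(x$radii)))
  invisible(x)
}

#' Reconstruct a polyenergetic PDD from a spectrum
#'
#' The forward model of the unfolding: the percentage depth dose of a
#' discrete spectrum is the fluence-weighted superposition of the
#' monoenergetic depth doses along the fan line,
#' \deqn{PDD(d) = 100 \frac{\sum_i p_i D(E_i, d)}{\sum_i p_i D(E_i, d_{norm})}.}
#' Bin widths cancel because \eqn{p_i} already absorbs them; the result is
#' invariant to rescaling all \eqn{p_i} by a common constant.
#'
#' @param spectrum A [spectrum()] on the basis energies.
#' @param fanline_mdds Per-energy depth-dose curves from
#'   [resample_to_fanline()].
#' @param norm_depth Normalization depth (cm), inside the depth range.
#' @return A [depth_dose_curve()].
#' @export
reconstruct_pdd <- function(spectrum, fanline_mdds, norm_depth = 10) {
  stopifnot(inherits(spectrum, "spectrum"),
            inherits(fanline_mdds, "fanline_mdds"))
  if (length(spectrum$p) != length(fanline_mdds$energies) ||
      max(abs(spectrum$binning$mid - fanline_mdds$energies)) > 1e-9) {
    stop("spectrum binning energies do not match the MDD basis energies",
         call. = FALSE)
  }
  num <- as.numeric(fanline_mdds$dose %*% spectrum$p)
  denom <- stats::approx(fanline_mdds$depths, num, xout = norm_depth)$y
  if (is.na(denom) || denom <= 0) {
    stop("degenerate normalization: superposed dose at norm_depth is not positive",
         call. = FALSE)
  }
  depth_dose_curve(fanline_mdds$depths, 100 * num / denom,
                   r0 = fanline_mdds$r0, norm_depth = norm_depth,
                   renormalize = TRUE)
}

#' Linearly resample a depth-dose curve onto new depth nodes
#'
#' @param curve A [depth_dose_curve()].
#' @param depths New depth nodes (cm), inside the curve's range.
#' @return A [depth_dose_curve()] on `depths` (renormalized so that the
#'   value at its `norm_depth` stays 100 when `norm_depth` is inside the
#'   new range).
#' @export
resample_curve <- function(curve, depths) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  depths <- as.numeric(depths)
  if (min(depths) < min(curve$depths) || max(depths) > max(curve$depths)) {
    stop("requested depths extend beyond the measured curve", call. = FALSE)
  }
  v <- stats::approx(curve$depths, curve$values, xout = depths)$y
  nd <- if (curve$norm_depth >= min(depths) && curve$norm_depth <= max(depths))
    curve$norm_depth else depths[which.max(v)]
  depth_dose_curve(depths, v, r0 = curve$r0, norm_depth = nd,
                   renormalize = TRUE)
}

window_indices <- function(depths, fit_window) {
  which(depths >= fit_window[1L] - 1e-9 & depths <= fit_window[2L] + 1e-9)
}

#' Per-depth relative difference between two PDDs
#'
#' \eqn{\delta_j = (PDD_{recon,j} - PDD_{meas,j}) / PDD_{meas,j} \times 100}
#' at every shared depth node inside the fit window.
#'
#' @param recon,meas [depth_dose_curve()] objects sharing depth nodes
#'   inside the window (resample first with [resample_curve()] if needed).
#' @param fit_window Depth interval `c(lo, hi)` in cm (default 2 to 25,
#'   which excludes the buildup region below the dose maximum).
#' @return Named numeric vector of \eqn{\delta_j} in percent (names are the
#'   depths).
#' @export
relative_difference <- function(recon, meas, fit_window = c(2, 25)) {
  stopifnot(inherits(recon, "depth_dose_curve"),
            inherits(meas, "depth_dose_curve"))
  ir <- window_indices(recon$depths, fit_window)
  im <- window_indices(meas$depths, fit_window)
  if (length(ir) == 0L || length(ir) != length(im) ||
      max(abs(recon$depths[ir] - meas$depths[im])) > 1e-9) {
    stop("curves do not share depth nodes inside the fit window; resample first",
         call. = FALSE)
  }
  mv <- meas$values[im]
  if (any(mv == 0)) {
    stop("measured value is zero inside the fit window", call. = FALSE)
  }
  delta <- (recon$values[ir] - mv) / mv * 100
  names(delta) <- format(recon$depths[ir])
  delta
}

#' Fit objective: variance of the relative difference
#'
#' \eqn{\sigma^2 = m^{-1} \sum_j \delta_j^2} over the `m` depths of the fit
#' window — the quantity the unfolding minimizes. Zero iff the curves are
#' identical on the window.
#'
#' @inheritParams relative_difference
#' @return \eqn{\sigma^2} in percent squared.
#' @export
objective_sigma2 <- function(recon, meas, fit_window = c(2, 25)) {
  delta <- relative_difference(recon, meas, fit_window)
  if (length(delta) == 0L) stop("empty fit window", call. = FALSE)
  mean(delta^2)
}

# superposed fan-line dose of one spectrum at one depth
superposed_dose_at <- function(spectrum, fanline_mdds, depth) {
  num <- as.numeric(fanline_mdds$dose %*% spectrum$p)
  v <- stats::approx(fanline_mdds$depths, num, xout = depth)$y
  if (is.na(v)) stop("depth ", depth, " cm outside the basis depth grid",
                     call. = FALSE)
  v
}

#' Compute an off-axis ratio profile from a spectrum family
#'
#' The OAR at one depth is the fluence-ratio-weighted superposed dose along
#' each fan line, normalized to the central axis:
#' \deqn{OAR(r_0) = 100 \frac{w(r_0) \sum_i p_i(r_0) D(E_i, d, r_0)}
#'                           {w(0) \sum_i p_i(0) D(E_i, d, 0)}.}
#' The fluence ratio \eqn{w(r_0)} carries the lateral fluence profile
#' (flattening-filter horns) that PDD shapes cannot constrain.
#'
#' @param family A [spectrum_family()].
#' @param fluence_ratios One scalar \eqn{w} per member; `w[1]` (central
#'   axis) must be 1.
#' @param basis An [mdd_basis()].
#' @param depth Profile depth (cm), inside the basis depth grid.
#' @param geometry A [beam_geometry()]; defaults to the basis geometry.
#' @return A [lateral_profile()].
#' @export
compute_oar <- function(family, fluence_ratios, basis, depth,
                        geometry = basis$geometry) {
  stopifnot(inherits(family, "spectrum_family"), inherits(basis, "mdd_basis"))
  m <- length(family$members)
  if (length(fluence_ratios) != m) {
    stop("need one fluence ratio per family member", call. = FALSE)
  }
  if (abs(fluence_ratios[1L] - 1) > 1e-12 && family$r0[1L] == 0) {
    stop("the central-axis fluence ratio must be 1 by convention",
         call. = FALSE)
  }
  if (depth < min(geometry$depth_grid) || depth > max(geometry$depth_grid)) {
    stop("depth outside the basis depth grid", call. = FALSE)
  }
  a <- vapply(seq_len(m), function(k) {
    fl <- resample_to_fanline(basis, family$r0[k], geometry)
    fluence_ratios[k] * superposed_dose_at(family$members[[k]], fl, depth)
  }, numeric(1))
  lateral_profile(family$r0, 100 * a / a[1L], depth)
}

#' Fit per-radius fluence ratios to measured lateral profiles
#'
#' Determines one fluence ratio \eqn{w(r_0)} per family member (shared
#' across all depths) by least squares on the radial relative difference
#' \eqn{\delta_r}. Because \eqn{w(r_0)} multiplies the computed OAR
#' linearly, the per-radius solution is closed-form: with
#' \eqn{t_d = OAR_{calc, w=1}(r_0, d) / OAR_{meas}(r_0, d)} over the fitted
#' depths \eqn{d}, minimizing \eqn{\sum_d (w t_d - 1)^2} gives
#' \eqn{w = \sum_d t_d / \sum_d t_d^2}.
#'
#' @param family A [spectrum_family()].
#' @param basis An [mdd_basis()].
#' @param measured List of [lateral_profile()] objects at one or more
#'   depths, sharing the family's radii.
#' @param geometry A [beam_geometry()]; defaults to the basis geometry.
#' @param per_depth If `TRUE`, fit one ratio per radius and depth instead
#'   of sharing across depths; returns a matrix (radius x depth).
#' @return Numeric vector of fluence ratios (first element 1), or a matrix
#'   when `per_depth = TRUE`.
#' @export
fit_fluence_ratios <- function(family, basis, measured,
                               geometry = basis$geometry, per_depth = FALSE) {
  stopifnot(inherits(family, "spectrum_family"), inherits(basis, "mdd_basis"))
  if (length(measured) < 1L) stop("need at least one measured profile",
                                  call. = FALSE)
  m <- length(family$members)
  tmat <- matrix(NA_real_, m, length(measured))  # t = calc(w=1) / meas
  for (j in seq_along(measured)) {
    prof <- measured[[j]]
    stopifnot(inherits(prof, "lateral_profile"))
    idx <- match(round(family$r0, 9), round(prof$radii, 9))
    if (anyNA(idx)) {
      stop("measured profile at d = ", prof$depth,
           " cm does not cover the family radii", call. = FALSE)
    }
    calc <- compute_oar(family, rep(1, m), basis, prof$depth, geometry)
    tmat[, j] <- calc$values / prof$values[idx]
  }
  if (per_depth) {
    w <- 1 / tmat
    w[1L, ] <- 1
    rownames(w) <- format(family$r0)
    colnames(w) <- vapply(measured, function(p) format(p$depth), character(1))
    return(w)
  }
  w <- rowSums(tmat) / rowSums(tmat^2)
  w[1L] <- 1
  w
}
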