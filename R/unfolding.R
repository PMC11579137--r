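#' Unfolding configuration
#'
#' Collects the free choices of the spectral unfolding: fit window and
#' normalization depth, sequential versus joint treatment of the radii,
#' the candidate peak bins scanned for the fluence maximum, and numerical
#' tolerances.
#'
#' Each candidate-peak subproblem is reparametrized into a convex quadratic
#' program and solved exactly (see the package vignette), so the unfolding
#' is deterministic: no random starts are involved and `seed` only matters
#' to downstream synthetic-data helpers that may share a config.
#'
#' @param fit_window Depth interval `c(lo, hi)` in cm over which the
#'   objective is evaluated (default 2 to 25 cm: beyond the dose maximum,
#'   excluding the buildup region).
#' @param norm_depth PDD normalization depth in cm (default 10).
#' @param mode `"sequential"` (default): solve center to edge, each
#'   solution constraining the next radius; `"joint"`: refine all radii
#'   together under the full softening chain by block-coordinate descent.
#' @param scale `"profiled"` (default) treats the overall curve scale as a
#'   nuisance parameter during the fit and renormalizes the reconstruction
#'   afterwards — the measured value at the normalization depth is a noisy
#'   sample like any other, and pinning the fit to it would convert its
#'   noise into a spectral bias; `"pinned"` enforces the normalization-depth
#'   equality inside the optimization (the exact variance-of-relative-
#'   difference minimizer for d10-normalized curves).
#' @param peak_scan Candidate peak bin indices (1-based). Default `NULL`
#'   means: all bins from the one containing 0.5 MeV upward.
#' @param tol_objective Relative objective-decrease tolerance that stops
#'   the joint-mode sweeps (default 1e-8).
#' @param tol_feasibility Slack allowed when verifying constraints on a
#'   returned solution (default 1e-8).
#' @param max_sweeps Maximum block-coordinate sweeps in joint mode
#'   (default 50).
#' @param seed Optional integer recorded in the provenance snapshot.
#' @return Object of class `unfold_config`.
#' @export
unfold_config <- function(fit_window = c(2, 25), norm_depth = 10,
                          mode = c("sequential", "joint"),
                          scale = c("profiled", "pinned"),
                          peak_scan = NULL,
                          tol_objective = 1e-8, tol_feasibility = 1e-8,
                          max_sweeps = 50L, seed = NULL) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  if (length(fit_window) != 2L || fit_window[1L] >= fit_window[2L]) {
    stop("fit_window must be an increasing depth interval", call. = FALSE)
  }
  if (tol_objective <= 0 || tol_feasibility <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  if (!is.null(peak_scan) && length(peak_scan) == 0L) {
    stop("peak_scan must be non-empty", call. = FALSE)
  }
  structure(list(fit_window = fit_window, norm_depth = norm_depth,
                 mode = mode, scale = scale, peak_scan = peak_scan,
                 tol_objective = tol_objective,
                 tol_feasibility = tol_feasibility,
                 max_sweeps = as.integer(max_sweeps), seed = seed),
            class = "unfold_config")
}

default_peak_scan <- function(binning, from_energy = 0.5) {
  first <- findInterval(from_energy, binning$edges, rightmost.closed = TRUE)
  first <- min(max(first, 1L), binning$n)
  seq.int(first, binning$n)
}

#' Linear constraint set for one unfolding subproblem
#'
#' Builds the constraints of the candidate-peak subproblem in relative
#' fluence space: the probability simplex (`p >= 0`, `sum(p) = 1`),
#' unimodality about `peak_index`, and — when an inner-radius spectrum is
#' supplied — the pairwise softening ordering (fluence at the current,
#' outer, radius must dominate the inner spectrum below the peak and be
#' dominated by it above the peak). All constraints are linear;
#' inequalities are encoded as rows of `A %*% p <= b`.
#'
#' @param n_bins Number of energy bins.
#' @param peak_index Candidate peak bin (1-based).
#' @param inner_spectrum Optional [spectrum()] at the adjacent inner
#'   radius, or a bare fluence vector.
#' @param outer_spectrum Optional spectrum at the adjacent outer radius
#'   (used by the joint mode); ordering reversed relative to
#'   `inner_spectrum`.
#' @return Object of class `unfold_constraints`: list with `A`, `b`
#'   (inequalities), `n`, `peak`.
#' @export
build_constraints <- function(n_bins, peak_index, inner_spectrum = NULL,
                              outer_spectrum = NULL) {
  if (peak_index < 1L || peak_index > n_bins) {
    stop("peak_index out of range", call. = FALSE)
  }
  rows <- list(); rhs <- numeric(0)
  unit <- function(i) { e <- numeric(n_bins); e[i] <- 1; e }
  # unimodality: p_{i} - p_{i+1} <= 0 below the peak, >= 0 at and above it
  if (peak_index > 1L) {
    for (i in seq_len(peak_index - 1L)) {
      rows[[length(rows) + 1L]] <- unit(i) - unit(i + 1L); rhs <- c(rhs, 0)
    }
  }
  if (peak_index < n_bins) {
    for (i in peak_index:(n_bins - 1L)) {
      rows[[length(rows) + 1L]] <- unit(i + 1L) - unit(i); rhs <- c(rhs, 0)
    }
  }
  add_ordering <- function(ref_p, sign) {
    # sign = +1: current dominates ref below peak, is dominated above
    for (i in seq_len(n_bins)) {
      if (i < peak_index) {
        rows[[length(rows) + 1L]] <<- -sign * unit(i)
        rhs <<- c(rhs, -sign * ref_p[i])
      } else if (i > peak_index) {
        rows[[length(rows) + 1L]] <<- sign * unit(i)
        rhs <<- c(rhs, sign * ref_p[i])
      }
    }
  }
  if (!is.null(inner_spectrum)) {
    ip <- if (inherits(inner_spectrum, "spectrum")) inner_spectrum$p
          else as.numeric(inner_spectrum)
    if (length(ip) != n_bins) stop("inner spectrum length mismatch",
                                   call. = FALSE)
    add_ordering(ip, +1)
  }
  if (!is.null(outer_spectrum)) {
    op <- if (inherits(outer_spectrum, "spectrum")) outer_spectrum$p
          else as.numeric(outer_spectrum)
    if (length(op) != n_bins) stop("outer spectrum length mismatch",
                                   call. = FALSE)
    add_ordering(op, -1)
  }
  A <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0, n_bins)
  structure(list(A = A, b = rhs, n = n_bins, peak = peak_index),
            class = "unfold_constraints")
}

#' Evaluate an unfolding constraint set at a fluence vector
#'
#' @param constraints An [build_constraints()] result.
#' @param p Fluence vector.
#' @param tol Feasibility slack.
#' @return `TRUE` iff `p` is on the simplex and satisfies every inequality
#'   within `tol`.
#' @export
constraints_satisfied <- function(constraints, p, tol = 1e-8) {
  p <- if (inherits(p, "spectrum")) p$p else as.numeric(p)
  if (any(p < -tol) || abs(sum(p) - 1) > tol) return(FALSE)
  if (nrow(constraints$A) == 0L) return(TRUE)
  all(constraints$A %*% p - constraints$b <= tol)
}

# --- core QP ----------------------------------------------------------------
#
# The objective sigma^2(p) is a ratio of linear forms in p (the PDD is
# renormalized at d10 by sum_i p_i D_i(d10)). Substituting
#     q = p / sum_i p_i D_i(d10)
# fixes the denominator: the reconstructed PDD becomes 100 * (D q)_j,
# linear in q, so sigma^2 is an exact linear least squares in q. Every
# linear constraint a.p <= b maps to the homogeneous (a - b * 1).q <= 0
# because p = q / sum(q) and sum(q) > 0; the simplex equality sum(p) = 1
# holds automatically and is replaced by c10.q = 1 with c10 = D(d10).
# The subproblem is therefore a convex QP with a unique solution.

solve_peak_qp <- function(Cmat, cons, c10, scale = c("profiled", "pinned"),
                          ridge = 1e-9) {
  scale <- match.arg(scale)
  n <- cons$n
  # map p-space inequalities a.p <= b to homogeneous q-space rows
  Aq <- if (nrow(cons$A) > 0L) cons$A - outer(cons$b, rep(1, n))
        else matrix(0, 0, n)
  # column equilibration (exact reparametrization y = s * q), then a
  # vanishing Tikhonov ridge: the mono-energy curves are nearly collinear,
  # so the Gram matrix is numerically rank-deficient; the ridge (1e-9 on a
  # unit diagonal) makes the factorization well-posed while leaving the
  # achieved objective unchanged to well below solver tolerance.
  s <- sqrt(colSums(Cmat^2))
  s[s == 0] <- 1
  Cs <- sweep(Cmat, 2L, s, "/")
  G <- crossprod(Cs)
  dvec <- as.numeric(crossprod(Cs, rep(1, nrow(Cmat))))
  # solve.QP: min 1/2 y'Dy - d'y, s.t. t(Amat) y >= bvec, first meq equalities
  if (scale == "pinned") {
    # hard d10 normalization: c10.q = 1
    Amat <- t(rbind(c10 / s, -sweep(Aq, 2L, s, "/"), diag(n)))
    bvec <- c(1, rep(0, nrow(Aq)), rep(0, n))
    meq <- 1L
  } else {
    # overall scale treated as a nuisance (profiled out by leaving the
    # homogeneous q free); the reconstruction is renormalized afterwards
    Amat <- t(rbind(-sweep(Aq, 2L, s, "/"), diag(n)))
    bvec <- rep(0, nrow(Aq) + n)
    meq <- 0L
  }
  # unit-normalize constraint rows (columns of Amat): the active-set solver
  # is sensitive to badly scaled constraints after column equilibration
  rn <- sqrt(colSums(Amat^2))
  rn[rn == 0] <- 1
  Amat <- sweep(Amat, 2L, rn, "/")
  bvec <- bvec / rn
  # escalate the ridge if the factorization/active-set stage fails; the
  # objective is flat along the null directions, so a slightly larger ridge
  # changes which near-minimizer is returned, not the achieved fit
  sol <- NULL
  for (lam in ridge * c(1, 100, 1e4)) {
    Dl <- G + diag(lam * mean(diag(G)), n)
    sol <- tryCatch(quadprog::solve.QP(Dl, dvec, Amat, bvec, meq = meq),
                    error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol)) return(NULL)
  q <- sol$solution / s
  q[q < 0] <- 0
  if (anyNA(q) || sum(q) <= 0) return(NULL)
  q / sum(q)
}

# prepare the least-squares design for one fan line: row j is
# 100 * D(E_i, d_j) / M_j, target 1; plus the d10 column c10
unfold_design <- function(measured, fanline_mdds, config) {
  meas <- resample_curve(measured, fanline_mdds$depths[
    fanline_mdds$depths >= min(measured$depths) - 1e-9 &
    fanline_mdds$depths <= max(measured$depths) + 1e-9])
  idx <- window_indices(meas$depths, config$fit_window)
  if (length(idx) == 0L) {
    stop("measured curve does not cover the fit window", call. = FALSE)
  }
  didx <- match(round(meas$depths[idx], 9), round(fanline_mdds$depths, 9))
  D <- fanline_mdds$dose[didx, , drop = FALSE]
  M <- meas$values[idx]
  c10 <- vapply(seq_along(fanline_mdds$energies), function(i)
    stats::approx(fanline_mdds$depths, fanline_mdds$dose[, i],
                  xout = config$norm_depth)$y, numeric(1))
  if (anyNA(c10) || any(c10 <= 0)) {
    stop("MDD basis is not positive at the normalization depth", call. = FALSE)
  }
  list(C = 100 * D / M, meas = meas, c10 = c10)
}

#' Unfold the spectrum of one fan line
#'
#' Estimates the relative fluences \eqn{p_i} that minimize the variance
#' \eqn{\sigma^2} of the relative difference between the reconstructed and
#' measured PDD, subject to the simplex, unimodality about a scanned peak
#' bin, and (optionally) the softening ordering against an inner-radius
#' spectrum. Each candidate peak yields a convex QP solved exactly; the
#' feasible candidate with the smallest \eqn{\sigma^2} wins, ties going to
#' the lower peak index.
#'
#' @param measured A [depth_dose_curve()] covering the fit window.
#' @param fanline_mdds Per-energy curves from [resample_to_fanline()].
#' @param config An [unfold_config()].
#' @param inner_spectrum Optional [spectrum()] at the adjacent inner radius.
#' @return List with `spectrum` ([spectrum()] at the fan line's `r0`),
#'   `sigma2` (evaluated, not predicted), `peak_index`, `max_abs_delta`,
#'   `converged`, and `scanned` (per-candidate diagnostics).
#' @export
unfold_single <- function(measured, fanline_mdds, config = unfold_config(),
                          inner_spectrum = NULL) {
  stopifnot(inherits(measured, "depth_dose_curve"),
            inherits(fanline_mdds, "fanline_mdds"),
            inherits(config, "unfold_config"))
  n <- length(fanline_mdds$energies)
  binning <- fanline_mdds$binning
  if (is.null(binning)) binning <- binning_from_energies(fanline_mdds$energies)
  ssd <- if (is.null(fanline_mdds$ssd)) 100 else fanline_mdds$ssd
  if (n == 1L) {
    s <- spectrum(1, binning, r0 = fanline_mdds$r0, ssd = ssd)
    recon <- reconstruct_pdd(s, fanline_mdds, config$norm_depth)
    meas <- resample_curve(measured, recon$depths[
      recon$depths >= min(measured$depths) - 1e-9 &
      recon$depths <= max(measured$depths) + 1e-9])
    recon <- resample_curve(recon, meas$depths)
    s2 <- objective_sigma2(recon, meas, config$fit_window)
    return(list(spectrum = s, sigma2 = s2, peak_index = 1L,
                max_abs_delta = max(abs(relative_difference(
                  recon, meas, config$fit_window))),
                converged = TRUE, scanned = data.frame(
                  peak = 1L, sigma2 = s2, feasible = TRUE)))
  }
  peaks <- config$peak_scan
  if (is.null(peaks)) peaks <- default_peak_scan(binning)
  des <- unfold_design(measured, fanline_mdds, config)

  eval_sigma2 <- function(p) {
    s <- spectrum(p, binning, r0 = fanline_mdds$r0, ssd = ssd)
    recon <- reconstruct_pdd(s, fanline_mdds, config$norm_depth)
    recon <- resample_curve(recon, des$meas$depths)
    list(spectrum = s,
         sigma2 = objective_sigma2(recon, des$meas, config$fit_window),
         delta = relative_difference(recon, des$meas, config$fit_window))
  }

  best <- NULL
  scanned <- data.frame(peak = integer(0), sigma2 = numeric(0),
                        feasible = logical(0))
  for (k in sort(peaks)) {
    cons <- build_constraints(n, k, inner_spectrum)
    p <- solve_peak_qp(des$C, cons, des$c10, scale = config$scale)
    feasible <- !is.null(p) && constraints_satisfied(cons, p,
                                                     config$tol_feasibility)
    s2 <- NA_real_
    if (feasible) {
      ev <- eval_sigma2(p)
      s2 <- ev$sigma2
      if (is.null(best) || s2 < best$sigma2 - 1e-15) {
        best <- list(spectrum = ev$spectrum, sigma2 = s2, peak_index = k,
                     max_abs_delta = max(abs(ev$delta)), converged = TRUE)
      }
    }
    scanned <- rbind(scanned, data.frame(peak = k, sigma2 = s2,
                                         feasible = feasible))
  }
  if (is.null(best)) {
    stop("infeasible: no scanned peak index admits a spectrum satisfying ",
         "the unimodality/softening constraints",
         if (!is.null(inner_spectrum))
           " (the inner-radius spectrum may contradict the measured curve)",
         call. = FALSE)
  }
  best$scanned <- scanned
  best
}

#' Unfold a whole beam: spectra at every measured radius
#'
#' Runs the per-radius unfolding over a set of measured PDD curves at
#' strictly increasing radial distances. In `"sequential"` mode (the
#' default) radii are solved center to edge and each solution becomes the
#' softening bound of the next radius, which enforces the full ordering
#' chain transitively. In `"joint"` mode the sequential solution is then
#' refined by block-coordinate descent: each radius is re-solved under
#' constraints from both neighbours (peak indices held fixed) until the
#' summed objective stops decreasing.
#'
#' @param measured List of [depth_dose_curve()] objects, `r0` strictly
#'   increasing (first typically 0).
#' @param basis An [mdd_basis()].
#' @param geometry A [beam_geometry()]; defaults to the basis geometry.
#' @param config An [unfold_config()].
#' @return Object of class `unfold_result`: list with `family`
#'   ([spectrum_family()]), `per_radius` (data frame: `r0`, `sigma2`,
#'   `peak_index`, `iterations`, `converged`, `max_abs_delta`), and
#'   `provenance` (config snapshot plus input digests).
#' @export
unfold_family <- function(measured, basis, geometry = basis$geometry,
                          config = unfold_config()) {
  stopifnot(inherits(basis, "mdd_basis"), inherits(config, "unfold_config"))
  if (length(measured) < 1L) stop("need at least one measured curve",
                                  call. = FALSE)
  r0s <- vapply(measured, function(cu) cu$r0, numeric(1))
  if (any(diff(r0s) <= 0)) {
    stop("measured curves must come in strictly increasing r0 order",
         call. = FALSE)
  }
  fls <- lapply(r0s, function(r) resample_to_fanline(basis, r, geometry))

  inner <- NULL
  fits <- vector("list", length(measured))
  for (k in seq_along(measured)) {
    fits[[k]] <- tryCatch(
      unfold_single(measured[[k]], fls[[k]], config, inner_spectrum = inner),
      error = function(e) stop("radius r0 = ", r0s[k], " cm: ",
                               conditionMessage(e), call. = FALSE)
    )
    inner <- fits[[k]]$spectrum
  }
  sweeps <- 1L

  if (config$mode == "joint" && length(measured) > 1L) {
    designs <- lapply(seq_along(measured), function(k)
      unfold_design(measured[[k]], fls[[k]], config))
    peaks <- vapply(fits, function(f) f$peak_index, integer(1))
    total <- sum(vapply(fits, function(f) f$sigma2, numeric(1)))
    for (sw in seq_len(config$max_sweeps)) {
      for (k in seq_along(fits)) {
        cons <- build_constraints(
          length(basis$energies), peaks[k],
          inner_spectrum = if (k > 1L) fits[[k - 1L]]$spectrum,
          outer_spectrum = if (k < length(fits)) fits[[k + 1L]]$spectrum)
        p <- solve_peak_qp(designs[[k]]$C, cons, designs[[k]]$c10,
                           scale = config$scale)
        if (!is.null(p) && constraints_satisfied(cons, p,
                                                 config$tol_feasibility)) {
          s <- spectrum(p, fits[[k]]$spectrum$binning, r0 = r0s[k],
                        ssd = geometry$ssd)
          recon <- reconstruct_pdd(s, fls[[k]], config$norm_depth)
          recon <- resample_curve(recon, designs[[k]]$meas$depths)
          s2 <- objective_sigma2(recon, designs[[k]]$meas, config$fit_window)
          if (s2 <= fits[[k]]$sigma2 + 1e-15) {
            fits[[k]]$spectrum <- s
            fits[[k]]$sigma2 <- s2
            fits[[k]]$max_abs_delta <- max(abs(relative_difference(
              recon, designs[[k]]$meas, config$fit_window)))
          }
        }
      }
      sweeps <- sweeps + 1L
      new_total <- sum(vapply(fits, function(f) f$sigma2, numeric(1)))
      if (total - new_total <= config$tol_objective * max(total, 1e-300)) {
        total <- new_total
        break
      }
      total <- new_total
    }
  }

  family <- spectrum_family(lapply(fits, function(f) f$spectrum))
  per_radius <- data.frame(
    r0 = r0s,
    sigma2 = vapply(fits, function(f) f$sigma2, numeric(1)),
    peak_index = vapply(fits, function(f) f$peak_index, integer(1)),
    iterations = sweeps,
    converged = vapply(fits, function(f) f$converged, logical(1)),
    max_abs_delta = vapply(fits, function(f) f$max_abs_delta, numeric(1))
  )
  structure(list(
    family = family,
    per_radius = per_radius,
    provenance = list(
      config = unclass(config),
      n_curves = length(measured),
      basis_dim = dim(basis$dose),
      basis_checksum = signif(sum(basis$dose), 12),
      measured_checksum = signif(sum(vapply(measured,
        function(cu) sum(cu$values), numeric(1))), 12)
    )
  ), class = "unfold_result")
}

#' @export
print.unfold_result <- function(x, ...) {
  cat("Unfolded spectrum family\n")
  print(x$per_radius, row.names = FALSE)
  invisible(x)
}
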