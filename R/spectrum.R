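#' Discrete relative-fluence spectrum
#'
#' A spectrum is the vector of relative photon fluences \eqn{p_i} on an
#' energy binning, normalized so that \eqn{\sum_i p_i = 1}, tagged with the
#' radial distance \eqn{r_0} (cm, on the phantom surface / SSD plane) and the
#' off-axis angle \eqn{\theta = \arctan(r_0/\mathrm{SSD})} it belongs to.
#' Spectra are dimensionless relative quantities: no absolute fluence
#' calibration is carried anywhere, because depth-dose and off-axis ratios
#' are themselves ratios.
#'
#' @param p Numeric vector of non-negative relative fluences, one per bin.
#' @param binning An [energy_binning()].
#' @param r0 Radial distance on the SSD plane in cm (default 0, central axis).
#' @param ssd Source-surface distance in cm used to derive the off-axis
#'   angle (default 100).
#' @param normalize If `TRUE` (default), `p` is rescaled to sum to one;
#'   if `FALSE`, a sum differing from 1 by more than `1e-9` is an error.
#' @return An object of class `spectrum`: list with `p`, `binning`, `r0`,
#'   `theta` (degrees).
#' @export
#' @examples
#' s <- spectrum(rep(1, 13) / 13, default_binning())
#' mean_energy(s)
spectrum <- function(p, binning, r0 = 0, ssd = 100, normalize = TRUE) {
  stopifnot(inherits(binning, "energy_binning"))
  p <- as.numeric(p)
  if (length(p) != binning$n) {
    stop("invalid spectrum: length(p) = ", length(p),
         " does not match the binning (n = ", binning$n, ")", call. = FALSE)
  }
  if (anyNA(p) || any(p < 0)) {
    stop("invalid spectrum: p must be non-negative and free of NA",
         call. = FALSE)
  }
  s <- sum(p)
  if (s <= 0) {
    stop("degenerate spectrum: all relative fluences are zero", call. = FALSE)
  }
  if (normalize) {
    p <- p / s
  } else if (abs(s - 1) > 1e-9) {
    stop("invalid spectrum: sum(p) = ", format(s),
         " differs from 1 by more than 1e-9", call. = FALSE)
  }
  if (r0 < 0) stop("r0 must be non-negative", call. = FALSE)
  structure(
    list(p = p, binning = binning, r0 = r0,
         theta = off_axis_angle(r0, ssd)),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("Spectrum at r0 = %g cm (theta = %.3g deg), %d bins, mean energy %.3f MeV\n",
              x$r0, x$theta, x$binning$n, mean_energy(x)))
  invisible(x)
}

#' Energy fluence from relative fluence
#'
#' Converts a spectrum's relative fluences to per-bin energy fluences
#' \eqn{\Psi_i = p_i E_i}, the form used by TERMA-based convolution dose
#' engines and by the tabular spectrum interchange format.
#'
#' @param spectrum A [spectrum()].
#' @return Numeric vector \eqn{\Psi_i} (MeV, relative), length `n`.
#' @seealso [p_from_psi()] for the inverse.
#' @export
psi_from_p <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum"))
  spectrum$p * spectrum$binning$mid
}

#' Relative fluence from energy fluence
#'
#' Inverts [psi_from_p()]: given per-bin energy fluences \eqn{\Psi_i},
#' recovers relative fluences \eqn{p_i \propto \Psi_i / E_i}, renormalized
#' to sum to one. This is how tabulated energy-fluence spectra are ingested.
#'
#' @param psi Numeric vector of non-negative energy fluences, length `n`.
#' @param binning An [energy_binning()].
#' @inheritParams spectrum
#' @return A [spectrum()].
#' @export
p_from_psi <- function(psi, binning, r0 = 0, ssd = 100) {
  stopifnot(inherits(binning, "energy_binning"))
  psi <- as.numeric(psi)
  if (length(psi) != binning$n) {
    stop("invalid spectrum: length(psi) does not match the binning",
         call. = FALSE)
  }
  if (anyNA(psi) || any(psi < 0)) {
    stop("psi must be non-negative and free of NA", call. = FALSE)
  }
  if (sum(psi) <= 0) {
    stop("degenerate spectrum: all energy fluences are zero", call. = FALSE)
  }
  spectrum(psi / binning$mid, binning, r0 = r0, ssd = ssd)
}

#' Mean energy of a spectrum
#'
#' \eqn{\bar E = \sum_i \Psi_i = \sum_i p_i E_i} (the division by
#' \eqn{\sum_i p_i} is a no-op because spectra are normalized).
#'
#' @param spectrum A [spectrum()].
#' @return Mean energy in MeV.
#' @export
mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum"))
  sum(spectrum$p * spectrum$binning$mid)
}

#' Rebin a spectrum onto a different energy binning
#'
#' Redistributes relative fluence proportionally to bin-overlap width,
#' treating fluence as a piecewise-constant density \eqn{p_i/\Delta E_i}
#' inside each source bin. Total fluence is conserved exactly, after which
#' the result is renormalized (a pure renormalization when the target covers
#' the source support).
#'
#' @param spectrum A [spectrum()].
#' @param target An [energy_binning()] overlapping the source support.
#' @return A [spectrum()] on `target` with the same `r0`.
#' @export
rebin <- function(spectrum, target) {
  stopifnot(inherits(spectrum, "spectrum"), inherits(target, "energy_binning"))
  src <- spectrum$binning
  # overlap(i, j) = length of [src bin i] \cap [target bin j]
  lo <- pmax(matrix(src$edges[-(src$n + 1L)], src$n, target$n),
             matrix(target$edges[-(target$n + 1L)], src$n, target$n, byrow = TRUE))
  hi <- pmin(matrix(src$edges[-1L], src$n, target$n),
             matrix(target$edges[-1L], src$n, target$n, byrow = TRUE))
  ov <- pmax(hi - lo, 0)
  if (sum(ov) == 0) {
    stop("empty overlap: target binning does not intersect the source support",
         call. = FALSE)
  }
  dens <- spectrum$p / src$width
  p_new <- as.numeric(crossprod(ov, dens))
  if (sum(p_new) <= 0) {
    stop("empty overlap: no fluence falls inside the target binning",
         call. = FALSE)
  }
  spectrum(p_new, target, r0 = spectrum$r0,
           ssd = ssd_from_theta(spectrum$r0, spectrum$theta))
}

# recover the ssd implied by a stored (r0, theta) pair; central axis is
# angle-free so any ssd reproduces theta = 0
ssd_from_theta <- function(r0, theta) {
  if (r0 == 0 || theta == 0) return(100)
  r0 / tan(theta * pi / 180)
}

#' Test unimodality of a fluence vector about a given peak bin
#'
#' `TRUE` iff `p` is non-decreasing up to `peak_index` and non-increasing
#' after it — the shape constraint imposed on every unfolded spectrum
#' (depth dose varies only slightly within a small energy range, so without
#' it the fit can return physically unrealistic, oscillating spectra).
#'
#' @param p Numeric vector (a `spectrum` is also accepted).
#' @param peak_index Bin index of the candidate fluence maximum (1-based).
#' @param tol Slack allowed on each pairwise comparison (default 0).
#' @return Logical scalar.
#' @export
check_unimodal <- function(p, peak_index, tol = 0) {
  if (inherits(p, "spectrum")) p <- p$p
  n <- length(p)
  if (peak_index < 1L || peak_index > n) {
    stop("peak_index out of range", call. = FALSE)
  }
  up <- if (peak_index > 1L) diff(p[seq_len(peak_index)]) else numeric(0)
  down <- if (peak_index < n) diff(p[peak_index:n]) else numeric(0)
  all(up >= -tol) && all(down <= tol)
}

#' Family of spectra at increasing radial distances
#'
#' An ordered collection of [spectrum()] objects sharing one energy binning,
#' with strictly increasing `r0` — the output of unfolding depth-dose curves
#' along several fan lines of one beam.
#'
#' @param members List of [spectrum()] objects, `r0` strictly increasing.
#' @return Object of class `spectrum_family`: list with `members`, `binning`,
#'   `r0` (vector of radii).
#' @export
spectrum_family <- function(members) {
  if (length(members) == 0L) {
    stop("a spectrum family needs at least one member", call. = FALSE)
  }
  ok <- vapply(members, inherits, logical(1), what = "spectrum")
  if (!all(ok)) stop("all members must be spectrum objects", call. = FALSE)
  b <- members[[1L]]$binning
  shared <- vapply(members, function(s) same_binning(s$binning, b), logical(1))
  if (!all(shared)) {
    stop("all members must share a common energy binning", call. = FALSE)
  }
  r0 <- vapply(members, function(s) s$r0, numeric(1))
  if (any(diff(r0) <= 0)) {
    stop("member r0 values must be strictly increasing", call. = FALSE)
  }
  structure(list(members = members, binning = b, r0 = r0),
            class = "spectrum_family")
}

#' @export
print.spectrum_family <- function(x, ...) {
  cat(sprintf("Spectrum family: %d radii (%s cm), %d bins\n",
              length(x$members), paste(format(x$r0), collapse = ", "),
              x$binning$n))
  invisible(x)
}

#' @export
length.spectrum_family <- function(x) length(x$members)

family_p_matrix <- function(family) {
  vapply(family$members, function(s) s$p, numeric(family$binning$n))
}

#' Test the off-axis softening ordering of a spectrum family
#'
#' Checks the gradual-softening chain from the central axis outward: for
#' every bin below a member's peak, the relative fluence must be
#' non-decreasing with radius, and for every bin above the peak,
#' non-increasing. The comparison between adjacent members uses the outer
#' member's peak index (the convention under which the family is unfolded
#' center-to-edge).
#'
#' @param family A [spectrum_family()].
#' @param peak_indices Integer vector, one peak bin per member (1-based).
#' @param tol Slack per pairwise comparison (default 0).
#' @return Logical scalar.
#' @export
check_softening <- function(family, peak_indices, tol = 0) {
  stopifnot(inherits(family, "spectrum_family"))
  m <- length(family$members)
  if (length(peak_indices) != m) {
    stop("need exactly one peak index per family member", call. = FALSE)
  }
  if (m == 1L) return(TRUE)
  P <- family_p_matrix(family)
  n <- family$binning$n
  for (k in seq_len(m - 1L)) {
    peak <- peak_indices[k + 1L]
    below <- seq_len(n) < peak
    above <- seq_len(n) > peak
    d <- P[, k + 1L] - P[, k]
    if (any(d[below] < -tol) || any(d[above] > tol)) return(FALSE)
  }
  TRUE
}

#' Project a spectrum family onto the softening-ordered set
#'
#' Enforces the cross-radius softening ordering by a cumulative pass from
#' the central axis outward: below each member's peak the fluence is raised
#' to the running maximum over inner radii, above the peak lowered to the
#' running minimum, then each member is renormalized. On a family that
#' already satisfies [check_softening()] this is the identity.
#'
#' @inheritParams check_softening
#' @return A [spectrum_family()].
#' @export
project_softening <- function(family, peak_indices) {
  stopifnot(inherits(family, "spectrum_family"))
  m <- length(family$members)
  if (length(peak_indices) != m) {
    stop("need exactly one peak index per family member", call. = FALSE)
  }
  P <- family_p_matrix(family)
  n <- family$binning$n
  if (m > 1L) {
    for (k in 2:m) {
      peak <- peak_indices[k]
      below <- seq_len(n) < peak
      above <- seq_len(n) > peak
      P[below, k] <- pmax(P[below, k], P[below, k - 1L])
      P[above, k] <- pmin(P[above, k], P[above, k - 1L])
    }
  }
  members <- lapply(seq_len(m), function(k) {
    s <- family$members[[k]]
    spectrum(P[, k], family$binning, r0 = s$r0,
             ssd = ssd_from_theta(s$r0, s$theta))
  })
  spectrum_family(members)
}

#' Index of the fluence maximum
#'
#' @param spectrum A [spectrum()] or bare numeric vector.
#' @return 1-based index of the largest relative fluence (first on ties).
#' @export
find_peak <- function(spectrum) {
  p <- if (inherits(spectrum, "spectrum")) spectrum$p else as.numeric(spectrum)
  which.max(p)
}
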