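#' Beam and scoring-grid geometry
#'
#' Bundles the irradiation geometry (source-surface distance, square field
#' side at the SSD plane) with the cylindrical grid on which the
#' monoenergetic depth doses are scored: discrete radial positions
#' (central axis represented as radius 0, annuli by representative radii)
#' and uniformly spaced depths measured parallel to the central axis.
#'
#' Defaults reproduce the standard 6 MV commissioning setup: SSD 100 cm,
#' 40 cm x 40 cm field, radii 0 and 1.5 to 21.5 cm in 1 cm steps, depths
#' 0.2 to 25 cm in 2 mm steps (depth bins represented by their outer edge).
#'
#' @param ssd Source-surface distance (cm), > 0.
#' @param field_side Square field side at the SSD plane (cm), > 0.
#' @param radial_grid Radial scoring positions (cm), sorted ascending,
#'   first element 0.
#' @param depth_grid Depth positions (cm), sorted ascending, uniform spacing.
#' @param extrapolation How to evaluate fan-line radii beyond the outermost
#'   scored radius: `"clamp"` (default: hold the outermost column, warn) or
#'   `"linear"` (extrapolate from the outer two columns).
#' @return Object of class `beam_geometry`.
#' @export
beam_geometry <- function(ssd = 100,
                          field_side = 40,
                          radial_grid = c(0, seq(1.5, 21.5, by = 1)),
                          depth_grid = seq(0.2, 25, by = 0.2),
                          extrapolation = c("clamp", "linear")) {
  extrapolation <- match.arg(extrapolation)
  if (ssd <= 0) stop("ssd must be positive", call. = FALSE)
  if (field_side <= 0) stop("field_side must be positive", call. = FALSE)
  radial_grid <- as.numeric(radial_grid)
  depth_grid <- as.numeric(depth_grid)
  if (radial_grid[1L] != 0 || any(diff(radial_grid) <= 0)) {
    stop("radial_grid must start at 0 and increase strictly", call. = FALSE)
  }
  if (any(diff(depth_grid) <= 0)) {
    stop("depth_grid must be strictly increasing", call. = FALSE)
  }
  if (length(depth_grid) > 1L &&
      max(abs(diff(depth_grid) - diff(depth_grid)[1L])) > 1e-9) {
    stop("depth_grid spacing must be uniform", call. = FALSE)
  }
  structure(list(ssd = ssd, field_side = field_side,
                 radial_grid = radial_grid, depth_grid = depth_grid,
                 extrapolation = extrapolation),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("Beam geometry: SSD %g cm, field %g x %g cm, %d radii (0-%g cm), %d depths (%g-%g cm)\n",
              x$ssd, x$field_side, x$field_side, length(x$radial_grid),
              max(x$radial_grid), length(x$depth_grid),
              min(x$depth_grid), max(x$depth_grid)))
  invisible(x)
}

#' Off-axis angle of a fan line
#'
#' Angle between the central axis and the ray from the source through the
#' point at radial distance `r0` on the SSD plane:
#' \eqn{\theta = \arctan(r_0/\mathrm{SSD})}.
#'
#' @param r0 Radial distance on the SSD plane (cm), >= 0.
#' @param ssd Source-surface distance (cm), > 0.
#' @return Angle in degrees.
#' @export
#' @examples
#' off_axis_angle(18, 100)  # 10.2 degrees
off_axis_angle <- function(r0, ssd) {
  if (any(ssd <= 0)) stop("ssd must be positive", call. = FALSE)
  if (any(r0 < 0)) stop("r0 must be non-negative", call. = FALSE)
  atan(r0 / ssd) * 180 / pi
}

#' Radial distance of a fan line at depth
#'
#' A fan line through `r0` on the surface diverges from the source; at
#' depth `d` (measured parallel to the central axis) it crosses radius
#' \eqn{r(d) = (r_0/\mathrm{SSD}) (\mathrm{SSD} + d)}.
#'
#' @inheritParams off_axis_angle
#' @param d Depth parallel to the central axis (cm), >= 0.
#' @return Radius at depth `d` in cm.
#' @export
fanline_radius <- function(r0, ssd, d) {
  if (any(ssd <= 0)) stop("ssd must be positive", call. = FALSE)
  if (any(d < 0)) stop("d must be non-negative", call. = FALSE)
  (r0 / ssd) * (ssd + d)
}

#' Equal-area circular field radius
#'
#' Radius of the circle with the same area as a square field of the given
#' side (the cylindrical scoring geometry uses the equivalent circular
#' field; a 40 cm side maps to 22.568 cm).
#'
#' @param field_side Square field side (cm), > 0.
#' @return Radius in cm.
#' @export
equivalent_circle_radius <- function(field_side) {
  if (any(field_side <= 0)) stop("field_side must be positive", call. = FALSE)
  sqrt(field_side^2 / pi)
}

#' Resample an MDD basis onto a fan line
#'
#' For one fan line through `r0`, evaluates every monoenergetic depth-dose
#' column of the cylindrical basis along the divergent ray: at each depth
#' `d` of the depth grid, the basis is linearly interpolated in radius at
#' [fanline_radius()] `r(d)`. Depths stay parallel to the central axis.
#' At `r0 = 0` the central-axis column is returned unchanged.
#'
#' Fan-line radii beyond the outermost scored radius are handled per the
#' geometry's `extrapolation` setting; under `"clamp"` a warning reports
#' how many depth nodes were clamped and the result carries the count in
#' attribute `n_clamped`.
#'
#' @param basis An [mdd_basis()].
#' @param r0 Radial distance of the fan line on the SSD plane (cm), >= 0.
#' @param geometry A [beam_geometry()]; defaults to the basis geometry.
#' @return Object of class `fanline_mdds`: list with `depths`, `energies`,
#'   `dose` (matrix, depths x energies), `r0`, `theta`.
#' @export
resample_to_fanline <- function(basis, r0, geometry = basis$geometry) {
  stopifnot(inherits(basis, "mdd_basis"))
  if (r0 < 0) stop("r0 must be non-negative", call. = FALSE)
  rg <- geometry$radial_grid
  dg <- geometry$depth_grid
  ne <- length(basis$energies)
  rd <- fanline_radius(r0, geometry$ssd, dg)
  n_clamped <- sum(rd > max(rg))

  if (r0 == 0) {
    dose <- t(basis$dose[, 1L, , drop = TRUE])
    if (ne == 1L) dose <- matrix(basis$dose[1L, 1L, ], ncol = 1L)
  } else {
    # per-depth linear interpolation in radius; rd is increasing with depth
    idx <- findInterval(rd, rg, rightmost.closed = FALSE, all.inside = TRUE)
    frac <- (rd - rg[idx]) / (rg[idx + 1L] - rg[idx])
    if (geometry$extrapolation == "clamp") {
      frac <- pmin(pmax(frac, 0), 1)
      if (n_clamped > 0) {
        warning(sprintf(
          "fan line r0 = %g cm leaves the scored region beyond %g cm radius at %d depth node(s); outermost column clamped",
          r0, max(rg), n_clamped), call. = FALSE)
      }
    }
    dose <- matrix(0, length(dg), ne)
    for (i in seq_len(ne)) {
      Di <- basis$dose[i, , ]  # radius x depth
      lo <- Di[cbind(idx, seq_along(dg))]
      hi <- Di[cbind(idx + 1L, seq_along(dg))]
      dose[, i] <- (1 - frac) * lo + frac * hi
    }
  }
  structure(list(depths = dg, energies = basis$energies, dose = dose,
                 r0 = r0, theta = off_axis_angle(r0, geometry$ssd),
                 ssd = geometry$ssd, binning = basis$binning,
                 n_clamped = n_clamped),
            class = "fanline_mdds")
}
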