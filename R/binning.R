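#' Variable-width energy binning
#'
#' Defines the discretization of the photon energy axis used throughout the
#' package: `n` contiguous bins with strictly increasing boundary energies.
#' Each bin is represented by its mid-energy \eqn{E_i} (the energy at which
#' the monoenergetic depth dose is evaluated) and its width
#' \eqn{\Delta E_i}.
#'
#' @param edges Numeric vector of bin boundary energies in MeV, length
#'   `n + 1`, strictly increasing.
#' @return An object of class `energy_binning`: a list with elements
#'   `edges`, `mid` (mid-energies \eqn{E_i}), `width` (\eqn{\Delta E_i})
#'   and `n`.
#' @seealso [default_binning()] for the standard 13-bin scheme.
#' @export
#' @examples
#' b <- energy_binning(c(0.05, 0.5, 2, 7))
#' b$mid
energy_binning <- function(edges) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L) {
    stop("'edges' must contain at least two boundary energies", call. = FALSE)
  }
  if (anyNA(edges) || any(diff(edges) <= 0)) {
    stop("'edges' must be strictly increasing and free of NA", call. = FALSE)
  }
  n <- length(edges) - 1L
  structure(
    list(
      edges = edges,
      mid = (edges[-1L] + edges[-(n + 1L)]) / 2,
      width = diff(edges),
      n = n
    ),
    class = "energy_binning"
  )
}

#' Default 13-bin energy scheme for 6 MV beams
#'
#' The standard binning used for unfolding 6 MV spectra: 13 bins spanning
#' 0.05 to 7.00 MeV whose widths grow with energy, tracking the flattening
#' of the water attenuation coefficient (narrow bins where depth dose is
#' energy-sensitive, wide bins where it is not). Mid-energies are 0.100,
#' 0.200, 0.300, 0.425, 0.600, 0.850, 1.200, 1.650, 2.200, 2.875, 3.675,
#' 4.625 and 6.075 MeV.
#'
#' @return An [energy_binning()] object with `n = 13`.
#' @export
default_binning <- function() {
  energy_binning(c(0.05, 0.15, 0.25, 0.35, 0.50, 0.70, 1.00,
                   1.40, 1.90, 2.50, 3.25, 4.10, 5.15, 7.00))
}

#' @export
print.energy_binning <- function(x, ...) {
  cat("Energy binning:", x$n, "bins,",
      format(x$edges[1L]), "-", format(x$edges[x$n + 1L]), "MeV\n")
  print(data.frame(low = x$edges[-(x$n + 1L)], high = x$edges[-1L],
                   mid = x$mid, width = x$width))
  invisible(x)
}

same_binning <- function(a, b, tol = 1e-12) {
  a$n == b$n && max(abs(a$edges - b$edges)) <= tol
}

# Recover a binning from bare mid-energies (e.g. an MDD file without edge
# metadata): boundaries halfway between neighbours, end bins symmetric; the
# stated mid-energies are kept exactly.
binning_from_energies <- function(mids) {
  mids <- as.numeric(mids)
  if (length(mids) == 1L) {
    b <- energy_binning(c(mids - 0.05, mids + 0.05))
  } else {
    inner <- (mids[-length(mids)] + mids[-1L]) / 2
    b <- energy_binning(c(max(2 * mids[1L] - inner[1L], mids[1L] / 2),
                          inner,
                          2 * mids[length(mids)] - inner[length(inner)]))
  }
  b$mid <- mids
  b
}
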