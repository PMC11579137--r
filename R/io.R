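#' Write an MDD basis to long-format CSV
#'
#' One row per (energy, radius, depth) cell with columns `energy_mev`,
#' `r0_cm`, `depth_cm`, `dose_per_fluence`, `sd_percent`. This long CSV is
#' the package's native rendering of published MDD spreadsheets (which
#' typically tabulate one depth-dose block per energy and radius: map each
#' block cell to one row, carrying its energy and radius labels).
#'
#' @param basis An [mdd_basis()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mdd_basis <- function(basis, path) {
  stopifnot(inherits(basis, "mdd_basis"))
  g <- basis$geometry
  grid <- expand.grid(depth_cm = g$depth_grid, r0_cm = g$radial_grid,
                      energy_mev = basis$energies,
                      KEEP.OUT.ATTRS = FALSE)
  dose <- aperm(basis$dose, c(3L, 2L, 1L))  # depth, radius, energy
  sdp <- if (is.null(basis$sd_percent)) NA_real_
         else as.numeric(aperm(basis$sd_percent, c(3L, 2L, 1L)))
  out <- data.frame(energy_mev = grid$energy_mev, r0_cm = grid$r0_cm,
                    depth_cm = grid$depth_cm,
                    dose_per_fluence = as.numeric(dose),
                    sd_percent = sdp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an MDD basis from long-format CSV
#'
#' Inverse of [write_mdd_basis()]: grids are inferred from the distinct
#' energies, radii and depths, and completeness of the
#' energy x radius x depth lattice is enforced.
#'
#' @param path CSV file with columns `energy_mev`, `r0_cm`, `depth_cm`,
#'   `dose_per_fluence` and optionally `sd_percent`.
#' @param ssd,field_side Geometry not carried by the table (defaults 100
#'   and 40 cm).
#' @param binning Optional [energy_binning()] whose mid-energies must
#'   match the file's energies.
#' @return An [mdd_basis()].
#' @export
read_mdd_basis <- function(path, ssd = 100, field_side = 40, binning = NULL) {
  df <- utils::read.csv(path)
  need <- c("energy_mev", "r0_cm", "depth_cm", "dose_per_fluence")
  if (!all(need %in% names(df))) {
    stop("MDD CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  energies <- sort(unique(df$energy_mev))
  radii <- sort(unique(df$r0_cm))
  depths <- sort(unique(df$depth_cm))
  key <- paste(df$energy_mev, df$r0_cm, df$depth_cm)
  full <- expand.grid(depth_cm = depths, r0_cm = radii, energy_mev = energies,
                      KEEP.OUT.ATTRS = FALSE)
  full_key <- paste(full$energy_mev, full$r0_cm, full$depth_cm)
  missing <- setdiff(full_key, key)
  if (length(missing) > 0L) {
    stop("incomplete MDD grid: ", length(missing), " missing cell(s), e.g. ",
         paste(utils::head(missing, 10L), collapse = "; "), call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop("duplicated MDD grid cells in ", path, call. = FALSE)
  }
  ord <- order(match(df$energy_mev, energies), match(df$r0_cm, radii),
               match(df$depth_cm, depths))
  dose <- array(df$dose_per_fluence[ord],
                dim = c(length(depths), length(radii), length(energies)))
  dose <- aperm(dose, c(3L, 2L, 1L))
  sdp <- NULL
  if ("sd_percent" %in% names(df) && !anyNA(df$sd_percent)) {
    sdp <- aperm(array(df$sd_percent[ord],
                       dim = c(length(depths), length(radii),
                               length(energies))), c(3L, 2L, 1L))
  }
  geometry <- beam_geometry(ssd = ssd, field_side = field_side,
                            radial_grid = radii, depth_grid = depths)
  mdd_basis(energies, geometry, dose, sd_percent = sdp, binning = binning)
}

scan_header <- function(curve) {
  if (inherits(curve, "depth_dose_curve")) {
    c(kind = "pdd", r0_cm = curve$r0, norm_depth_cm = curve$norm_depth)
  } else {
    c(kind = "oar", depth_cm = curve$depth)
  }
}

#' Write a scan (PDD or OAR) to CSV
#'
#' Two data columns — `position_cm`, `value_percent` — preceded by a
#' comment-style header block (`# key: value`) declaring the curve kind
#' (`pdd` or `oar`), its `r0` or depth, SSD, field size and normalization
#' point.
#'
#' @param curve A [depth_dose_curve()] or [lateral_profile()].
#' @param path Output file path.
#' @param ssd,field_side Geometry recorded in the header.
#' @return `path`, invisibly.
#' @export
write_scan <- function(curve, path, ssd = 100, field_side = 40) {
  hdr <- c(scan_header(curve), ssd_cm = ssd, field_side_cm = field_side)
  lines <- sprintf("# %s: %s", names(hdr), vapply(hdr, format, character(1)))
  if (inherits(curve, "depth_dose_curve")) {
    pos <- curve$depths
  } else {
    pos <- curve$radii
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  writeLines("position_cm,value_percent", con)
  writeLines(sprintf("%.10g,%.10g", pos, curve$values), con)
  invisible(path)
}

#' Read a scan (PDD or OAR) from CSV
#'
#' Parses the header block written by [write_scan()] and returns the typed
#' curve with its invariants enforced. A PDD whose value at the declared
#' normalization depth is off by at most 0.5% is silently renormalized;
#' a larger deviation is an error unless `renormalize = TRUE`.
#'
#' @param path Scan CSV path.
#' @param renormalize Force renormalization regardless of the deviation.
#' @return A [depth_dose_curve()] or [lateral_profile()] per the header.
#' @export
read_scan <- function(path, renormalize = FALSE) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr_lines, regexec("^#\\s*([^:]+):\\s*(.+)$", hdr_lines))
  if (any(lengths(kv) != 3L)) stop("malformed scan header", call. = FALSE)
  hdr <- stats::setNames(vapply(kv, `[`, character(1), 3L),
                         trimws(vapply(kv, `[`, character(1), 2L)))
  if (!"kind" %in% names(hdr)) stop("scan header lacks 'kind'", call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("position_cm", "value_percent") %in% names(df))) {
    stop("scan body must have columns position_cm,value_percent",
         call. = FALSE)
  }
  ssd <- as.numeric(hdr["ssd_cm"]); if (is.na(ssd)) ssd <- 100
  if (hdr["kind"] == "pdd") {
    nd <- as.numeric(hdr["norm_depth_cm"])
    if (is.na(nd)) stop("pdd scan header lacks norm_depth_cm", call. = FALSE)
    at_norm <- stats::approx(df$position_cm, df$value_percent, xout = nd)$y
    if (!renormalize && abs(at_norm - 100) > 0.5) {
      stop("scan reads ", format(at_norm), " at its declared norm depth (",
           nd, " cm); deviation exceeds 0.5% - pass renormalize = TRUE ",
           "if this is intended", call. = FALSE)
    }
    depth_dose_curve(df$position_cm, df$value_percent,
                     r0 = as.numeric(hdr["r0_cm"]), norm_depth = nd,
                     ssd = ssd, renormalize = TRUE)
  } else if (hdr["kind"] == "oar") {
    dep <- as.numeric(hdr["depth_cm"])
    if (is.na(dep)) stop("oar scan header lacks depth_cm", call. = FALSE)
    off <- abs(df$value_percent[df$position_cm == 0][1L] - 100)
    if (!renormalize && (is.na(off) || off > 0.5)) {
      stop("oar scan central-axis value deviates from 100 by more than 0.5%",
           call. = FALSE)
    }
    lateral_profile(df$position_cm, df$value_percent, dep, renormalize = TRUE)
  } else {
    stop("unknown scan kind: ", hdr["kind"], call. = FALSE)
  }
}

#' Write a spectrum family as an energy-fluence table
#'
#' CSV mirroring the conventional presentation of unfolded spectra: first
#' column the mid-energies `energy_mev`, then one column per radius
#' labelled `"<r0> cm"`, cells the energy fluences \eqn{\Psi_i} in
#' 4-significant-figure scientific notation.
#'
#' @param family A [spectrum_family()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(family, path) {
  stopifnot(inherits(family, "spectrum_family"))
  psi <- vapply(family$members, psi_from_p, numeric(family$binning$n))
  out <- data.frame(energy_mev = sprintf("%.3f", family$binning$mid))
  for (k in seq_along(family$members)) {
    out[[sprintf("%g cm", family$r0[k])]] <- sprintf("%.3e", psi[, k])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an energy-fluence spectrum table
#'
#' Inverse of [write_spectrum_table()]: each radius column is converted
#' from energy fluence back to relative fluence via [p_from_psi()]
#' (renormalizing, since tabulated values are rounded).
#'
#' @param path Spectrum-table CSV path.
#' @param binning Optional [energy_binning()]; when omitted, a binning is
#'   recovered from the tabulated mid-energies (exact for the default
#'   13-bin scheme, midpoint-boundary otherwise).
#' @param ssd SSD used to derive off-axis angles (default 100 cm).
#' @return A [spectrum_family()].
#' @export
read_spectrum_table <- function(path, binning = NULL, ssd = 100) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "energy_mev") {
    stop("spectrum table must start with an energy_mev column", call. = FALSE)
  }
  mids <- as.numeric(df$energy_mev)
  if (is.null(binning)) {
    db <- default_binning()
    binning <- if (length(mids) == db$n && max(abs(mids - db$mid)) < 1e-9)
      db else binning_from_energies(mids)
  }
  rcols <- names(df)[-1L]
  r0 <- as.numeric(sub("\\s*cm\\s*$", "", rcols))
  if (anyNA(r0)) stop("radius columns must be labelled like '4 cm'",
                      call. = FALSE)
  ord <- order(r0)
  members <- lapply(ord, function(k)
    p_from_psi(as.numeric(df[[rcols[k]]]), binning, r0 = r0[k], ssd = ssd))
  spectrum_family(members)
}

#' Published 6 MV reference spectra
#'
#' Energy-fluence spectra of a flattened 6 MV Elekta Versa HD beam
#' (40 cm x 40 cm field, SSD 100 cm) determined by depth-dose
#' reconstruction at radial distances 0 to 18 cm in 2 cm steps, shipped
#' with the package as reference data on the default 13-bin scheme.
#'
#' @return A [spectrum_family()] (10 members, r0 = 0..18 cm).
#' @export
#' @examples
#' fam <- reference_spectra_6mv()
#' mean_energy(fam$members[[1]])
reference_spectra_6mv <- function() {
  path <- system.file("extdata", "spectra_6mv_versahd.csv",
                      package = "pddrecon", mustWork = TRUE)
  read_spectrum_table(path, binning = default_binning())
}

#' Read a run configuration file
#'
#' YAML with up to four blocks — `geometry`, `binning`, `unfold`,
#' `synthetic` — mapping onto [beam_geometry()], [energy_binning()],
#' [unfold_config()] and [synthetic_beam_spec()] arguments. Unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return List with elements `geometry`, `binning`, `unfold`,
#'   `synthetic` (each `NULL` if its block is absent).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("geometry", "binning", "unfold", "synthetic")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) {
    stop("unknown config block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  take <- function(block, fn, allowed) {
    if (is.null(cfg[[block]])) return(NULL)
    bad <- setdiff(names(cfg[[block]]), allowed)
    if (length(bad) > 0L) {
      stop("unknown key(s) in '", block, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    do.call(fn, cfg[[block]])
  }
  binning <- take("binning", energy_binning, "edges")
  geometry <- take("geometry", beam_geometry,
                   c("ssd", "field_side", "radial_grid", "depth_grid",
                     "extrapolation"))
  unfold <- take("unfold", unfold_config,
                 c("fit_window", "norm_depth", "mode", "peak_scan",
                   "tol_objective", "tol_feasibility", "max_sweeps", "seed"))
  syn_args <- cfg$synthetic
  synthetic <- NULL
  if (!is.null(syn_args)) {
    allowed <- c("radii", "softening_rate", "horn_a", "horn_b", "noise_sd",
                 "peak_energy", "peak_width", "radial_tilt", "seed")
    bad <- setdiff(names(syn_args), allowed)
    if (length(bad) > 0L) {
      stop("unknown key(s) in 'synthetic': ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(binning)) syn_args$binning <- binning
    synthetic <- do.call(synthetic_beam_spec, syn_args)
  }
  list(geometry = geometry, binning = binning, unfold = unfold,
       synthetic = synthetic)
}

#' Write the resolved configuration snapshot of a run
#'
#' @param config Named list (e.g. an `unfold_config` and friends) to
#'   snapshot.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_snapshot <- function(config, path) {
  drop_classes <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop_classes)
      attributes(x) <- list(names = names(x))
    } else if (is.function(x)) {
      x <- NULL
    }
    x
  }
  yaml::write_yaml(drop_classes(config), path)
  invisible(path)
}
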