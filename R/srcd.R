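#' Construct a CD spectrum
#'
#' Wavelength grids are canonicalized to ascending order. The unit flag is
#' always set: raw machine units (`"mdeg"`), mean residue ellipticity
#' (`"mre"`, deg cm^2 dmol^-1) or per-residue molar extinction difference
#' (`"delta_epsilon"`, M^-1 cm^-1). Conversion metadata (concentration in
#' mg/mL, path length in mm, residue count, mean residue weight) must be
#' present before unit conversion.
#'
#' @param wavelength_nm wavelength grid, nm (strictly monotone).
#' @param signal CD signal in `unit`.
#' @param unit one of `"mdeg"`, `"mre"`, `"delta_epsilon"`.
#' @param concentration_mg_ml,path_length_mm,n_residues,mrw optional
#'   conversion metadata (mean residue weight in Da).
#' @return object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength_nm, signal, unit = c("mdeg", "mre", "delta_epsilon"),
                        concentration_mg_ml = NULL, path_length_mm = NULL,
                        n_residues = NULL, mrw = NULL) {
  unit <- match.arg(unit)
  stopifnot(length(wavelength_nm) == length(signal))
  if (is.unsorted(wavelength_nm, strictly = TRUE)) {
    if (is.unsorted(rev(wavelength_nm), strictly = TRUE)) {
      stop("wavelength grid must be strictly monotone")
    }
    wavelength_nm <- rev(wavelength_nm)
    signal <- rev(signal)
  }
  structure(list(wavelength = wavelength_nm, signal = signal, unit = unit,
                 meta = list(concentration_mg_ml = concentration_mg_ml,
                             path_length_mm = path_length_mm,
                             n_residues = n_residues, mrw = mrw)),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("cd_spectrum: %d points, %g-%g nm, unit %s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$unit))
  invisible(x)
}

#' @export
plot.cd_spectrum <- function(x, ...) {
  ylab <- switch(x$unit, mdeg = "ellipticity (mdeg)",
                 mre = expression(paste("[", theta, "] (deg ", cm^2, " ", dmol^-1, ")")),
                 delta_epsilon = expression(Delta * epsilon))
  graphics::plot(x$wavelength, x$signal, type = "l",
                 xlab = "wavelength (nm)", ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Read a 2-3 column CD spectrum text file
#'
#' Columns: wavelength (nm), signal, optional error. Header and comment
#' lines (including PCDDB-flavoured metadata) are skipped.
#'
#' @param path file path.
#' @param unit unit of the signal column.
#' @param ... metadata passed to [cd_spectrum()].
#' @return a `cd_spectrum`.
#' @export
read_cd <- function(path, unit = "mdeg", ...) {
  lines <- readLines(path, warn = FALSE)
  num_re <- "^\\s*[-+]?[0-9.]+([eE][-+]?[0-9]+)?(\\s+[-+]?[0-9.]+([eE][-+]?[0-9]+)?){1,}\\s*$"
  keep <- grepl(num_re, lines)
  if (!any(keep)) stop("no numeric rows in ", path)
  tab <- utils::read.table(text = lines[keep])
  cd_spectrum(tab[[1]], tab[[2]], unit = unit, ...)
}

#' Write a CD spectrum as 2-column text
#' @param spec a `cd_spectrum`.
#' @param path output path.
#' @export
write_cd <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wavelength(nm) signal(%s)", spec$unit), con)
  writeLines(sprintf("%.6g %.10g", spec$wavelength, spec$signal), con)
  invisible(path)
}

#' Convert a raw spectrum to mean-residue units
#'
#' Mean residue ellipticity `[theta] = theta_mdeg * MRW / (10 * c * l_cm)`
#' with concentration in mg/mL and path length in cm (path metadata is
#' stored in mm and converted internally); `delta_epsilon = [theta] / 3298`.
#'
#' @param spec a `cd_spectrum` in `"mdeg"` with complete metadata.
#' @param to `"mre"` or `"delta_epsilon"`.
#' @return converted `cd_spectrum`.
#' @export
to_mean_residue_units <- function(spec, to = c("mre", "delta_epsilon")) {
  to <- match.arg(to)
  stopifnot(inherits(spec, "cd_spectrum"))
  if (spec$unit != "mdeg") stop("expected a raw spectrum in mdeg")
  m <- spec$meta
  if (is.null(m$concentration_mg_ml) || is.null(m$path_length_mm) ||
      is.null(m$mrw)) {
    stop("conversion metadata incomplete (need concentration, path length, MRW)")
  }
  if (m$concentration_mg_ml <= 0 || m$path_length_mm <= 0) {
    stop("concentration and path length must be positive")
  }
  l_cm <- m$path_length_mm / 10
  mre <- spec$signal * m$mrw / (10 * m$concentration_mg_ml * l_cm)
  out <- spec
  out$signal <- if (to == "mre") mre else mre / 3298
  out$unit <- to
  out
}

#' Convert a mean-residue spectrum back to raw mdeg
#'
#' Inverse of [to_mean_residue_units()] under the same metadata.
#'
#' @param spec a `cd_spectrum` in `"mre"` or `"delta_epsilon"`.
#' @return `cd_spectrum` in mdeg.
#' @export
from_mean_residue_units <- function(spec) {
  stopifnot(inherits(spec, "cd_spectrum"))
  if (spec$unit == "mdeg") return(spec)
  m <- spec$meta
  if (is.null(m$concentration_mg_ml) || is.null(m$path_length_mm) ||
      is.null(m$mrw)) {
    stop("conversion metadata incomplete")
  }
  mre <- if (spec$unit == "delta_epsilon") spec$signal * 3298 else spec$signal
  out <- spec
  out$signal <- mre * (10 * m$concentration_mg_ml * m$path_length_mm / 10) / m$mrw
  out$unit <- "mdeg"
  out
}

#' Spectral subtraction
#'
#' `mode = "plain"` returns `a - b` on the common wavelength range (linear
#' interpolation onto the coarser grid when the grids differ; flagged in the
#' `interpolated` attribute). `mode = "residue_weighted"` returns
#' `(n_a * a - n_b * b) / (n_a - n_b)` with `n` the residue counts, the
#' per-residue spectrum of the region present in `a` but not `b` — e.g.
#' subtracting a DNA-binding-domain spectrum (per-residue) from a
#' DBD-plus-TAD spectrum to obtain the theoretical spectrum of the
#' transactivation domain alone.
#'
#' @param a,b `cd_spectrum` objects in the same mean-residue unit.
#' @param mode `"plain"` or `"residue_weighted"`.
#' @param n_a,n_b residue counts (default from metadata).
#' @return a `cd_spectrum` of the difference.
#' @export
subtract_spectra <- function(a, b, mode = c("residue_weighted", "plain"),
                             n_a = a$meta$n_residues, n_b = b$meta$n_residues) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "cd_spectrum"), inherits(b, "cd_spectrum"))
  if (a$unit == "mdeg" || b$unit == "mdeg" || a$unit != b$unit) {
    stop("both spectra must be in the same mean-residue unit")
  }
  lo <- max(min(a$wavelength), min(b$wavelength))
  hi <- min(max(a$wavelength), max(b$wavelength))
  if (lo >= hi) stop("disjoint wavelength ranges")
  sel_a <- a$wavelength >= lo & a$wavelength <= hi
  sel_b <- b$wavelength >= lo & b$wavelength <= hi
  interpolated <- FALSE
  if (sum(sel_a) <= sum(sel_b)) {
    grid <- a$wavelength[sel_a]
    ya <- a$signal[sel_a]
    yb <- stats::approx(b$wavelength, b$signal, xout = grid)$y
    interpolated <- !isTRUE(all.equal(grid, b$wavelength[sel_b]))
  } else {
    grid <- b$wavelength[sel_b]
    yb <- b$signal[sel_b]
    ya <- stats::approx(a$wavelength, a$signal, xout = grid)$y
    interpolated <- TRUE
  }
  if (mode == "residue_weighted") {
    if (is.null(n_a) || is.null(n_b)) stop("residue counts required")
    if (n_a == n_b) stop("residue counts must differ in residue_weighted mode")
    y <- (n_a * ya - n_b * yb) / (n_a - n_b)
  } else {
    y <- ya - yb
  }
  out <- cd_spectrum(grid, y, unit = a$unit,
                     n_residues = if (mode == "residue_weighted" &&
                                      !is.null(n_a) && !is.null(n_b))
                       abs(n_a - n_b) else NULL)
  attr(out, "interpolated") <- interpolated
  attr(out, "mode") <- mode
  out
}

#' Summary table of a TFE titration series
#'
#' One row per titration point with the signal at 222 nm and 208 nm (linear
#' interpolation on the grid); the strength of the 222 nm band tracks
#' induced alpha-helix. Monotonicity of |signal at 222 nm| is reported in
#' the `monotone_222` attribute, not enforced.
#'
#' @param spectra list of `list(fraction_tfe = , spectrum = )` entries (or a
#'   named list of spectra with fractions as names).
#' @return data.frame of class `tfe_series` with columns `fraction_tfe`,
#'   `signal_222`, `signal_208`.
#' @export
tfe_series <- function(spectra) {
  if (length(spectra) == 0) stop("empty titration series")
  rows <- lapply(spectra, function(el) {
    sp <- el$spectrum
    stopifnot(inherits(sp, "cd_spectrum"))
    if (222 < min(sp$wavelength) || 222 > max(sp$wavelength)) {
      stop("222 nm outside spectral range")
    }
    s222 <- stats::approx(sp$wavelength, sp$signal, xout = 222)$y
    s208 <- if (208 >= min(sp$wavelength) && 208 <= max(sp$wavelength)) {
      stats::approx(sp$wavelength, sp$signal, xout = 208)$y
    } else NA_real_
    data.frame(fraction_tfe = el$fraction_tfe, signal_222 = s222,
               signal_208 = s208)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fraction_tfe), ]
  rownames(out) <- NULL
  attr(out, "monotone_222") <- !is.unsorted(abs(out$signal_222))
  class(out) <- c("tfe_series", "data.frame")
  out
}
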