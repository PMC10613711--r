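# Physical constants (CODATA), in the package's internal units
# (nm, ps, kJ/mol, K, bar, Da, elementary charges).
.kB <- 0.00831446261815324          # kJ mol-1 K-1
.f_coulomb <- 138.935458            # kJ mol-1 nm e-2 (1/(4 pi eps0) * NA * e^2)
.N_A <- 6.02214076e23               # mol-1
.bar_per_kJmolnm3 <- 16.6054        # 1 kJ mol-1 nm-3 in bar

#' Inverse Debye screening length of a monovalent electrolyte
#'
#' kappa = sqrt(2 N_A e^2 I / (eps0 eps_r kB T)), returned in nm^-1. At
#' physiological ionic strength (150 mM, 300 K, eps_r 78.3) this evaluates to
#' 1.27 nm^-1.
#'
#' @param ionic_strength_mM ionic strength in mM (monovalent salt).
#' @param T_K temperature in K.
#' @param eps_r relative dielectric constant of the solvent.
#' @return inverse Debye length in nm^-1; 0 for zero ionic strength.
#' @export
debye_kappa <- function(ionic_strength_mM, T_K = 300, eps_r = 78.3) {
  if (T_K <= 0) stop("temperature must be positive")
  if (eps_r <= 0) stop("relative dielectric must be positive")
  if (ionic_strength_mM < 0) stop("ionic strength must be non-negative")
  e <- 1.602176634e-19     # C
  eps0 <- 8.8541878128e-12 # F/m
  kB <- 1.380649e-23       # J/K
  I <- ionic_strength_mM * 1e-3 * 1e3 * .N_A  # ions per m^3 (mol/m^3 * N_A)
  kappa_m <- sqrt(2 * e^2 * I / (eps0 * eps_r * kB * T_K))
  kappa_m * 1e-9  # m^-1 -> nm^-1
}

#' Load coarse-grained force-field parameters
#'
#' Reads a YAML parameter file with a `global` block (bond length/stiffness,
#' pair interaction strength epsilon, relative dielectric, inverse Debye
#' length kappa, nonbonded cutoff) and a per-residue `beads` table (charge,
#' hydropathy lambda, bead diameter sigma, mass). The file shipped with the
#' package holds HPS-family defaults and can be swapped for any other
#' published one-bead-per-residue table.
#'
#' @param path YAML file; default is the packaged parameter set.
#' @return object of class `forcefield`.
#' @export
read_forcefield <- function(path = system.file("extdata", "forcefield.yaml",
                                               package = "idrsuite")) {
  raw <- yaml::read_yaml(path)
  g <- raw$global
  needed <- c("bond_b0", "bond_k", "epsilon", "eps_r", "kappa", "cutoff")
  if (!all(needed %in% names(g))) {
    stop("parameter file missing global key(s): ",
         paste(setdiff(needed, names(g)), collapse = ", "))
  }
  beads <- do.call(rbind, lapply(names(raw$beads), function(code) {
    b <- raw$beads[[code]]
    data.frame(code = code, charge = b$charge, lambda = b$lambda,
               sigma = b$sigma, mass = b$mass, stringsAsFactors = FALSE)
  }))
  ff <- forcefield(bond_b0 = g$bond_b0, bond_k = g$bond_k, epsilon = g$epsilon,
                   eps_r = g$eps_r, kappa = g$kappa, cutoff = g$cutoff,
                   beads = beads)
  attr(ff, "file") <- path
  attr(ff, "checksum") <- unname(tools::md5sum(path))
  ff
}

#' Construct force-field parameters directly
#'
#' @param bond_b0 harmonic bond length (nm).
#' @param bond_k bond stiffness (kJ mol-1 nm-2).
#' @param epsilon pair interaction strength (kJ mol-1).
#' @param eps_r relative dielectric (dimensionless).
#' @param kappa inverse Debye length (nm-1).
#' @param cutoff nonbonded cutoff (nm); must exceed the largest bead sigma.
#' @param beads data.frame with columns code, charge, lambda, sigma, mass.
#' @return object of class `forcefield`.
#' @export
forcefield <- function(bond_b0 = 0.38, bond_k = 2000, epsilon = 0.8368,
                       eps_r = 80, kappa = 1.27, cutoff = 1.5,
                       beads = read_forcefield()$beads) {
  stopifnot(kappa >= 0, bond_b0 > 0, bond_k >= 0, epsilon >= 0, eps_r > 0)
  stopifnot(all(c("code", "charge", "lambda", "sigma", "mass") %in% names(beads)))
  if (any(beads$sigma <= 0) || any(beads$mass <= 0)) {
    stop("bead sigma and mass must be positive")
  }
  if (cutoff <= max(beads$sigma)) stop("cutoff must exceed the largest bead sigma")
  if (!all(beads$charge %in% c(-1, 0, 1))) {
    stop("default charge assignment allows charges -1, 0, +1 only")
  }
  rownames(beads) <- beads$code
  structure(list(bond_b0 = bond_b0, bond_k = bond_k, epsilon = epsilon,
                 eps_r = eps_r, kappa = kappa, cutoff = cutoff, beads = beads),
            class = "forcefield")
}

#' Write force-field parameters to a YAML file
#' @param ff a [forcefield()].
#' @param path output path.
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "forcefield"))
  beads <- lapply(seq_len(nrow(ff$beads)), function(i) {
    b <- ff$beads[i, ]
    list(charge = b$charge, lambda = b$lambda, sigma = b$sigma, mass = b$mass)
  })
  names(beads) <- ff$beads$code
  yaml::write_yaml(list(
    version = 1,
    global = ff[c("bond_b0", "bond_k", "epsilon", "eps_r", "kappa", "cutoff")],
    beads = beads
  ), path)
  invisible(path)
}

#' @export
print.forcefield <- function(x, ...) {
  cat("coarse-grained forcefield: 1 bead per residue\n")
  cat(sprintf("  bond: b0 = %.3g nm, k = %.4g kJ/mol/nm^2\n", x$bond_b0, x$bond_k))
  cat(sprintf("  pair: epsilon = %.4g kJ/mol (Ashbaugh-Hatch), cutoff = %.3g nm\n",
              x$epsilon, x$cutoff))
  cat(sprintf("  electrostatics: Debye-Hueckel, eps_r = %.3g, kappa = %.3g nm^-1\n",
              x$eps_r, x$kappa))
  cat(sprintf("  bead table: %d residue types\n", nrow(x$beads)))
  invisible(x)
}

# Per-bead parameter vectors for a vector of residue codes.
bead_vectors <- function(ff, codes) {
  miss <- setdiff(unique(codes), ff$beads$code)
  if (length(miss)) stop("residue(s) missing from bead table: ",
                         paste(miss, collapse = ", "))
  b <- ff$beads[codes, ]
  list(charge = b$charge, lambda = b$lambda, sigma = b$sigma, mass = b$mass)
}
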