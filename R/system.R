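#' Construct a coarse-grained bead system
#'
#' @param pos N x 3 matrix of bead positions (nm).
#' @param chain integer vector (length N) giving the chain index of each bead;
#'   consecutive beads within a chain are bonded.
#' @param codes character vector of one-letter residue codes per bead.
#' @param box cubic box edge (nm).
#' @param sequence the chain sequence (all chains share it), a
#'   [protein_sequence()] or NULL.
#' @param vel optional N x 3 velocity matrix (nm/ps).
#' @param periodic logical; apply periodic boundary conditions.
#' @return object of class `cg_system`.
#' @export
cg_system <- function(pos, chain, codes, box, sequence = NULL, vel = NULL,
                      periodic = TRUE) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, nrow(pos) == length(chain),
            length(codes) == length(chain), box > 0)
  if (!all(is.finite(pos))) stop("positions must be finite")
  if (!is.null(vel)) {
    vel <- as.matrix(vel)
    stopifnot(all(dim(vel) == dim(pos)))
  }
  structure(list(pos = pos, chain = as.integer(chain), codes = codes,
                 box = box, sequence = sequence, vel = vel,
                 periodic = isTRUE(periodic)),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("cg_system: %d beads, %d chain(s), box edge %.3g nm (%s)\n",
              nrow(x$pos), length(unique(x$chain)), x$box,
              if (x$periodic) "periodic" else "open"))
  invisible(x)
}

n_chains <- function(system) length(unique(system$chain))

#' Build an initial multi-chain system on a regular grid
#'
#' Chain centers of mass are placed on a regular cubic grid of
#' `ceiling(n_copies^(1/3))^3` sites spanning the box; each chain is given an
#' independent random-walk initial conformation (bond length from the force
#' field) whose center of mass is moved onto its grid site. A buffer is
#' required between grid sites so neighboring random coils do not
#' interpenetrate badly before minimization.
#'
#' @param seq a [protein_sequence()]; every chain is a copy of it.
#' @param n_copies number of chains (>= 1).
#' @param box cubic box edge in nm.
#' @param seed integer seed for the random conformations.
#' @param ff a [forcefield()] (bond length, masses).
#' @return a [cg_system()].
#' @export
build_system <- function(seq, n_copies, box, seed = 1L, ff = read_forcefield()) {
  stopifnot(inherits(seq, "protein_sequence"), n_copies >= 1, box > 0)
  L <- length(seq)
  m <- ceiling(n_copies^(1 / 3) - 1e-9)
  spacing <- box / m
  # require grid spacing to hold two ideal-coil radii plus a small buffer
  rg_ideal <- ff$bond_b0 * sqrt(L / 6)
  if (spacing < 1.2 * rg_ideal + 0.3) {
    stop(sprintf(
      "box too small: grid spacing %.2f nm < required %.2f nm for %d-residue coils",
      spacing, 1.2 * rg_ideal + 0.3, L))
  }
  set.seed(as.integer(seed))
  codes <- rep(seq_chars(seq), n_copies)
  bv <- bead_vectors(ff, seq_chars(seq))
  centers <- as.matrix(expand.grid(x = (seq_len(m) - 0.5) * spacing,
                                   y = (seq_len(m) - 0.5) * spacing,
                                   z = (seq_len(m) - 0.5) * spacing))
  centers <- centers[seq_len(n_copies), , drop = FALSE]
  pos <- matrix(0, n_copies * L, 3)
  for (c_i in seq_len(n_copies)) {
    steps <- random_unit_vectors(L - 1L) * ff$bond_b0
    walk <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    if (L == 1L) walk <- matrix(0, 1, 3)
    com <- colSums(walk * bv$mass) / sum(bv$mass)
    walk <- sweep(walk, 2, com - centers[c_i, ])
    pos[(c_i - 1L) * L + seq_len(L), ] <- walk
  }
  cg_system(pos, rep(seq_len(n_copies), each = L), codes, box,
            sequence = seq)
}

# n uniformly distributed unit vectors (n x 3)
random_unit_vectors <- function(n) {
  if (n == 0L) return(matrix(0, 0, 3))
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Re-box a system to a target total residue density
#'
#' Used between the NPT compression stage and production: molecules are
#' unwrapped across the old periodic boundaries (chains made whole), the
#' aggregate is recentered on its center of mass, and a new cubic box with
#' volume `V = N_residues / (N_A * rho_res)` is drawn around it, placing the
#' condensed phase in a dilute simulation cell.
#'
#' @param system a [cg_system()].
#' @param rho_res_mM target total residue density in mM.
#' @param ff a [forcefield()] (bead masses for the center of mass).
#' @return a [cg_system()] with the new box.
#' @export
set_box_density <- function(system, rho_res_mM, ff = read_forcefield()) {
  stopifnot(inherits(system, "cg_system"))
  if (rho_res_mM <= 0) stop("residue density must be positive")
  n <- nrow(system$pos)
  # V[nm^3] = N / (N_A * c[mol/L]) * 1e24 nm^3/L
  vol <- n * 1e27 / (.N_A * rho_res_mM)
  edge <- vol^(1 / 3)
  mass <- bead_vectors(ff, system$codes)$mass
  pos <- gather_chains(system$pos, system$chain, system$box, mass)
  com <- colSums(pos * mass) / sum(mass)
  pos <- sweep(pos, 2, com - edge / 2)
  out <- system
  out$pos <- pos
  out$box <- edge
  out
}

# Unwrap chains and gather them across periodic images: each molecule is
# made whole, then assigned the periodic image that brings its center of
# mass closest to the center of mass of the molecules gathered so far
# (nearest molecule first). A condensed phase that filled the old periodic
# box is thereby reassembled as one contiguous aggregate before re-boxing.
gather_chains <- function(pos, chain, box, mass) {
  pos <- unwrap_chains(pos, chain, box)
  ids <- unique(chain)
  coms <- t(vapply(ids, function(c_i) {
    idx <- chain == c_i
    colSums(pos[idx, , drop = FALSE] * mass[idx]) / sum(mass[idx])
  }, numeric(3)))
  msum <- vapply(ids, function(c_i) sum(mass[chain == c_i]), 1.0)
  placed <- rep(FALSE, length(ids))
  placed[1] <- TRUE
  ref <- coms[1, ]
  ref_mass <- msum[1]
  while (!all(placed)) {
    open <- which(!placed)
    d <- coms[open, , drop = FALSE] -
      matrix(ref, length(open), 3, byrow = TRUE)
    dm <- d - box * round(d / box)
    k <- open[which.min(rowSums(dm^2))]
    shift <- -box * round((coms[k, ] - ref) / box)
    if (any(shift != 0)) {
      idx <- chain == ids[k]
      pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2, -shift)
      coms[k, ] <- coms[k, ] + shift
    }
    ref <- (ref * ref_mass + coms[k, ] * msum[k]) / (ref_mass + msum[k])
    ref_mass <- ref_mass + msum[k]
    placed[k] <- TRUE
  }
  pos
}

# make each chain whole across periodic boundaries by walking its bonds
unwrap_chains <- function(pos, chain, box) {
  out <- pos
  for (c_i in unique(chain)) {
    idx <- which(chain == c_i)
    if (length(idx) < 2L) next
    d <- diff(pos[idx, , drop = FALSE])
    d <- d - box * round(d / box)
    out[idx, ] <- matrix(pos[idx[1L], ], length(idx), 3, byrow = TRUE) +
      rbind(0, apply(d, 2, cumsum))
  }
  out
}

#' Maxwell-Boltzmann velocities
#'
#' @param system a [cg_system()].
#' @param T_K temperature (K).
#' @param ff a [forcefield()] (bead masses).
#' @param seed integer seed.
#' @return the system with velocities drawn at `T_K`.
#' @export
assign_velocities <- function(system, T_K, ff = read_forcefield(), seed = 1L) {
  set.seed(as.integer(seed))
  mass <- bead_vectors(ff, system$codes)$mass
  n <- nrow(system$pos)
  sd <- sqrt(.kB * T_K / mass)
  system$vel <- matrix(stats::rnorm(3 * n), n, 3) * sd
  system
}
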