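#' Intermolecular contacts in one frame
#'
#' A contact is an unordered pair of beads on *different* molecules whose
#' minimum-image center distance is at most `rc`. Contacts are counted per
#' bead pair, once each.
#'
#' @param pos N x 3 position matrix (nm).
#' @param chain integer chain index per bead.
#' @param box cubic box edge (nm).
#' @param rc contact cutoff (nm); must not exceed half the box edge under
#'   periodic boundaries.
#' @param L residues per chain (all chains equal length).
#' @param periodic logical.
#' @return data.frame with columns `mol_a`, `res_i`, `mol_b`, `res_j`
#'   (`mol_a < mol_b`); residue indices are 1-based within the chain.
#' @export
intermolecular_contacts <- function(pos, chain, box, rc, L, periodic = TRUE) {
  if (rc <= 0) stop("rc must be positive")
  if (periodic && rc > box / 2) {
    stop("rc exceeds half the box edge (minimum-image violation)")
  }
  pr <- cpp_contacts(as.matrix(pos), as.integer(chain), box, periodic, rc)
  if (nrow(pr) == 0) {
    return(data.frame(mol_a = integer(), res_i = integer(),
                      mol_b = integer(), res_j = integer()))
  }
  mol <- chain[pr[, 1]]
  mol2 <- chain[pr[, 2]]
  res <- (pr[, 1] - 1L) %% L + 1L
  res2 <- (pr[, 2] - 1L) %% L + 1L
  swap <- mol > mol2
  out <- data.frame(
    mol_a = ifelse(swap, mol2, mol), res_i = ifelse(swap, res2, res),
    mol_b = ifelse(swap, mol, mol2), res_j = ifelse(swap, res, res2))
  out
}

#' Frame-averaged intermolecular contact map by residue index
#'
#' `map[i, j]` is the number of intermolecular bead contacts between residue
#' indices i and j, summed over frames and molecule pairs, divided by
#' `n_frames * n_molecules`, and symmetrized (each contact contributes to
#' both `[i, j]` and `[j, i]`). The attached 1D vector is the row sum.
#'
#' @param traj a `cg_trajectory` (all chains one sequence length).
#' @param rc contact cutoff, nm.
#' @return object of class `contact_map`: list with `map` (L x L), `vec`,
#'   `n_frames`, `n_molecules`, `rc`.
#' @export
contact_map_by_index <- function(traj, rc = 1.0) {
  stopifnot(inherits(traj, "cg_trajectory"))
  tab <- table(traj$chain)
  if (length(unique(as.integer(tab))) != 1L) {
    stop("heterogeneous chain lengths are not supported")
  }
  L <- as.integer(tab[1])
  nmol <- length(tab)
  C <- matrix(0, L, L)
  for (f in seq_along(traj$frames)) {
    ct <- intermolecular_contacts(traj$frames[[f]], traj$chain, traj$boxes[f],
                                  rc, L, traj$periodic)
    if (nrow(ct)) {
      flat <- (ct$res_j - 1L) * L + ct$res_i
      C <- C + matrix(tabulate(flat, nbins = L * L), L, L)
    }
  }
  M <- C + t(C)
  diag(M) <- diag(C)
  M <- M / (length(traj$frames) * nmol)
  structure(list(map = M, vec = rowSums(M), n_frames = length(traj$frames),
                 n_molecules = nmol, rc = rc,
                 codes = traj$codes[seq_len(L)],
                 positions = if (!is.null(traj$sequence))
                   traj$sequence$first_residue_number + seq_len(L) - 1L
                 else seq_len(L)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d x %d residues, %d frames, %d molecules, rc = %g nm\n",
              nrow(x$map), ncol(x$map), x$n_frames, x$n_molecules, x$rc))
  cat(sprintf("  total (per molecule per frame): %.4g\n", sum(x$map)))
  invisible(x)
}

#' @export
plot.contact_map <- function(x, ...) {
  graphics::image(x$positions, x$positions, x$map,
                  xlab = "residue", ylab = "residue",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Reduce a by-index contact map to residue types
#'
#' Type entry (u, v) sums the index entries whose residue codes are u and v;
#' the total is conserved exactly. `n_bead` counts each residue type in one
#' chain.
#'
#' @param cmap a [contact_map_by_index()] result.
#' @param seq optional [protein_sequence()]; defaults to the trajectory's.
#' @return object of class `type_contact_map`: 20 x 20 `map`, `n_bead`.
#' @export
reduce_by_type <- function(cmap, seq = NULL) {
  stopifnot(inherits(cmap, "contact_map"))
  codes <- if (is.null(seq)) cmap$codes else seq_chars(seq)
  if (length(codes) != nrow(cmap$map)) stop("sequence length does not match map")
  Tm <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  idx <- match(codes, AA_CODES)
  for (i in seq_along(codes)) {
    for (j in seq_along(codes)) {
      Tm[idx[i], idx[j]] <- Tm[idx[i], idx[j]] + cmap$map[i, j]
    }
  }
  nb <- vapply(AA_CODES, function(a) sum(codes == a), 1L)
  structure(list(map = Tm, n_bead = nb, rc = cmap$rc,
                 n_frames = cmap$n_frames, n_molecules = cmap$n_molecules),
            class = "type_contact_map")
}

#' @export
print.type_contact_map <- function(x, ...) {
  cat(sprintf("type_contact_map: 20 x 20, total %.4g contacts/molecule/frame\n",
              sum(x$map)))
  invisible(x)
}

#' Interaction fractions over residue-category pairs
#'
#' Aggregates a type contact map over the five residue categories and
#' normalizes by the total number of interactions, giving `F_int` over the 15
#' unordered category pairs (sums to 1 in raw mode). With
#' `abundance_normalized = TRUE` each type entry is first divided by
#' `n_bead(u) * n_bead(v)` (the simple product convention, also for u = v)
#' before aggregation, then renormalized, correcting for the fact that
#' abundant residue types accumulate contacts merely by being abundant.
#'
#' @param tmap a [reduce_by_type()] result.
#' @param scheme a [category_scheme()].
#' @param abundance_normalized logical flag.
#' @return object of class `interaction_summary`: data.frame with
#'   `category_a`, `category_b`, `f_int`; attribute `abundance_normalized`.
#' @export
interaction_fractions <- function(tmap, scheme = category_scheme(),
                                  abundance_normalized = FALSE) {
  stopifnot(inherits(tmap, "type_contact_map"))
  M <- tmap$map
  if (sum(M) <= 0) stop("zero total contacts")
  if (abundance_normalized) {
    nb <- tmap$n_bead
    W <- outer(nb, nb)
    pos <- W > 0
    M[pos] <- M[pos] / W[pos]
    M[!pos] <- 0
  }
  cat_of <- unname(scheme[rownames(M)])
  C <- matrix(0, 5, 5, dimnames = list(CATEGORY_NAMES, CATEGORY_NAMES))
  for (a in CATEGORY_NAMES) {
    for (b in CATEGORY_NAMES) {
      C[a, b] <- sum(M[cat_of == a, cat_of == b, drop = FALSE])
    }
  }
  pairs <- which(upper.tri(C, diag = TRUE), arr.ind = TRUE)
  f <- apply(pairs, 1, function(ij) {
    a <- ij[1]; b <- ij[2]
    if (a == b) C[a, a] else C[a, b] + C[b, a]
  })
  f <- f / sum(C)
  out <- data.frame(category_a = CATEGORY_NAMES[pairs[, 1]],
                    category_b = CATEGORY_NAMES[pairs[, 2]],
                    f_int = as.numeric(f))
  attr(out, "abundance_normalized") <- abundance_normalized
  class(out) <- c("interaction_summary", "data.frame")
  out
}

#' Per-frame cluster-size trace
#'
#' Chains are graph nodes; an edge joins two chains sharing at least one
#' intermolecular contact; cluster sizes are the connected-component sizes
#' (they sum to the number of chains at every frame).
#'
#' @param traj a `cg_trajectory`.
#' @param rc contact cutoff, nm.
#' @return object of class `cluster_trace`: list with `times` (ps),
#'   `sizes` (list of integer vectors) and `largest` (largest-cluster series).
#' @export
cluster_trace <- function(traj, rc = 1.0) {
  stopifnot(inherits(traj, "cg_trajectory"))
  tab <- table(traj$chain)
  L <- as.integer(tab[1])
  nmol <- length(tab)
  sizes <- vector("list", length(traj$frames))
  for (f in seq_along(traj$frames)) {
    ct <- intermolecular_contacts(traj$frames[[f]], traj$chain, traj$boxes[f],
                                  rc, L, traj$periodic)
    edges <- unique(ct[, c("mol_a", "mol_b")])
    g <- igraph::graph_from_data_frame(edges,
                                       vertices = data.frame(name = seq_len(nmol)),
                                       directed = FALSE)
    comp <- igraph::components(g)
    sizes[[f]] <- sort(as.integer(comp$csize), decreasing = TRUE)
  }
  structure(list(times = traj$times, sizes = sizes,
                 largest = vapply(sizes, max, 1L), n_molecules = nmol),
            class = "cluster_trace")
}

#' @export
print.cluster_trace <- function(x, ...) {
  cat(sprintf("cluster_trace: %d frames, %d chains; largest cluster %d-%d\n",
              length(x$sizes), x$n_molecules, min(x$largest), max(x$largest)))
  invisible(x)
}

#' @export
plot.cluster_trace <- function(x, ...) {
  graphics::plot(x$times / 1000, x$largest, type = "s", xlab = "time (ns)",
                 ylab = "largest cluster (chains)",
                 ylim = c(0, x$n_molecules), ...)
  graphics::abline(h = x$n_molecules, lty = 3)
  invisible(x)
}

#' Write a contact map as dense tabular text
#' @param cmap a `contact_map` or `type_contact_map`.
#' @param path output path.
#' @export
write_contact_map <- function(cmap, path) {
  utils::write.table(cmap$map, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
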