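# Independent brute-force oracles used to pin the semantics of the fast paths.

# minimum-image distance matrix, plain R
mic_dist <- function(pos, box, periodic = TRUE) {
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dv <- sweep(pos, 2, pos[i, ])
    if (periodic) dv <- dv - box * round(dv / box)
    d[i, ] <- sqrt(rowSums(dv^2))
  }
  d
}

# all intermolecular bead contacts from the full O(N^2) distance matrix
oracle_contacts <- function(pos, chain, box, rc, periodic = TRUE) {
  d <- mic_dist(pos, box, periodic)
  mask <- upper.tri(d) & d <= rc & outer(chain, chain, "!=")
  hits <- which(mask, arr.ind = TRUE)
  if (nrow(hits) == 0) return(NULL)
  unname(cbind(hits[, 1], hits[, 2]))
}

# by-index contact map from the oracle contact list (same normalization
# contract as contact_map_by_index)
oracle_contact_map <- function(frames, chain, boxes, rc, L, periodic = TRUE) {
  nmol <- length(unique(chain))
  C <- matrix(0, L, L)
  for (f in seq_along(frames)) {
    ct <- oracle_contacts(frames[[f]], chain, boxes[f], rc, periodic)
    if (!is.null(ct)) {
      for (k in seq_len(nrow(ct))) {
        i <- (ct[k, 1] - 1) %% L + 1
        j <- (ct[k, 2] - 1) %% L + 1
        C[i, j] <- C[i, j] + 1
      }
    }
  }
  M <- C + t(C)
  diag(M) <- diag(C)
  M / (length(frames) * nmol)
}

# random small multi-chain system for contact tests
random_contact_system <- function(n_chains, L, box, seed) {
  set.seed(seed)
  pos <- matrix(runif(n_chains * L * 3, 0, box), ncol = 3)
  chain <- rep(seq_len(n_chains), each = L)
  list(pos = pos, chain = chain, box = box, L = L)
}

# protein sequences used across tests
poly_seq <- function(code, n, ...) {
  protein_sequence(paste(rep(code, n), collapse = ""), ...)
}

tiny_ff <- function(...) forcefield(...)

seq_chars <- idrsuite:::seq_chars
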