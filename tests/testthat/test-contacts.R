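ff <- read_forcefield()

make_traj <- function(frames, chain, boxes, periodic = TRUE) {
  structure(list(frames = frames, times = seq_along(frames) * 5,
                 boxes = boxes, stage = "test", seed = 0, chain = chain,
                 codes = rep("A", length(chain)), sequence = NULL,
                 periodic = periodic),
            class = "cg_trajectory")
}

test_that("contact definition: boundary, intramolecular exclusion, separation", {
  # two chains far apart
  pos <- rbind(c(1, 1, 1), c(1, 1, 2), c(8, 8, 8), c(8, 8, 9))
  ct <- intermolecular_contacts(pos, c(1, 1, 2, 2), box = 20, rc = 1, L = 2)
  expect_equal(nrow(ct), 0)
  # boundary: distance rc - eps counts once
  pos2 <- rbind(c(0.5, 0, 0), c(1.499, 0, 0))
  ct2 <- intermolecular_contacts(pos2, c(1, 2), box = 20, rc = 1, L = 1)
  expect_equal(nrow(ct2), 1)
  expect_equal(ct2$mol_a, 1)
  expect_equal(ct2$mol_b, 2)
  # same pair on one chain is not a contact
  ct3 <- intermolecular_contacts(pos2, c(1, 1), box = 20, rc = 1, L = 2)
  expect_equal(nrow(ct3), 0)
  # rc beyond half the box violates minimum image
  expect_error(intermolecular_contacts(pos2, c(1, 2), box = 1.5, rc = 1, L = 1),
               "half the box")
})

test_that("contact counting equals the brute-force all-pairs oracle", {
  for (trial in 1:25) {
    sys <- random_contact_system(n_chains = sample(2:5, 1),
                                 L = sample(3:20, 1),
                                 box = runif(1, 4, 8), seed = 1000 + trial)
    rc <- runif(1, 0.5, min(1.5, sys$box / 2 - 0.01))
    fast <- intermolecular_contacts(sys$pos, sys$chain, sys$box, rc, sys$L)
    slow <- oracle_contacts(sys$pos, sys$chain, sys$box, rc)
    n_slow <- if (is.null(slow)) 0 else nrow(slow)
    expect_equal(nrow(fast), n_slow)
    if (n_slow > 0) {
      # same bead pairs regardless of ordering convention
      fast_keys <- sort(paste(pmin((fast$mol_a - 1) * sys$L + fast$res_i,
                                   (fast$mol_b - 1) * sys$L + fast$res_j),
                              pmax((fast$mol_a - 1) * sys$L + fast$res_i,
                                   (fast$mol_b - 1) * sys$L + fast$res_j)))
      slow_keys <- sort(paste(slow[, 1], slow[, 2]))
      expect_equal(fast_keys, slow_keys)
    }
  }
})

test_that("by-index map matches oracle, averages frames, normalizes by molecules", {
  sys <- random_contact_system(3, 6, 5, seed = 42)
  frames <- list(sys$pos, sys$pos + 0.3, sys$pos)
  traj <- make_traj(frames, sys$chain, rep(5, 3))
  cm <- contact_map_by_index(traj, rc = 1.2)
  M_oracle <- oracle_contact_map(frames, sys$chain, rep(5, 3), 1.2, 6)
  expect_equal(cm$map, M_oracle)
  expect_true(isSymmetric(cm$map))
  expect_equal(cm$vec, rowSums(cm$map))
  # duplicating every frame leaves the map unchanged
  traj2 <- make_traj(c(frames, frames), sys$chain, rep(5, 6))
  expect_equal(contact_map_by_index(traj2, rc = 1.2)$map, cm$map)
  # zero-contact trajectory gives the zero matrix
  farpos <- sys$pos
  farpos[sys$chain == 2, ] <- farpos[sys$chain == 2, ] + 100
  sparse <- make_traj(list(farpos), sys$chain, 1000)
  expect_true(all(contact_map_by_index(sparse, rc = 0.25)$map >= 0))
})

test_that("type reduction conserves totals and matches brute force", {
  set.seed(9)
  codes6 <- c("A", "S", "K", "E", "A", "F")
  sys <- random_contact_system(3, 6, 5, seed = 7)
  traj <- make_traj(list(sys$pos), sys$chain, 5)
  traj$codes <- rep(codes6, 3)
  cm <- contact_map_by_index(traj, rc = 1.5)
  tm <- reduce_by_type(cm)
  expect_equal(sum(tm$map), sum(cm$map), tolerance = 1e-12)
  expect_true(isSymmetric(tm$map))
  expect_equal(unname(tm$n_bead[c("A", "S", "K", "E", "F")]),
               c(2L, 1L, 1L, 1L, 1L))
  # brute-force reduction
  Tm <- matrix(0, 20, 20, dimnames = list(idrsuite:::AA_CODES,
                                          idrsuite:::AA_CODES))
  for (i in 1:6) for (j in 1:6) {
    Tm[codes6[i], codes6[j]] <- Tm[codes6[i], codes6[j]] + cm$map[i, j]
  }
  expect_equal(tm$map, Tm)
  # homopolymer: single nonzero entry
  trajA <- make_traj(list(sys$pos), sys$chain, 5)
  cmA <- contact_map_by_index(trajA, rc = 1.5)
  tmA <- reduce_by_type(cmA)
  expect_equal(sum(tmA$map != 0), 1)
  expect_equal(tmA$map["A", "A"], sum(cmA$map))
})

test_that("interaction fractions sum to one and aggregate correctly", {
  sys <- random_contact_system(3, 6, 5, seed = 11)
  traj <- make_traj(list(sys$pos), sys$chain, 5)
  traj$codes <- rep(c("A", "S", "K", "E", "A", "F"), 3)
  tm <- reduce_by_type(contact_map_by_index(traj, rc = 1.5))
  fi <- interaction_fractions(tm)
  expect_equal(nrow(fi), 15)
  expect_equal(sum(fi$f_int), 1, tolerance = 1e-9)
  expect_true(all(fi$f_int >= 0))
  # hand-computed aggregation for a constructed 2-type map
  tm2 <- tm
  tm2$map[] <- 0
  tm2$map["A", "A"] <- 4
  tm2$map["A", "S"] <- 1.5
  tm2$map["S", "A"] <- 1.5
  tm2$map["S", "S"] <- 3
  fi2 <- interaction_fractions(tm2)
  get <- function(a, b) fi2$f_int[(fi2$category_a == a & fi2$category_b == b) |
                                  (fi2$category_a == b & fi2$category_b == a)]
  expect_equal(get("aliphatic", "aliphatic"), 0.4)
  expect_equal(get("aliphatic", "hydrophilic"), 0.3)
  expect_equal(get("hydrophilic", "hydrophilic"), 0.3)
  # all-aliphatic contacts concentrate in one bin
  tm3 <- tm
  tm3$map[] <- 0
  tm3$map["L", "V"] <- 2
  tm3$map["V", "L"] <- 2
  fi3 <- interaction_fractions(tm3)
  expect_equal(get3 <- fi3$f_int[fi3$category_a == "aliphatic" &
                                 fi3$category_b == "aliphatic"], 1.0)
  expect_error(interaction_fractions({tm0 <- tm; tm0$map[] <- 0; tm0}),
               "zero total")
  # abundance normalization: uniform map over two equally abundant types
  # stays uniform, so both modes agree there
  fiN <- interaction_fractions(tm2, abundance_normalized = TRUE)
  expect_equal(sum(fiN$f_int), 1, tolerance = 1e-9)
})

test_that("maps are invariant under molecule relabeling", {
  sys <- random_contact_system(4, 5, 6, seed = 13)
  traj <- make_traj(list(sys$pos), sys$chain, 6)
  cm1 <- contact_map_by_index(traj, rc = 1.3)
  # relabel molecules 1<->3 by reordering beads
  perm <- c(3, 2, 1, 4)
  idx <- unlist(lapply(perm, function(m) which(sys$chain == m)))
  traj2 <- make_traj(list(sys$pos[idx, ]), rep(1:4, each = 5), 6)
  cm2 <- contact_map_by_index(traj2, rc = 1.3)
  expect_equal(cm2$map, cm1$map)
})

test_that("cluster trace gives transitive components summing to all chains", {
  # A touches B, B touches C, A far from C -> one cluster of 3
  pos <- rbind(c(1, 1, 1), c(1.8, 1, 1), c(2.6, 1, 1), c(9, 9, 9))
  traj <- make_traj(list(pos), c(1, 2, 3, 4), 20)
  tr <- cluster_trace(traj, rc = 1.0)
  expect_equal(sort(tr$sizes[[1]], decreasing = TRUE), c(3, 1))
  expect_equal(sum(tr$sizes[[1]]), 4)
  expect_equal(tr$largest, 3)
  # all chains mutually distant
  posfar <- matrix(c(1, 1, 1, 5, 5, 5, 10, 10, 10), ncol = 3, byrow = TRUE)
  trf <- cluster_trace(make_traj(list(posfar), 1:3, 30), rc = 1.0)
  expect_equal(trf$sizes[[1]], c(1L, 1L, 1L))
  # constructed dense droplet: all chains in one cluster in every frame
  set.seed(21)
  dense <- matrix(rnorm(12 * 4 * 3, sd = 0.8), ncol = 3) + 10
  trd <- cluster_trace(make_traj(list(dense, dense), rep(1:12, each = 4),
                                 c(40, 40)), rc = 1.5)
  expect_equal(trd$largest, c(12L, 12L))
})
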