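ff <- read_forcefield()

test_that("Debye screening constant: physiological value, zero limit, scaling", {
  expect_equal(debye_kappa(150, 300, 78.3), 1.27, tolerance = 0.02 / 1.27)
  expect_equal(debye_kappa(0, 300, 78.3), 0)
  expect_equal(debye_kappa(600, 300, 78.3), 2 * debye_kappa(150, 300, 78.3),
               tolerance = 1e-12)
  expect_error(debye_kappa(150, -1, 78.3), "positive")
  expect_error(debye_kappa(150, 300, 0), "positive")
})

test_that("pair energies match hand-evaluated Debye-Hueckel terms", {
  sysK <- cg_system(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 2), c("K", "K"),
                    box = 50)
  ff0 <- forcefield(kappa = 0, eps_r = 80)
  e0 <- potential_energy(sysK, ff0)
  expect_equal(e0$electrostatic, 138.935458 / 80 *
                 exp(0) * 1, tolerance = 1e-9)
  ff1 <- forcefield(kappa = 1.27, eps_r = 80)
  e1 <- potential_energy(sysK, ff1)
  expect_equal(e1$electrostatic, e0$electrostatic * exp(-1.27),
               tolerance = 1e-12)
  # single bead: all terms zero
  e <- potential_energy(cg_system(matrix(0, 1, 3), 1L, "A", box = 10), ff)
  expect_equal(unlist(e[c("total", "bond", "electrostatic", "short_range")]),
               c(total = 0, bond = 0, electrostatic = 0, short_range = 0))
  # exact overlap is singular
  so <- cg_system(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 2), c("A", "A"), box = 10)
  expect_error(potential_energy(so, ff), "singular")
})

test_that("screening limit: kappa -> infinity recovers the no-electrostatics energy", {
  set.seed(3)
  pos <- matrix(runif(30, 0, 4), ncol = 3)
  sys <- cg_system(pos, rep(1:2, each = 5), rep(c("K", "E"), 5), box = 12)
  e_inf <- potential_energy(sys, forcefield(kappa = 1e4))
  e_off <- potential_energy(sys, forcefield(kappa = 0))
  expect_lt(abs(e_inf$electrostatic), 1e-8)
  expect_equal(e_inf$short_range, e_off$short_range)
  expect_equal(e_inf$bond, e_off$bond)
})

test_that("pair forces sum to zero on an isolated system", {
  set.seed(7)
  for (k in 1:5) {
    n <- 20
    pos <- matrix(runif(3 * n, 0, 5), ncol = 3)
    sys <- cg_system(pos, rep(1:4, each = 5),
                     sample(c("K", "E", "A", "S", "F"), n, TRUE), box = 15)
    f <- potential_energy(sys, ff, forces = TRUE)$forces
    expect_lt(max(abs(colSums(f))), 1e-9)
  }
})

test_that("minimization finds the analytic pair minimum and reports state", {
  sysd <- cg_system(rbind(c(0, 0, 0), c(0.2, 0, 0)), c(1, 2), c("A", "A"),
                    box = 20)
  m <- minimize(sysd, ff, tol = 1e-6)
  d <- mic_dist(m$pos, 20)[1, 2]
  expect_equal(d, 2^(1 / 6) * 0.504, tolerance = 1e-4)
  expect_true(attr(m, "converged"))
  # fixed point: re-minimizing changes nothing appreciable
  m2 <- minimize(m, ff, tol = 1e-6)
  expect_lt(abs(attr(m2, "energy") - attr(m, "energy")), 1e-10)
  # iteration cap reported, not silent
  bad <- cg_system(rbind(c(0, 0, 0), c(0.05, 0, 0)), c(1, 2), c("A", "A"),
                   box = 20)
  expect_warning(minimize(bad, ff, tol = 1e-9, max_iter = 1), "not converged")
})

test_that("build_system places chain centers on a regular grid", {
  s8 <- build_system(poly_seq("G", 2), 8, box = 8, seed = 1, ff = ff)
  expect_equal(nrow(s8$pos), 16)
  coms <- t(vapply(1:8, function(c_i) colMeans(s8$pos[s8$chain == c_i, ]),
                   numeric(3)))
  spacing <- 8 / 2
  expected <- as.matrix(expand.grid(c(2, 6), c(2, 6), c(2, 6)))
  # mass-weighted = arithmetic mean for a homopolymer
  ord <- order(round(coms[, 3]), round(coms[, 2]), round(coms[, 1]))
  orde <- order(expected[, 3], expected[, 2], expected[, 1])
  expect_equal(unname(coms[ord, ]), unname(expected[orde, ]), tolerance = 1e-8)

  big <- build_system(poly_seq("S", 352), 2, box = 40, seed = 1, ff = ff)
  expect_equal(nrow(big$pos), 704)
  expect_error(build_system(poly_seq("S", 352), 120, box = 1, seed = 1, ff = ff),
               "too small")
})

test_that("re-boxing to a residue density gives the analytic volume", {
  s1 <- cg_system(matrix(c(5, 5, 5), 1, 3), 1L, "G", box = 10)
  r1 <- set_box_density(s1, 80, ff)
  expect_equal(r1$box^3, 20.76, tolerance = 1e-3)
  expect_equal(r1$box, 2.75, tolerance = 1e-2)
  # 42,240 residues at 80 mM (positions synthetic, geometry irrelevant)
  expect_equal((42240 * 1e27 / (6.02214076e23 * 80))^(1 / 3), 95.77,
               tolerance = 1e-3)
  expect_error(set_box_density(s1, 0, ff), "positive")
  # center of mass lands at the box center and chains are whole
  s2 <- build_system(poly_seq("G", 20), 4, box = 12, seed = 2, ff = ff)
  r2 <- set_box_density(s2, 80, ff)
  expect_equal(colMeans(r2$pos), rep(r2$box / 2, 3), tolerance = 1e-8)
  bond_len <- sqrt(rowSums(diff(r2$pos[r2$chain == 1, ])^2))
  expect_true(all(bond_len < 1))   # no broken chains after unwrap
})

test_that("NVT: equipartition temperature, determinism, zero duration", {
  sys10 <- build_system(poly_seq("G", 10), 1, 10, seed = 2, ff = ff)
  cfg <- protocol_config(tau_t_ps = 1, seed = 3)
  tr <- run_nvt(sys10, ff, cfg, duration_ns = 1)
  tt <- attr(tr, "temperature_trace")
  mt <- mean(tail(tt, length(tt) / 2))
  expect_gt(mt, 291)
  expect_lt(mt, 309)

  tr2 <- run_nvt(sys10, ff, cfg, duration_ns = 0.02)
  tr3 <- run_nvt(sys10, ff, cfg, duration_ns = 0.02)
  expect_identical(tr2$frames, tr3$frames)

  tr0 <- run_nvt(sys10, ff, cfg, duration_ns = 0)
  expect_equal(n_frames(tr0), 1)
  expect_equal(tr0$times, 0)
})

test_that("zero-friction integration conserves energy (symplectic limit)", {
  cfg0 <- protocol_config(tau_t_ps = 0, seed = 1)
  sys2 <- cg_system(rbind(c(0, 0, 0), c(0.5, 0, 0)), c(1, 1), c("A", "A"),
                    box = 10, vel = matrix(0, 2, 3))
  tr <- idrsuite:::run_md_stage(sys2, ff, cfg0, duration_ns = 0.2, "t", 1)
  en <- attr(tr, "energy_trace")   # total (kinetic + potential), 1e4 steps
  expect_gt(length(en), 500)
  expect_lt((max(en) - min(en)) / abs(mean(en)), 0.01)
})

test_that("NPT: Berendsen box response and zero-compressibility limit", {
  # non-overlapping repulsive gas above 1 bar expands monotonically at first
  pos <- as.matrix(expand.grid(x = (1:4) * 2 - 1, y = (1:4) * 2 - 1,
                               z = (1:4) * 2 - 1))
  n <- nrow(pos)
  gas <- cg_system(pos, seq_len(n), rep("E", n), box = 8)
  cfg <- protocol_config(tau_t_ps = 1, tau_p_ps = 1,
                         compressibility_bar = 4.5e-3, seed = 5,
                         include_initial = TRUE)
  tr <- idrsuite:::run_md_stage(gas, ff, cfg, 0.05, "npt", 5, barostat = TRUE,
                                sample_every_ns = 0.005)
  expect_true(all(diff(tr$boxes[1:5]) > 0))

  cfg0 <- protocol_config(compressibility_bar = 0, seed = 5)
  tr0 <- idrsuite:::run_md_stage(gas, ff, cfg0, 0.02, "npt", 5, barostat = TRUE,
                                 sample_every_ns = 0.005)
  expect_true(all(tr0$boxes == 8))

  tr1 <- idrsuite:::run_md_stage(gas, ff, cfg, 0.02, "npt", 6, barostat = TRUE,
                                 sample_every_ns = 0.005)
  tr2 <- idrsuite:::run_md_stage(gas, ff, cfg, 0.02, "npt", 6, barostat = TRUE,
                                 sample_every_ns = 0.005)
  expect_identical(tr1$frames, tr2$frames)
})

test_that("droplet protocol runs all stages in order at toy scale", {
  seqx <- gen_idr_sequence(30, composition_preset("aliphatic_rich"), seed = 2)
  cfg <- protocol_config(scale_factor = 1 / 5000, seed = 7)
  res <- suppressWarnings(droplet_protocol(seqx, 4, ff, cfg, seed = 7))
  expect_s3_class(res, "droplet_protocol_result")
  expect_equal(res$stages$stage,
               c("minimization", "nvt", "npt", "re-box", "minimization-2",
                 "production"))
  # production frame count = duration / sampling interval at any scale
  expect_equal(n_frames(res$production),
               round(cfg$production_ns / cfg$sampling_ns))
  expect_equal(res$production$stage, "production")
  # the re-boxed system hits the target residue density
  n_res <- nrow(res$expanded$pos)
  expect_equal(res$expanded$box^3, n_res * 1e27 / (6.02214076e23 * 80),
               tolerance = 1e-10)
})

test_that("protocol config validates sampling interval and echoes defaults", {
  cfg <- protocol_config()
  expect_equal(cfg$temperature, 300)
  expect_equal(cfg$timestep_fs, 20)
  expect_equal(cfg$tau_t_ps, 100)
  expect_equal(cfg$tau_p_ps, 10)
  expect_equal(cfg$pressure_bar, 1)
  expect_equal(cfg$compressibility_bar, 4.5e-5)
  expect_equal(cfg$min_tol, 1)
  expect_equal(c(cfg$nvt_ns, cfg$npt_ns, cfg$production_ns), c(50, 500, 3000))
  expect_equal(cfg$sampling_ns, 5)
  expect_equal(cfg$rho_res_mM, 80)
  expect_equal(round(cfg$production_ns / cfg$sampling_ns), 600)
  expect_error(protocol_config(production_ns = 10, sampling_ns = 3), "divide")
})

test_that("trajectories export as extended XYZ with box metadata", {
  sys <- build_system(poly_seq("G", 5), 2, 8, seed = 1, ff = ff)
  cfg <- protocol_config(seed = 1, include_initial = TRUE)
  tr <- run_nvt(sys, ff, cfg, duration_ns = 0.01)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  lines <- readLines(f)
  expect_equal(lines[1], "10")
  expect_match(lines[2], "box_nm=")
  expect_equal(length(lines), n_frames(tr) * 12)
})
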