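#' Potential energy of a coarse-grained system
#'
#' Total energy with per-term decomposition: harmonic bonds, Debye-Hueckel
#' screened electrostatics (`f_C q_i q_j exp(-kappa r) / (eps_r r)` with
#' `f_C = 138.935 kJ mol-1 nm e-2`) and the hydropathy-scaled Ashbaugh-Hatch
#' short-range term truncated at the cutoff. Minimum-image convention under
#' periodic boundaries; bonded (1-2) pairs are excluded from nonbonded terms.
#'
#' @param system a [cg_system()].
#' @param ff a [forcefield()].
#' @param forces logical; also return the force matrix.
#' @return list with `total`, `bond`, `electrostatic`, `short_range`
#'   (kJ/mol), `virial`, and optionally `forces` (kJ/mol/nm).
#' @export
potential_energy <- function(system, ff = read_forcefield(), forces = FALSE) {
  stopifnot(inherits(system, "cg_system"), inherits(ff, "forcefield"))
  bv <- bead_vectors(ff, system$codes)
  res <- cpp_energy(system$pos, system$chain, bv$charge, bv$sigma, bv$lambda,
                    bv$mass, system$box, system$periodic,
                    ff$bond_b0, ff$bond_k, ff$epsilon, ff$eps_r, ff$kappa,
                    ff$cutoff)
  if (res$singular) stop("singular pair: two beads at zero separation")
  out <- res[c("total", "bond", "electrostatic", "short_range", "virial")]
  if (forces) out$forces <- res$forces
  out
}

#' Steepest-descent energy minimization
#'
#' Adaptive-step steepest descent until the largest force component falls
#' below `tol` (kJ/mol/nm) or the iteration cap is reached; energy is
#' non-increasing across accepted steps. Non-convergence is reported with a
#' warning, never silently.
#'
#' @param system a [cg_system()].
#' @param ff a [forcefield()].
#' @param tol force tolerance in kJ/mol/nm (default 1, the protocol value).
#' @param max_iter iteration cap.
#' @return the minimized [cg_system()]; attributes `converged`,
#'   `iterations`, `max_force`, `energy`.
#' @export
minimize <- function(system, ff = read_forcefield(), tol = 1, max_iter = 5000L) {
  stopifnot(inherits(system, "cg_system"))
  bv <- bead_vectors(ff, system$codes)
  res <- cpp_minimize(system$pos, system$chain, bv$charge, bv$sigma, bv$lambda,
                      bv$mass, system$box, system$periodic,
                      ff$bond_b0, ff$bond_k, ff$epsilon, ff$eps_r, ff$kappa,
                      ff$cutoff, tol, as.integer(max_iter))
  if (!res$converged) {
    warning(sprintf("minimization not converged: max force %.3g kJ/mol/nm after %d iterations",
                    res$max_force, res$iterations))
  }
  out <- system
  out$pos <- res$pos
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  attr(out, "max_force") <- res$max_force
  attr(out, "energy") <- res$energy
  out
}

#' Simulation protocol configuration
#'
#' Defaults reproduce the staged droplet-formation protocol: 300 K, 20 fs
#' timestep, thermostat time constant 100 ps, Berendsen barostat with
#' tau_p = 10 ps at 1 bar reference pressure and compressibility
#' 4.5e-5 bar^-1, minimization tolerance 1 kJ/mol/nm, 50 ns NVT, 500 ns NPT,
#' re-box to a total residue density of 80 mM, then a 3 us production run
#' sampled every 5 ns (600 frames). `scale_factor` multiplies all durations
#' and the sampling interval for desk-scale runs, preserving the frame count.
#'
#' @param temperature K.
#' @param timestep_fs integration timestep in fs.
#' @param tau_t_ps thermostat (Langevin friction) time constant, ps.
#' @param tau_p_ps barostat time constant, ps.
#' @param pressure_bar reference pressure, bar.
#' @param compressibility_bar isothermal compressibility, bar^-1.
#' @param min_tol minimization force tolerance, kJ/mol/nm.
#' @param nvt_ns,npt_ns,production_ns stage durations, ns.
#' @param sampling_ns production sampling interval, ns; must divide the
#'   production duration.
#' @param rho_res_mM target total residue density for the production box, mM.
#' @param seed master random seed; per-stage streams are derived from it.
#' @param scale_factor multiplies all durations and the sampling interval.
#' @param include_initial logical; store the initial frame in trajectories.
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(temperature = 300, timestep_fs = 20,
                            tau_t_ps = 100, tau_p_ps = 10,
                            pressure_bar = 1, compressibility_bar = 4.5e-5,
                            min_tol = 1,
                            nvt_ns = 50, npt_ns = 500, production_ns = 3000,
                            sampling_ns = 5, rho_res_mM = 80,
                            seed = 1L, scale_factor = 1,
                            include_initial = FALSE) {
  stopifnot(temperature > 0, timestep_fs > 0, nvt_ns >= 0, npt_ns >= 0,
            production_ns >= 0, sampling_ns > 0, rho_res_mM > 0,
            scale_factor > 0)
  ratio <- production_ns / sampling_ns
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("sampling interval must divide the production duration")
  }
  structure(list(temperature = temperature, timestep_fs = timestep_fs,
                 tau_t_ps = tau_t_ps, tau_p_ps = tau_p_ps,
                 pressure_bar = pressure_bar,
                 compressibility_bar = compressibility_bar,
                 min_tol = min_tol, nvt_ns = nvt_ns, npt_ns = npt_ns,
                 production_ns = production_ns, sampling_ns = sampling_ns,
                 rho_res_mM = rho_res_mM, seed = as.integer(seed),
                 scale_factor = scale_factor,
                 include_initial = isTRUE(include_initial)),
            class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("protocol_config:\n")
  cat(sprintf("  T = %g K, dt = %g fs, tau_t = %g ps, tau_p = %g ps\n",
              x$temperature, x$timestep_fs, x$tau_t_ps, x$tau_p_ps))
  cat(sprintf("  stages: min | NVT %g ns | NPT %g ns (%g bar) | re-box %g mM | min | production %g ns\n",
              x$nvt_ns, x$npt_ns, x$pressure_bar, x$rho_res_mM, x$production_ns))
  cat(sprintf("  sampling every %g ns, scale factor %g, seed %d\n",
              x$sampling_ns, x$scale_factor, x$seed))
  invisible(x)
}

new_trajectory <- function(frames, times, boxes, stage, seed, system) {
  structure(list(frames = frames, times = times, boxes = boxes,
                 stage = stage, seed = seed,
                 chain = system$chain, codes = system$codes,
                 sequence = system$sequence, periodic = system$periodic),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory [%s]: %d frames, %d beads, t = %.4g..%.4g ns\n",
              x$stage, length(x$frames), length(x$chain),
              if (length(x$times)) min(x$times) / 1000 else NA,
              if (length(x$times)) max(x$times) / 1000 else NA))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x a `cg_trajectory`.
#' @export
n_frames <- function(x) length(x$frames)

run_md_stage <- function(system, ff, config, duration_ns, stage, seed,
                         barostat = FALSE, sample_every_ns = NULL) {
  stopifnot(inherits(system, "cg_system"), inherits(config, "protocol_config"))
  if (duration_ns < 0) stop("duration must be non-negative")
  dt_ps <- config$timestep_fs * 1e-3
  n_steps <- round(duration_ns * 1000 / dt_ps)
  bv <- bead_vectors(ff, system$codes)
  if (is.null(system$vel)) {
    system <- assign_velocities(system, config$temperature, ff,
                                seed = seed + 7L)
  }
  if (n_steps == 0) {
    traj <- new_trajectory(list(system$pos), 0, system$box, stage, seed, system)
    attr(traj, "final_system") <- system
    return(traj)
  }
  if (is.null(sample_every_ns)) sample_every_ns <- config$sampling_ns
  sample_every <- max(1L, round(sample_every_ns * 1000 / dt_ps))
  gamma <- if (config$tau_t_ps > 0) 1 / config$tau_t_ps else 0
  res <- cpp_md(system$pos, system$vel, system$chain,
                bv$charge, bv$sigma, bv$lambda, bv$mass,
                system$box, system$periodic,
                ff$bond_b0, ff$bond_k, ff$epsilon, ff$eps_r, ff$kappa,
                ff$cutoff,
                as.integer(n_steps), dt_ps, config$temperature, gamma,
                barostat, config$tau_p_ps, config$pressure_bar,
                config$compressibility_bar,
                as.integer(sample_every), config$include_initial,
                as.integer(seed), 10L)
  final <- system
  final$pos <- res$final_pos
  final$vel <- res$final_vel
  final$box <- res$final_box
  traj <- new_trajectory(res$frames, res$times, res$boxes, stage, seed, system)
  attr(traj, "final_system") <- final
  attr(traj, "temperature_trace") <- res$temperature
  attr(traj, "energy_trace") <- res$total_energy
  traj
}

#' Constant-volume Langevin dynamics
#'
#' BAOAB-split Langevin integration at fixed box, friction `1/tau_t`.
#' Identical seed and configuration give a bit-identical trajectory.
#'
#' @param system a [cg_system()] (velocities drawn at the target temperature
#'   if absent).
#' @param ff a [forcefield()].
#' @param config a [protocol_config()].
#' @param duration_ns run length, ns (0 returns only the initial frame).
#' @param seed stage seed (default derived from config).
#' @return a `cg_trajectory`; the end state is in `attr(, "final_system")`.
#' @export
run_nvt <- function(system, ff = read_forcefield(), config = protocol_config(),
                    duration_ns = config$nvt_ns, seed = config$seed) {
  run_md_stage(system, ff, config, duration_ns, "nvt", seed, barostat = FALSE)
}

#' Constant-pressure Langevin dynamics (Berendsen barostat)
#'
#' As [run_nvt()] plus Berendsen weak-coupling box rescaling each step using
#' the configured compressibility; the instantaneous pressure comes from the
#' virial. Zero compressibility leaves the box fixed (reduces to NVT).
#'
#' @inheritParams run_nvt
#' @export
run_npt <- function(system, ff = read_forcefield(), config = protocol_config(),
                    duration_ns = config$npt_ns, seed = config$seed) {
  run_md_stage(system, ff, config, duration_ns, "npt", seed, barostat = TRUE)
}

#' Staged droplet-formation protocol
#'
#' Runs, in order: energy minimization; NVT equilibration; NPT compression
#' (Berendsen barostat) which condenses an attractive system toward liquid
#' density; re-boxing to the target total residue density (unwrap, recenter,
#' new cubic box); a second minimization; and the NVT production run sampled
#' at the configured interval. At the default configuration the production
#' stage yields 600 frames (3 us / 5 ns). All durations and the sampling
#' interval are multiplied by `config$scale_factor`, so desk-scale runs keep
#' the frame count.
#'
#' @param seq a [protein_sequence()]; the system is `n_copies` copies of it.
#' @param n_copies number of chains.
#' @param ff a [forcefield()].
#' @param config a [protocol_config()].
#' @param box initial cubic box edge (nm); default sized from the grid and
#'   chain dimensions.
#' @param seed master seed (default from config); per-stage streams derived.
#' @return object of class `droplet_protocol_result`: list with `stages`
#'   (names and durations), `minimized`, `nvt`, `npt`, `expanded`,
#'   `minimized2`, and `production` (a `cg_trajectory`).
#' @export
droplet_protocol <- function(seq, n_copies, ff = read_forcefield(),
                             config = protocol_config(), box = NULL,
                             seed = config$seed) {
  sf <- config$scale_factor
  L <- length(seq)
  if (is.null(box)) {
    # condensed start: the droplet is assembled at near-liquid density and
    # production then tests whether it survives in the dilute 80 mM cell
    m <- ceiling(n_copies^(1 / 3) - 1e-9)
    rg_ideal <- ff$bond_b0 * sqrt(L / 6)
    box <- m * (1.6 * rg_ideal + 0.4)
  }
  stage_fail <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("droplet protocol failed at stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  durations <- list(nvt = config$nvt_ns * sf, npt = config$npt_ns * sf,
                    production = config$production_ns * sf,
                    sampling = config$sampling_ns * sf)

  sys0 <- stage_fail("build", build_system(seq, n_copies, box, seed = seed, ff = ff))
  minimized <- stage_fail("minimization", minimize(sys0, ff, tol = config$min_tol))
  minimized$vel <- NULL
  nvt <- stage_fail("nvt", run_md_stage(minimized, ff, config, durations$nvt,
                                        "nvt", seed + 1L, barostat = FALSE,
                                        sample_every_ns = durations$sampling))
  npt <- stage_fail("npt", run_md_stage(attr(nvt, "final_system"), ff, config,
                                        durations$npt, "npt", seed + 2L,
                                        barostat = TRUE,
                                        sample_every_ns = durations$sampling))
  expanded <- stage_fail("re-box", set_box_density(attr(npt, "final_system"),
                                                   config$rho_res_mM, ff))
  vel_keep <- expanded$vel
  minimized2 <- stage_fail("minimization-2", minimize(expanded, ff,
                                                      tol = config$min_tol))
  minimized2$vel <- vel_keep
  production <- stage_fail("production",
    run_md_stage(minimized2, ff, config, durations$production, "production",
                 seed + 3L, barostat = FALSE,
                 sample_every_ns = durations$sampling))

  structure(list(
    stages = data.frame(
      stage = c("minimization", "nvt", "npt", "re-box", "minimization-2",
                "production"),
      duration_ns = c(NA, durations$nvt, durations$npt, NA, NA,
                      durations$production)),
    minimized = minimized, nvt = nvt, npt = npt, expanded = expanded,
    minimized2 = minimized2, production = production,
    seed = seed, config = config
  ), class = "droplet_protocol_result")
}

#' @export
print.droplet_protocol_result <- function(x, ...) {
  cat("droplet_protocol_result\n")
  print(x$stages)
  cat(sprintf("production: %d frames, box %.3g nm\n",
              n_frames(x$production), utils::tail(x$production$boxes, 1)))
  invisible(x)
}

#' Write a trajectory as extended XYZ
#'
#' One block per frame; the comment line carries the time (ps) and the cubic
#' box edge (nm).
#'
#' @param traj a `cg_trajectory`.
#' @param path output path.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(traj$chain)
  for (f in seq_along(traj$frames)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time_ps=%.6g box_nm=%.8g", traj$times[f], traj$boxes[f]), con)
    p <- traj$frames[[f]]
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$codes, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}
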