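# Seeded generators for every input class the pipeline consumes. Each
# generator is a pure function of its arguments plus the seed, and stores its
# ground truth alongside the data so recovery tests never recompute the truth
# independently.

#' Composition presets for synthetic disordered sequences
#'
#' `"tad_like"` emulates a Ser/Thr-rich, charge-depleted transactivation-
#' domain-like region (about 90% charged+polar, ~5% charged, ~10%
#' aliphatic); `"aliphatic_rich"` a strongly condensing sequence dominated by
#' A/I/L/P/V; `"polyanion"` a strongly dispersing acidic sequence. These are
#' synthetic fixtures, not any real protein's composition.
#'
#' @param preset preset name.
#' @return named probability vector over the 20 residue codes.
#' @export
composition_preset <- function(preset = c("tad_like", "aliphatic_rich",
                                          "polyanion")) {
  preset <- match.arg(preset)
  p <- setNames(rep(0, 20), AA_CODES)
  if (preset == "tad_like") {
    # 85% hydrophilic + 5% charged (=90% charged+polar), ~9% aliphatic
    p[c("S", "T", "Q", "N", "G", "H")] <- c(0.30, 0.19, 0.12, 0.07, 0.13, 0.04)
    p[c("K", "R", "D", "E")] <- c(0.02, 0.005, 0.0125, 0.0125)
    p[c("P", "A", "L", "V", "M", "C")] <- c(0.03, 0.025, 0.015, 0.01, 0.005, 0.005)
    p[c("F", "Y", "W")] <- c(0.004, 0.004, 0.002)
  } else if (preset == "aliphatic_rich") {
    p[c("A", "I", "L", "P", "V")] <- c(0.22, 0.15, 0.20, 0.13, 0.15)
    p[c("G", "S")] <- c(0.08, 0.07)
  } else {
    p[c("D", "E")] <- c(0.45, 0.45)
    p[c("G", "S")] <- c(0.05, 0.05)
  }
  p / sum(p)
}

#' Generate a random disordered-region-like sequence
#'
#' Multinomial draw from a residue composition. The realized composition is
#' stored in the `realized_composition` attribute (the generator's ground
#' truth).
#'
#' @param length sequence length.
#' @param composition named probability vector over residue codes (must sum
#'   to 1 within 1e-9); e.g. a [composition_preset()].
#' @param seed integer seed.
#' @param id sequence id.
#' @return a [protein_sequence()].
#' @export
gen_idr_sequence <- function(length, composition = composition_preset("tad_like"),
                             seed = 1L, id = "synthetic_idr") {
  if (any(composition < 0)) stop("probabilities must be non-negative")
  if (abs(sum(composition) - 1) > 1e-9) stop("probabilities must sum to 1")
  if (!all(names(composition) %in% AA_CODES)) stop("unknown residue code(s)")
  set.seed(as.integer(seed))
  draws <- sample(names(composition), size = length, replace = TRUE,
                  prob = composition)
  out <- protein_sequence(paste(draws, collapse = ""), id = id)
  attr(out, "realized_composition") <- table(factor(draws, levels = AA_CODES)) / length
  attr(out, "target_composition") <- composition
  out
}

#' Generate a freely-jointed-chain conformer ensemble
#'
#' Uniform random bond directions; every bond has length exactly `b`. Ideal-
#' chain theory gives `<Rg^2> = n_beads * b^2 / 6` for long chains, making
#' the ensemble an analytic oracle for scattering and Rg checks.
#'
#' @param n_conformers number of chains to draw.
#' @param n_beads beads per chain (>= 2).
#' @param b bond length, nm.
#' @param seed integer seed.
#' @return list of class `chain_ensemble`: `conformers` (list of N x 3
#'   matrices), `b`, `rg2` (per-conformer squared radius of gyration) and
#'   `mean_rg2`.
#' @export
gen_chain_ensemble <- function(n_conformers, n_beads, b = 0.38, seed = 1L) {
  stopifnot(n_beads >= 2, b > 0, n_conformers >= 1)
  set.seed(as.integer(seed))
  conf <- vector("list", n_conformers)
  rg2 <- numeric(n_conformers)
  for (k in seq_len(n_conformers)) {
    steps <- random_unit_vectors(n_beads - 1L) * b
    walk <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    walk <- sweep(walk, 2, colMeans(walk))
    conf[[k]] <- walk
    rg2[k] <- mean(rowSums(walk^2))
  }
  structure(list(conformers = conf, b = b, n_beads = n_beads, rg2 = rg2,
                 mean_rg2 = mean(rg2), seed = seed),
            class = "chain_ensemble")
}

# analytic form factors -----------------------------------------------------

saxs_model_intensity <- function(model, q, params) {
  switch(model,
    guinier = params$I0 * exp(-(q * params$Rg)^2 / 3),
    debye_chain = params$I0 * debye_fn((q * params$Rg)^2),
    sphere = {
      x <- q * params$R
      f <- ifelse(x < 1e-8, 1, 3 * (sin(x) - x * cos(x)) / x^3)
      params$I0 * f^2
    },
    stop("unknown model: ", model))
}

#' Generate a synthetic scattering curve with known ground truth
#'
#' Evaluates an analytic model (Guinier Gaussian, Debye ideal chain, or
#' homogeneous sphere) exactly, then applies multiplicative Gaussian noise of
#' the stated fraction; the sigma column is `noise * I`. The model, its
#' parameters and the noiseless curve are stored in the `truth` attribute.
#'
#' @param model `"guinier"`, `"debye_chain"` or `"sphere"`.
#' @param params list: `I0` and `Rg` (nm) for the first two, `I0` and `R`
#'   (sphere radius, nm) for the sphere.
#' @param q momentum-transfer grid, nm^-1.
#' @param noise multiplicative noise fraction (0 = exact).
#' @param seed integer seed.
#' @return a [scattering_curve()] with attribute `truth`.
#' @export
gen_saxs_curve <- function(model = c("guinier", "debye_chain", "sphere"),
                           params = list(I0 = 1, Rg = 5), q, noise = 0,
                           seed = 1L) {
  model <- match.arg(model)
  if (model %in% c("guinier", "debye_chain")) {
    if (is.null(params$Rg) || params$Rg <= 0) stop("params$Rg must be positive")
  } else if (is.null(params$R) || params$R <= 0) stop("params$R must be positive")
  if (is.null(params$I0)) params$I0 <- 1
  I_true <- saxs_model_intensity(model, q, params)
  I <- I_true
  if (noise > 0) {
    set.seed(as.integer(seed))
    I <- I_true * (1 + noise * stats::rnorm(length(q)))
  }
  out <- scattering_curve(q, I, sigma = if (noise > 0) noise * I_true else NULL)
  attr(out, "truth") <- list(model = model, params = params, I_true = I_true,
                             noise = noise, seed = seed)
  out
}

# Gaussian band helper
gauss_band <- function(wl, center, width, amplitude) {
  amplitude * exp(-0.5 * ((wl - center) / width)^2)
}

#' Synthetic CD basis spectra
#'
#' Two fixed synthetic shapes on a wavelength grid: a helix-like basis with
#' negative bands near 208 and 222 nm and a positive band near 193 nm, and a
#' coil-like basis with a negative band near 200 nm. These are Gaussian-band
#' constructions for testing spectrum arithmetic, not literature reference
#' sets.
#'
#' @param wavelength_nm wavelength grid (default 170-280 nm, 1 nm step).
#' @return list with `helix` and `coil` `cd_spectrum` objects (unit `"mre"`).
#' @export
cd_basis <- function(wavelength_nm = 170:280) {
  helix <- gauss_band(wavelength_nm, 193, 7, 60000) +
    gauss_band(wavelength_nm, 208, 6, -32000) +
    gauss_band(wavelength_nm, 222, 7, -33000)
  coil <- gauss_band(wavelength_nm, 198, 7, -40000) +
    gauss_band(wavelength_nm, 218, 10, 3000)
  list(helix = cd_spectrum(wavelength_nm, helix, unit = "mre"),
       coil = cd_spectrum(wavelength_nm, coil, unit = "mre"))
}

#' Generate a synthetic CD titration series
#'
#' Linear mixtures of the two synthetic basis shapes: for each row of
#' `weights` the spectrum is `w_helix * helix + w_coil * coil` plus optional
#' additive Gaussian noise. Ground truth (the weights and noiseless
#' mixtures) is stored in the `truth` attribute.
#'
#' @param weights matrix or data.frame with columns `helix` and `coil`, one
#'   row per titration point (weights >= 0).
#' @param fractions titration labels (e.g. percent TFE), one per row.
#' @param noise additive noise standard deviation (signal units).
#' @param seed integer seed.
#' @param wavelength_nm wavelength grid.
#' @return list of `list(fraction_tfe, spectrum)` entries, ready for
#'   [tfe_series()], with attribute `truth`.
#' @export
gen_cd_spectra <- function(weights, fractions = seq_len(nrow(weights)) - 1,
                           noise = 0, seed = 1L, wavelength_nm = 170:280) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("weights must be non-negative")
  stopifnot(ncol(weights) == 2, length(fractions) == nrow(weights))
  basis <- cd_basis(wavelength_nm)
  set.seed(as.integer(seed))
  out <- vector("list", nrow(weights))
  clean <- vector("list", nrow(weights))
  for (i in seq_len(nrow(weights))) {
    y <- weights[i, 1] * basis$helix$signal + weights[i, 2] * basis$coil$signal
    clean[[i]] <- y
    if (noise > 0) y <- y + stats::rnorm(length(y), sd = noise)
    out[[i]] <- list(fraction_tfe = fractions[i],
                     spectrum = cd_spectrum(wavelength_nm, y, unit = "mre"))
  }
  attr(out, "truth") <- list(weights = weights, clean = clean, noise = noise,
                             seed = seed)
  out
}
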