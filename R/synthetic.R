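# Synthetic functional series with known ground truth: harmonic coefficients
# drawn zero-mean normal with a power-law SD profile over wavenumber,
# optional band modulations (condition effects), optional within-band
# coupling through a shared latent time course, spatial white noise, and a
# paired multi-subject two-condition study design emulating a
# psychedelic-vs-placebo contrast (low-k suppression, high-k boost,
# repertoire broadening).

#' Spectral profile of coefficient magnitudes
#'
#' The SD of `alpha_k` is `amplitude * k^(-exponent) * exp(-k / cutoff_k)`
#' (cut-off term only if given), times any band modulation factors. `|alpha|`
#' is then half-normal, so mean power inherits the `k^(-exponent)` decay.
#'
#' @param exponent power-law exponent of the SD profile (default 1).
#' @param amplitude overall scale (> 0).
#' @param cutoff_k optional exponential tail cut-off wavenumber.
#' @param band_modulations list of `list(band = c(lo, hi), factor = f)` with
#'   fractional bands; factors multiply the SD of member harmonics.
#' @return object of class `spectral_profile`.
#' @export
spectral_profile <- function(exponent = 1, amplitude = 1, cutoff_k = NULL,
                             band_modulations = list()) {
  if (amplitude <= 0) chd_input_error("amplitude must be positive")
  for (bm in band_modulations)
    if (is.null(bm$band) || is.null(bm$factor) || bm$factor <= 0)
      chd_input_error("each band modulation needs a band and a positive factor")
  structure(list(exponent = exponent, amplitude = amplitude,
                 cutoff_k = cutoff_k, band_modulations = band_modulations),
            class = "spectral_profile")
}

#' Per-harmonic coefficient SDs implied by a profile
#'
#' @param profile a `spectral_profile`.
#' @param m number of harmonics.
#' @return numeric vector of length m.
#' @export
profile_sd <- function(profile, m) {
  k <- seq_len(m)
  s <- profile$amplitude * k^(-profile$exponent)
  if (!is.null(profile$cutoff_k)) s <- s * exp(-k / profile$cutoff_k)
  for (bm in profile$band_modulations) {
    idx <- band_indices(bm$band, m)
    s[idx] <- s[idx] * bm$factor
  }
  s
}

#' Generate one functional series with known coefficients
#'
#' Coefficients are `alpha_k(t) = sd_k * z_k(t)` with `z` standard normal;
#' with coupling, harmonics inside the band share a latent time course with
#' mixing weight `w`: `z_k = w * u + sqrt(1 - w^2) * eps_k`, giving pairwise
#' latent correlation `w^2` inside the band. The vertex-space series is
#' `F = Psi alpha + noise` with iid spatial white noise.
#'
#' @param basis a `harmonic_basis`.
#' @param profile a `spectral_profile`.
#' @param T number of time points (>= 2).
#' @param noise_sd SD of the additive vertex-space noise.
#' @param seed RNG seed.
#' @param coupling optional `list(band = c(lo, hi), weight = w)`.
#' @param m number of modes to drive (default: all basis modes).
#' @return list with `series` (a `functional_series`), `alpha` (ground-truth
#'   m x T matrix), `sd_k`.
#' @export
generate_series <- function(basis, profile, T = 210, noise_sd = 0.1, seed = 1,
                            coupling = NULL, m = basis$m) {
  if (T < 2) chd_input_error("T must be >= 2")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  sd_k <- profile_sd(profile, m)
  z <- matrix(stats::rnorm(m * T), m, T)
  if (!is.null(coupling) && coupling$weight > 0) {
    idx <- band_indices(coupling$band, m)
    w <- coupling$weight
    u <- stats::rnorm(T)
    z[idx, ] <- w * matrix(u, length(idx), T, byrow = TRUE) +
      sqrt(1 - w^2) * z[idx, , drop = FALSE]
  }
  alpha <- sd_k * z
  F <- basis$evectors[, seq_len(m), drop = FALSE] %*% alpha
  if (noise_sd > 0) F <- F + matrix(stats::rnorm(length(F), sd = noise_sd),
                                    nrow(F), ncol(F))
  list(series = functional_series(as.matrix(F)), alpha = alpha, sd_k = sd_k)
}

#' Paired two-condition study design
#'
#' Defaults state the emulated world: 12 subjects, paired scans in a
#' baseline condition `"A"` (placebo-like) and an effect condition `"B"`
#' that applies the band modulations x0.8 to the lowest 1% of wavenumbers
#' and x1.3 to the top 80%, plus within-band coupling (shared latent, mixing
#' weight 0.6) in the top band. Subjects differ by a lognormal overall
#' amplitude factor. All per-scan seeds derive from the master seed.
#'
#' @param n_subjects number of subjects (default 12).
#' @param T time points per scan (default 210, ~7 min at TR = 2 s).
#' @param noise_sd vertex-space noise SD (default 0.1).
#' @param baseline_profile `spectral_profile` of condition A.
#' @param effect_modulations band modulations added in condition B.
#' @param coupling_a,coupling_b coupling specs per condition (`NULL` = none).
#' @param subject_amplitude_sdlog lognormal SD of the per-subject amplitude.
#' @param seed master seed.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_subjects = 12, T = 210, noise_sd = 0.01,
                         baseline_profile = spectral_profile(exponent = 0.5, amplitude = 1),
                         effect_modulations = list(
                           list(band = c(0, 0.01), factor = 0.8),
                           list(band = c(0.2, 1), factor = 1.3)),
                         coupling_a = NULL,
                         coupling_b = list(band = c(0.2, 1), weight = 0.6),
                         subject_amplitude_sdlog = 0.2,
                         seed = 1) {
  if (n_subjects < 2) chd_input_error("need at least 2 subjects")
  structure(list(n_subjects = n_subjects, T = T, noise_sd = noise_sd,
                 baseline_profile = baseline_profile,
                 effect_modulations = effect_modulations,
                 coupling_a = coupling_a, coupling_b = coupling_b,
                 subject_amplitude_sdlog = subject_amplitude_sdlog,
                 seed = seed),
            class = "study_design")
}

#' Generate a paired two-condition synthetic study
#'
#' @param basis a `harmonic_basis`.
#' @param design a `study_design`.
#' @param vertex_space if `FALSE`, skip the vertex-space projection and
#'   return ground-truth coefficients only (faster; bypasses the
#'   decomposition stage).
#' @return object of class `synthetic_study`: `scans` (list with `subject`,
#'   `condition`, `series` or NULL, `alpha`, `sd_k`), `index` data.frame,
#'   `truth` (per-harmonic condition-B SD factor and the predicted pooled
#'   repertoire sigma ratio), `design`.
#' @export
generate_study <- function(basis, design, vertex_space = TRUE) {
  m <- basis$m
  n_scans <- design$n_subjects * 2
  seeds <- derive_seeds(design$seed, n_scans + 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seeds[n_scans + 1])
  amp <- exp(stats::rnorm(design$n_subjects, 0, design$subject_amplitude_sdlog))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  scans <- list()
  idx <- 0L
  for (s in seq_len(design$n_subjects)) {
    for (condition in c("A", "B")) {
      idx <- idx + 1L
      p <- design$baseline_profile
      p$amplitude <- p$amplitude * amp[s]
      coupling <- design$coupling_a
      if (condition == "B") {
        p$band_modulations <- c(p$band_modulations, design$effect_modulations)
        coupling <- design$coupling_b
      }
      g <- generate_series(basis, p, T = design$T, noise_sd = design$noise_sd,
                           seed = seeds[idx], coupling = coupling, m = m)
      scans[[idx]] <- list(subject = s, condition = condition,
                           series = if (vertex_space) g$series else NULL,
                           alpha = g$alpha, sd_k = g$sd_k)
    }
  }
  factor_b <- {
    pa <- design$baseline_profile
    pb <- pa; pb$band_modulations <- c(pb$band_modulations, design$effect_modulations)
    profile_sd(pb, m) / profile_sd(pa, m)
  }
  structure(list(
    scans = scans,
    index = data.frame(subject = vapply(scans, `[[`, integer(1), "subject"),
                       condition = vapply(scans, `[[`, character(1), "condition")),
    truth = list(sd_factor_b = factor_b,
                 repertoire_sigma_ratio = sqrt(mean(factor_b^2))),
    design = design), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d subjects x 2 conditions, T = %d\n",
              x$design$n_subjects, x$design$T))
  invisible(x)
}
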