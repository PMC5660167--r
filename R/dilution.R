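#' Tissue state for the aggregate-dilution model
#'
#' Minimal description of a muscle sample for reconciling a per-mass
#' aggregate assay (Seprion ELISA) with per-nucleus image statistics.
#' Hypertrophy (factor `h`) enlarges fibres at constant myonuclei per fibre,
#' so the density of nuclei per unit mass falls as 1/h; a satellite-cell
#' fraction of aggregate-free nuclei further discounts the per-mass signal.
#'
#' @param nuclei_per_mg baseline (h = 1) nuclear density per mg tissue.
#' @param load_per_nucleus aggregate load per aggregate-bearing nucleus,
#'   arbitrary units.
#' @param hypertrophy_factor h > 0; 1 is the untreated baseline.
#' @param satellite_fraction fraction of nuclei that are aggregate-free
#'   satellite (Pax7+) nuclei, in [0, 1).
#' @return An object of class `tissue_state`.
#' @export
tissue_state <- function(nuclei_per_mg, load_per_nucleus,
                         hypertrophy_factor = 1, satellite_fraction = 0) {
  stopifnot_scalar(nuclei_per_mg, "nuclei_per_mg", lo = 1e-12)
  stopifnot_scalar(load_per_nucleus, "load_per_nucleus", lo = 0)
  stopifnot_scalar(hypertrophy_factor, "hypertrophy_factor", lo = 1e-12)
  stopifnot_scalar(satellite_fraction, "satellite_fraction", 0, 1 - 1e-12)
  structure(list(nuclei_per_mg = nuclei_per_mg,
                 load_per_nucleus = load_per_nucleus,
                 hypertrophy_factor = hypertrophy_factor,
                 satellite_fraction = satellite_fraction),
            class = "tissue_state")
}

#' Per-mass aggregate signal
#'
#' The model of the per-mass ELISA readout:
#' `signal = nuclei_per_mg / h * (1 - satellite_fraction) * load_per_nucleus`.
#' Linear in the per-nucleus load and proportional to 1/h: doubling fibre
#' volume at constant per-nucleus aggregation halves the per-mass signal
#' without any change in the aggregation process itself.
#'
#' @param state a [tissue_state()].
#' @return Aggregate units per mg (scalar).
#' @export
per_mass_signal <- function(state) {
  stopifnot(inherits(state, "tissue_state"))
  state$nuclei_per_mg / state$hypertrophy_factor *
    (1 - state$satellite_fraction) * state$load_per_nucleus
}

#' Reconcile per-mass and per-nucleus treatment ratios
#'
#' Classifies the joint pattern of a per-mass assay ratio (treated/vehicle)
#' and a per-nucleus image ratio. A drop in the per-mass signal with an
#' unchanged per-nucleus load is `"dilution"` (hypertrophy spreading a fixed
#' aggregation process over more tissue mass); a drop in both is
#' `"disease-modifying"`; anything else is `"mixed"`.
#'
#' @param elisa_ratio treated/vehicle per-mass signal (> 0).
#' @param image_ratio treated/vehicle per-nucleus aggregate load (> 0); the
#'   image-derived load per nucleus is
#'   `mean_nuclear_inclusion_px * pct_nuclei_with_inclusions / 100`
#'   (see [nuclear_load_from_stats()]).
#' @param tol relative tolerance defining "unchanged" (default 0.1).
#' @return A list with `verdict` ("dilution", "disease-modifying" or
#'   "mixed"), and the two ratios and tolerance.
#' @export
reconcile <- function(elisa_ratio, image_ratio, tol = 0.1) {
  stopifnot_scalar(elisa_ratio, "elisa_ratio", lo = 1e-12)
  stopifnot_scalar(image_ratio, "image_ratio", lo = 1e-12)
  stopifnot_scalar(tol, "tol", 0, 1)
  verdict <- if (elisa_ratio < 1 - tol && image_ratio >= 1 - tol) "dilution"
             else if (elisa_ratio < 1 - tol && image_ratio < 1 - tol)
               "disease-modifying"
             else "mixed"
  list(verdict = verdict, elisa_ratio = elisa_ratio,
       image_ratio = image_ratio, tol = tol)
}

#' Image-derived aggregate load per nucleus
#'
#' Maps per-ROI (or per-mouse mean) image statistics to the model's
#' per-nucleus load: mean nuclear-inclusion size times the fraction of
#' nuclei carrying an inclusion. Uses only the nuclear-inclusion panel
#' quantities of the ROI summary.
#'
#' @param mean_nuclear_inclusion_px mean nuclear inclusion size, pixels.
#' @param pct_nuclei_with_inclusions percentage of nuclei with an inclusion.
#' @return Load per nucleus (pixel units).
#' @export
nuclear_load_from_stats <- function(mean_nuclear_inclusion_px,
                                    pct_nuclei_with_inclusions) {
  mean_nuclear_inclusion_px * pct_nuclei_with_inclusions / 100
}

#' Simulate replicate per-mass ELISA signals
#'
#' Multiplicative lognormal noise with coefficient of variation `cv` around
#' the closed-form [per_mass_signal()] of each state (the noise factor has
#' mean 1, so the replicate mean converges to the closed form).
#'
#' @param states a list of [tissue_state()]s.
#' @param cv coefficient of variation (>= 0; 0 gives exact signals).
#' @param n_replicates replicates per state (>= 1).
#' @param seed integer seed or NULL.
#' @return A data.frame with columns `state`, `replicate`, `signal`.
#' @export
simulate_elisa <- function(states, cv, n_replicates, seed = NULL) {
  if (inherits(states, "tissue_state")) states <- list(states)
  stopifnot(length(states) >= 1L,
            all(vapply(states, inherits, TRUE, "tissue_state")))
  stopifnot_scalar(cv, "cv", lo = 0)
  stopifnot_scalar(n_replicates, "n_replicates", lo = 1, integer = TRUE)
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    res <- lapply(seq_along(states), function(i) {
      mu <- per_mass_signal(states[[i]])
      noise <- if (cv == 0) rep(1, n_replicates)
               else exp(stats::rnorm(n_replicates, -sdlog^2 / 2, sdlog))
      data.frame(state = i, replicate = seq_len(n_replicates),
                 signal = mu * noise)
    })
    do.call(rbind, res)
  })
}
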