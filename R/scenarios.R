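# Benchmark study conditions. These constructors freeze the synthetic
# acquisition regimes used to validate each stage of the pipeline; the test
# suite and the acceptance script both draw on them so the conditions are
# defined exactly once.

#' Synthetic study conditions for pipeline validation
#'
#' Frozen [synth_config()] presets emulating the acquisition regimes the
#' pipeline is validated against:
#'
#' * `scenario_distribution()` — three-cell images of rod-shaped vesicles at
#'   SNR 10 (vesicle peak / read-noise sd), either `"clustered"`
#'   (perinuclear/intermediate/periphery signal fractions 0.8/0.1/0.05) or
#'   `"uniform"` (0.2/0.3/0.4).
#' * `scenario_counting()` — two cells, 25 well-separated (>= 2 um)
#'   diffraction-limited spots each, SNR 10; for vesicles-per-nucleus
#'   counting.
#' * `scenario_coloc()` — two vesicle channels of 20 spots per cell with a
#'   configurable fraction of green spots placed on red centres;
#'   non-colocalized green spots are kept >= 3 um from every red centre.
#' * `scenario_oval()` — single-cell images for the radial-profile
#'   clustering readout: `"clustered"` packs 90% of the signal into a
#'   60-degree perinuclear sector (dense, overlapping vesicles, as in a
#'   microtubule-organizing-centre heap); `"cytosolic"` renders no discrete
#'   vesicles, only a bright diffuse cloud. Both share the same absolute
#'   camera read noise, since they emulate one acquisition regime.
#'
#' @param condition,phenotype which experimental condition to emulate.
#' @param seed RNG seed for the image.
#' @param coloc_fraction fraction of green spots placed on red spots.
#' @param noise_sd read-noise sd for the colocalization scenario (0 gives
#'   the noise-free variant).
#' @return a [synth_config()].
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_distribution <- function(condition = c("clustered", "uniform"),
                                  seed = 1) {
  condition <- match.arg(condition)
  fr <- if (condition == "clustered") c(0.8, 0.1, 0.05) else c(0.2, 0.3, 0.4)
  cfg <- synth_config(seed = seed, zone_intensity_fractions = fr,
                      vesicle_intensity = 20000)
  cfg$noise_sd <- vesicle_peak_amplitude(cfg) / 10
  cfg
}

#' @rdname scenarios
#' @export
scenario_counting <- function(seed = 1) {
  cfg <- synth_config(seed = seed, n_cells = 2, n_vesicles_per_cell = 25,
                      vesicle_shape = "spot", vesicle_sigma_um = 0.45,
                      min_separation_um = 2, vesicle_intensity = 20000,
                      zone_intensity_fractions = c(0.2, 0.3, 0.5))
  cfg$noise_sd <- vesicle_peak_amplitude(cfg) / 10
  cfg
}

#' @rdname scenarios
#' @export
scenario_coloc <- function(coloc_fraction, seed = 1, noise_sd = NULL) {
  cfg <- synth_config(seed = seed, n_cells = 2, n_vesicles_per_cell = 20,
                      vesicle_shape = "spot", vesicle_sigma_um = 0.45,
                      min_separation_um = 2, vesicle_intensity = 20000,
                      n_vesicle_channels = 2, coloc_fraction = coloc_fraction,
                      noncoloc_min_dist_um = 2,
                      zone_intensity_fractions = c(0.1, 0.3, 0.6))
  cfg$noise_sd <- if (is.null(noise_sd)) {
    vesicle_peak_amplitude(cfg) / 10
  } else noise_sd
  cfg
}

#' @rdname scenarios
#' @export
scenario_oval <- function(phenotype = c("clustered", "cytosolic"), seed = 1) {
  phenotype <- match.arg(phenotype)
  if (phenotype == "clustered") {
    synth_config(seed = seed, n_cells = 1, n_vesicles_per_cell = 20,
                 image_size_px = c(160, 160), min_separation_um = 0.3,
                 zone_intensity_fractions = c(0.9, 0.05, 0.05),
                 cluster_sector_deg = 60, vesicle_intensity = 20000,
                 noise_sd = 50)
  } else {
    synth_config(seed = seed, n_cells = 1, n_vesicles_per_cell = 0,
                 image_size_px = c(160, 160),
                 zone_intensity_fractions = c(0, 0, 0),
                 diffuse_intensity = 2e6, noise_sd = 50)
  }
}

#' Oval-profile clustering readout for one synthetic image
#'
#' Convenience wrapper chaining background subtraction, the nucleus oval
#' fit and the radial-sum classification for a generated image.
#'
#' @param generated output of [generate_image()].
#' @param channel vesicle channel to profile (default `"red"`).
#' @param peak_ratio_threshold passed to [classify_clustering()].
#' @return list from [classify_clustering()].
#' @export
classify_generated_image <- function(generated, channel = "red",
                                     peak_ratio_threshold = 2) {
  sub <- subtract_background(generated$image$channels[[channel]])
  oval <- fit_nucleus_oval(generated$truth$nucleus_mask)
  prof <- radial_sum_profile(sub, oval)
  classify_clustering(prof, peak_ratio_threshold)
}
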