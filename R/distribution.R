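#' Per-particle distance and intensity measurement
#'
#' For every labeled vesicle particle, measures the minimum distance-map
#' value over its pixels ("Distance (Min)"), the integrated intensity
#' ("IntDen", sum of channel values over its pixels), the area and the
#' centroid.
#'
#' @param labels integer label matrix (0 = background).
#' @param channel numeric matrix sampled for intensities (typically the
#'   background-subtracted vesicle channel).
#' @param dmap distance map from [distance_map()].
#' @return data.frame with columns `label`, `min_distance_px`,
#'   `integrated_intensity`, `area_px`, `centroid_row`, `centroid_col`.
#' @export
measure_particles <- function(labels, channel, dmap) {
  labels <- as_pixel_matrix(labels)
  channel <- as_pixel_matrix(channel)
  dmap <- as_pixel_matrix(dmap)
  if (!identical(dim(labels), dim(channel)) ||
      !identical(dim(labels), dim(dmap))) {
    stop("labels, channel and distance map must have identical shapes")
  }
  idx <- which(labels > 0)
  if (!length(idx)) {
    return(data.frame(label = integer(0), min_distance_px = numeric(0),
                      integrated_intensity = numeric(0), area_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  }
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- (idx - 1) %% nr + 1
  cols <- (idx - 1) %/% nr + 1
  n <- max(lab)
  area <- tabulate(lab, nbins = n)
  keep <- which(area > 0)
  data.frame(
    label = keep,
    min_distance_px = vapply(split(dmap[idx], lab), min, 1)[as.character(keep)],
    integrated_intensity = vapply(split(channel[idx], lab), sum, 1)[as.character(keep)],
    area_px = area[keep],
    centroid_row = (rowsum(rows, lab) / area[sort(unique(lab))])[, 1],
    centroid_col = (rowsum(cols, lab) / area[sort(unique(lab))])[, 1],
    row.names = NULL
  )
}

#' Assign radial zones from nucleus distances
#'
#' Converts pixel distances to micrometres and bins them into the three
#' radial zones: perinuclear (x < 2 um), intermediate (2 um < x < 5 um) and
#' periphery (x > 5 um). Distances falling exactly on a boundary are
#' assigned to the nearer-nucleus zone.
#'
#' @param min_distance_px numeric vector of distances in pixels (>= 0).
#' @param pixel_size_um micrometres per pixel (> 0); use 1 with boundaries
#'   expressed in pixels to reproduce a purely pixel-based binning.
#' @param boundaries_um zone edges, default `c(2, 5)`.
#' @return factor with levels perinuclear / intermediate / periphery.
#' @export
assign_zone <- function(min_distance_px, pixel_size_um,
                        boundaries_um = c(2, 5)) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (any(min_distance_px < 0)) stop("distances must be >= 0")
  x <- min_distance_px * pixel_size_um
  zone <- ifelse(x <= boundaries_um[1], "perinuclear",
                 ifelse(x <= boundaries_um[2], "intermediate", "periphery"))
  factor(zone, levels = c("perinuclear", "intermediate", "periphery"))
}

#' Zone-wise normalized intensity distribution
#'
#' Sums per-particle integrated intensities within each radial zone and
#' normalizes by the total fluorescence intensity of the image, yielding
#' the fraction of the image's signal residing in each zone.
#'
#' @param particles data.frame from [measure_particles()].
#' @param total_image_intensity total fluorescence of the (background-
#'   subtracted) vesicle channel (> 0).
#' @param pixel_size_um micrometres per pixel.
#' @param boundaries_um zone edges, default `c(2, 5)`.
#' @return one-row data.frame: `perinuclear`, `intermediate`, `periphery`
#'   fractions plus `n_perinuclear`, `n_intermediate`, `n_periphery`
#'   particle counts and `n_particles`.
#' @export
zone_distribution <- function(particles, total_image_intensity,
                              pixel_size_um, boundaries_um = c(2, 5)) {
  if (total_image_intensity <= 0) {
    stop("total_image_intensity must be > 0")
  }
  lv <- c("perinuclear", "intermediate", "periphery")
  if (!nrow(particles)) {
    out <- as.data.frame(as.list(stats::setNames(rep(0, 3), lv)))
    out[paste0("n_", lv)] <- 0L
    out$n_particles <- 0L
    return(out)
  }
  zone <- assign_zone(particles$min_distance_px, pixel_size_um, boundaries_um)
  sums <- tapply(particles$integrated_intensity, zone, sum, default = 0)
  counts <- table(zone)
  out <- as.data.frame(as.list(sums[lv] / total_image_intensity))
  names(out) <- lv
  out[paste0("n_", lv)] <- as.integer(counts[lv])
  out$n_particles <- nrow(particles)
  out
}

#' Aggregate zone distributions over images and biological repeats
#'
#' Mirrors the hierarchical averaging of the analysis: per-image fractions
#' are first averaged within each biological repeat, then the repeat means
#' are averaged and reported as mean +/- SEM (sample sd / sqrt(n_repeats)).
#'
#' @param distributions data.frame with one row per image: columns
#'   `repeat_id`, `perinuclear`, `intermediate`, `periphery` (e.g. stacked
#'   outputs of [zone_distribution()]).
#' @return data.frame with one row per zone: `zone`, `mean`, `sem`,
#'   `n_repeats`, `n_images`.
#' @export
aggregate_zone_distributions <- function(distributions) {
  lv <- c("perinuclear", "intermediate", "periphery")
  if (!nrow(distributions)) stop("no images to aggregate")
  if (!"repeat_id" %in% names(distributions)) {
    stop("distributions must carry a repeat_id column")
  }
  rep_means <- do.call(rbind, lapply(split(distributions, distributions$repeat_id),
                                     function(d) colMeans(d[lv])))
  n_rep <- nrow(rep_means)
  if (n_rep == 1) {
    warning("single biological repeat: SEM reported as 0")
    sem <- rep(0, 3)
  } else {
    sem <- apply(rep_means, 2, stats::sd) / sqrt(n_rep)
  }
  data.frame(zone = factor(lv, levels = lv),
             mean = as.numeric(colMeans(rep_means)),
             sem = as.numeric(sem),
             n_repeats = n_rep, n_images = nrow(distributions),
             row.names = NULL)
}

#' Default parameters of the distribution pipeline
#'
#' All paper-gap defaults live here: background similarity band k = 4,
#' nucleus median-filter radius 2, watershed on for nuclei, off for
#' vesicle channels, 2/5 um zone boundaries.
#'
#' @param nucleus_channel name of the nucleus channel.
#' @param ... overrides for any default.
#' @return named list of parameters.
#' @export
distribution_config <- function(nucleus_channel = "dapi", ...) {
  cfg <- list(
    nucleus_channel = nucleus_channel,
    background_k = 4,
    background_roi = NULL,          # NULL = automatic lowest-tile ROI
    nucleus_median_radius = 2,
    nucleus_watershed = TRUE,
    nucleus_min_area_px = 50,
    vesicle_watershed = FALSE,
    boundaries_um = c(2, 5),
    distance_clip_px = 255,
    min_particle_area_px = 1
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full zone-distribution pipeline on one image
#'
#' Automates the distribution macro: nucleus segmentation (isodata
#' threshold, median filter, watershed), Euclidean distance map, then for
#' each vesicle channel background subtraction, Max Entropy segmentation,
#' per-particle Distance (Min) / IntDen measurement, three-zone binning and
#' normalization by the total image fluorescence.
#'
#' @param image a [multichannel_image()] containing the nucleus channel and
#'   at least one vesicle channel.
#' @param config list from [distribution_config()].
#' @param keep_intermediates return masks, distance map and particle tables
#'   alongside the fractions (default FALSE).
#' @return data.frame with one row per vesicle channel (`channel` plus the
#'   columns of [zone_distribution()]); if `keep_intermediates`, a list
#'   with `distribution`, `particles`, `dmap`, `nucleus`.
#' @export
run_distribution_pipeline <- function(image, config = distribution_config(),
                                      keep_intermediates = FALSE) {
  stopifnot(inherits(image, "multichannel_image"))
  if (!config$nucleus_channel %in% names(image$channels)) {
    stop("nucleus stage: channel '", config$nucleus_channel, "' not found")
  }
  ves_names <- setdiff(names(image$channels), config$nucleus_channel)
  if (!length(ves_names)) stop("nucleus stage: no vesicle channels present")

  nuc <- nucleus_mask(image$channels[[config$nucleus_channel]],
                      median_radius_px = config$nucleus_median_radius,
                      watershed = config$nucleus_watershed,
                      min_area_px = config$nucleus_min_area_px)
  if (sum(nuc$mask) == 0) stop("nucleus stage: no nucleus found")
  dmap <- distance_map(nuc$mask, clip = config$distance_clip_px)

  results <- list()
  particles_all <- list()
  for (ch in ves_names) {
    raw <- image$channels[[ch]]
    bg <- if (is.null(config$background_roi)) NULL else {
      estimate_background(raw, config$background_roi)
    }
    sub <- subtract_background(raw, bg, similarity_k = config$background_k)
    total <- sum(sub)
    if (total <= 0 || length(unique(as.vector(sub))) < 2) {
      # empty channel: no signal, no particles
      zd <- zone_distribution(
        data.frame(label = integer(0), min_distance_px = numeric(0),
                   integrated_intensity = numeric(0), area_px = integer(0)),
        total_image_intensity = 1, pixel_size_um = image$pixel_size_um,
        boundaries_um = config$boundaries_um)
      results[[ch]] <- cbind(channel = ch, zd)
      next
    }
    thr <- threshold_max_entropy(sub)
    mask <- matrix(as.integer(sub > thr), nrow(sub), ncol(sub))
    labels <- if (config$vesicle_watershed) watershed_split(mask) else {
      label_components(mask)
    }
    pt <- measure_particles(labels, sub, dmap)
    if (config$min_particle_area_px > 1) {
      pt <- pt[pt$area_px >= config$min_particle_area_px, , drop = FALSE]
    }
    pt$zone <- assign_zone(pt$min_distance_px, image$pixel_size_um,
                           config$boundaries_um)
    pt$min_distance_um <- pt$min_distance_px * image$pixel_size_um
    zd <- zone_distribution(pt, total, image$pixel_size_um,
                            config$boundaries_um)
    results[[ch]] <- cbind(channel = ch, zd)
    particles_all[[ch]] <- pt
  }
  distribution <- do.call(rbind, results)
  rownames(distribution) <- NULL
  if (keep_intermediates) {
    list(distribution = distribution, particles = particles_all,
         dmap = dmap, nucleus = nuc)
  } else {
    distribution
  }
}
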