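#' Configuration for the synthetic image generator
#'
#' Builds and validates the parameter set describing one synthetic
#' acquisition: wide-field-like multi-channel images of endothelial cells
#' with elliptical nuclei and spot- or rod-shaped cytoplasmic vesicles
#' (Weibel-Palade bodies are cigar-shaped, roughly 1-3 um long). The
#' generator controls how the total vesicle-channel signal is split across
#' the three radial zones used by the distribution analysis, so that every
#' downstream measurement has an exact ground truth.
#'
#' @param image_size_px `c(height, width)` in pixels.
#' @param pixel_size_um micrometres per pixel (default 0.3, plausible for a
#'   40x wide-field acquisition).
#' @param bit_depth 8 or 16 (default 16).
#' @param n_cells number of cells (nuclei) per image.
#' @param nucleus_axes_um semi-axes `c(major, minor)` of the nuclear ellipse.
#' @param n_vesicles_per_cell vesicles rendered per cell in each vesicle
#'   channel.
#' @param vesicle_shape `"rod"` or `"spot"`.
#' @param vesicle_length_um rod length (ignored for spots).
#' @param vesicle_sigma_um Gaussian blur sigma of the rendered vesicle.
#' @param vesicle_intensity total integrated counts per vesicle above
#'   background.
#' @param zone_intensity_fractions fractions `c(perinuclear, intermediate,
#'   periphery)` of the channel's signal placed in each zone; each in
#'   \[0, 1\], summing to <= 1. The remainder is rendered as a diffuse
#'   cytosolic component (broad Gaussian around each nucleus).
#' @param zone_boundaries_um zone bin edges, default `c(2, 5)`.
#' @param diffuse_sigma_um sigma of the diffuse cytosolic component.
#' @param diffuse_intensity absolute diffuse (cytosolic) signal budget per
#'   channel per image, in counts; `NULL` (default) derives it from the
#'   remainder of `zone_intensity_fractions`. Set it with
#'   `n_vesicles_per_cell = 0` to emulate a purely cytosolic construct.
#' @param cluster_sector_deg if not `NULL`, vesicles of each cell are
#'   confined to an angular sector of this width (degrees) at a random
#'   orientation, emulating clustering at a microtubule organizing centre.
#' @param orientation rod orientation: `"tangential"` (to the nucleus, with
#'   +/- 15 degree jitter; keeps the radial footprint compact) or
#'   `"random"`.
#' @param min_separation_um minimum distance between vesicle centres.
#' @param n_vesicle_channels 1 (`"red"`) or 2 (`"red"` then `"green"`).
#' @param coloc_fraction fraction of green-channel vesicles placed exactly
#'   at red-channel vesicle centres (two-channel configurations only).
#' @param noncoloc_min_dist_um minimum distance of non-colocalized green
#'   vesicles from every red centre.
#' @param channel_offsets_um lateral `c(dy, dx)` shift applied to the green
#'   channel's rendered positions.
#' @param nucleus_intensity plateau intensity of the nucleus channel.
#' @param background_level constant background offset (counts).
#' @param noise_sd Gaussian read-noise standard deviation (counts).
#' @param poisson also apply Poisson (shot) noise (default FALSE).
#' @param seed RNG seed; identical config + seed gives bit-identical output.
#' @return validated list of class `synthetic_config`.
#' @export
synth_config <- function(image_size_px = c(256, 256),
                         pixel_size_um = 0.3,
                         bit_depth = 16,
                         n_cells = 3,
                         nucleus_axes_um = c(5, 3.5),
                         n_vesicles_per_cell = 30,
                         vesicle_shape = c("rod", "spot"),
                         vesicle_length_um = 1.5,
                         vesicle_sigma_um = 0.15,
                         vesicle_intensity = 5000,
                         zone_intensity_fractions = c(0.5, 0.3, 0.1),
                         zone_boundaries_um = c(2, 5),
                         diffuse_sigma_um = 8,
                         diffuse_intensity = NULL,
                         cluster_sector_deg = NULL,
                         orientation = c("tangential", "random"),
                         min_separation_um = 1,
                         n_vesicle_channels = 1,
                         coloc_fraction = 0,
                         noncoloc_min_dist_um = 3,
                         channel_offsets_um = c(0, 0),
                         nucleus_intensity = 3000,
                         background_level = 100,
                         noise_sd = 0,
                         poisson = FALSE,
                         seed = 1) {
  vesicle_shape <- match.arg(vesicle_shape)
  orientation <- match.arg(orientation)
  cfg <- list(
    image_size_px = as.integer(image_size_px), pixel_size_um = pixel_size_um,
    bit_depth = as.integer(bit_depth), n_cells = as.integer(n_cells),
    nucleus_axes_um = nucleus_axes_um,
    n_vesicles_per_cell = as.integer(n_vesicles_per_cell),
    vesicle_shape = vesicle_shape, vesicle_length_um = vesicle_length_um,
    vesicle_sigma_um = vesicle_sigma_um, vesicle_intensity = vesicle_intensity,
    zone_intensity_fractions = zone_intensity_fractions,
    zone_boundaries_um = zone_boundaries_um,
    diffuse_sigma_um = diffuse_sigma_um, diffuse_intensity = diffuse_intensity,
    cluster_sector_deg = cluster_sector_deg, orientation = orientation,
    min_separation_um = min_separation_um,
    n_vesicle_channels = as.integer(n_vesicle_channels),
    coloc_fraction = coloc_fraction,
    noncoloc_min_dist_um = noncoloc_min_dist_um,
    channel_offsets_um = channel_offsets_um,
    nucleus_intensity = nucleus_intensity,
    background_level = background_level,
    noise_sd = noise_sd, poisson = isTRUE(poisson), seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      length(image_size_px) == 2, all(image_size_px > 0),
      pixel_size_um > 0, bit_depth %in% c(8, 16), n_cells >= 1,
      length(nucleus_axes_um) == 2, all(nucleus_axes_um > 0),
      n_vesicles_per_cell >= 0, vesicle_length_um > 0, vesicle_sigma_um > 0,
      vesicle_intensity > 0,
      length(zone_intensity_fractions) == 3,
      all(zone_intensity_fractions >= 0), all(zone_intensity_fractions <= 1),
      sum(zone_intensity_fractions) <= 1 + 1e-12,
      length(zone_boundaries_um) == 2, zone_boundaries_um[1] > 0,
      zone_boundaries_um[2] > zone_boundaries_um[1],
      diffuse_sigma_um > 0, min_separation_um >= 0,
      n_vesicle_channels %in% c(1, 2),
      coloc_fraction >= 0, coloc_fraction <= 1,
      length(channel_offsets_um) == 2,
      background_level >= 0, noise_sd >= 0
    )
  })
  if (!is.null(cfg$cluster_sector_deg)) {
    stopifnot(cfg$cluster_sector_deg > 0, cfg$cluster_sector_deg <= 360)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# ---- rendering primitives ---------------------------------------------------

# Add a pixel-integrated 2-D Gaussian of total `mass` centred at subpixel
# (r0, c0) into `img` (patch of +/- 4 sigma; exact mass up to tail truncation).
render_gaussian <- function(img, r0, c0, sigma_px, mass) {
  h <- ceiling(4 * sigma_px)
  rs <- max(1, floor(r0) - h):min(nrow(img), floor(r0) + h + 1)
  cs <- max(1, floor(c0) - h):min(ncol(img), floor(c0) + h + 1)
  wr <- stats::pnorm(rs + 0.5, r0, sigma_px) - stats::pnorm(rs - 0.5, r0, sigma_px)
  wc <- stats::pnorm(cs + 0.5, c0, sigma_px) - stats::pnorm(cs - 0.5, c0, sigma_px)
  img[rs, cs] <- img[rs, cs] + mass * outer(wr, wc)
  img
}

# Render one vesicle on a standalone patch; returns the patch, its placement,
# and the total rendered mass.
render_vesicle_patch <- function(cfg, r0, c0, phi) {
  sigma_px <- cfg$vesicle_sigma_um / cfg$pixel_size_um
  if (cfg$vesicle_shape == "spot") {
    half <- ceiling(4 * sigma_px) + 1L
    patch <- matrix(0, 2 * half + 1, 2 * half + 1)
    patch <- render_gaussian(patch, half + 1 + (r0 - round(r0)),
                             half + 1 + (c0 - round(c0)), sigma_px,
                             cfg$vesicle_intensity)
  } else {
    len_px <- cfg$vesicle_length_um / cfg$pixel_size_um
    half <- ceiling(len_px / 2 + 4 * sigma_px) + 1L
    patch <- matrix(0, 2 * half + 1, 2 * half + 1)
    k <- max(3L, ceiling(len_px / 0.2))
    t <- seq(-len_px / 2, len_px / 2, length.out = k)
    pr <- half + 1 + (r0 - round(r0)) + t * sin(phi)
    pc <- half + 1 + (c0 - round(c0)) + t * cos(phi)
    for (i in seq_len(k)) {
      patch <- render_gaussian(patch, pr[i], pc[i], sigma_px,
                               cfg$vesicle_intensity / k)
    }
  }
  list(patch = patch, half = (nrow(patch) - 1L) / 2L)
}

# Blit a patch centred at integer pixel (rr, cc) into img (no clipping
# expected; placement margins keep patches inside the frame).
blit_patch <- function(img, patch, half, rr, cc) {
  rs <- (rr - half):(rr + half)
  cs <- (cc - half):(cc + half)
  img[rs, cs] <- img[rs, cs] + patch
  img
}

largest_remainder_counts <- function(n, fractions) {
  if (n == 0 || sum(fractions) <= 0) return(rep(0L, length(fractions)))
  f <- fractions / sum(fractions)
  base <- floor(n * f)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * f - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# ---- generator --------------------------------------------------------------

#' Generate one synthetic multi-channel image with ground truth
#'
#' Renders `n_cells` blurred elliptical nuclei, then places vesicles in the
#' perinuclear / intermediate / periphery distance zones so that each zone
#' receives the configured fraction of the channel's total signal; the
#' remainder is rendered as a diffuse cytosolic cloud. Noise is applied
#' last; the ground truth describes the noise-free rendering.
#'
#' Ground-truth zone labels are assigned from the minimum distance of each
#' vesicle's rendered half-maximum footprint to the nucleus mask — the same
#' quantity ("Distance (Min)") the analysis pipeline measures.
#'
#' @param config a [synth_config()].
#' @return list with elements `image` (a [multichannel_image()]) and
#'   `truth` (vesicle table, cell table, colocalization pairs, per-channel
#'   zone fractions, and the nucleus mask used for placement).
#' @export
generate_image <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  nr <- cfg$image_size_px[1]; nc <- cfg$image_size_px[2]
  ps <- cfg$pixel_size_um
  a_px <- cfg$nucleus_axes_um[1] / ps
  b_px <- cfg$nucleus_axes_um[2] / ps

  # --- nuclei ---
  border <- ceiling(a_px + (cfg$zone_boundaries_um[2] + 2) / ps)
  if (2 * border >= min(nr, nc)) {
    stop("image too small for the requested nucleus and zone geometry")
  }
  min_sep <- 2 * a_px + 3 / ps
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(cfg$n_cells)) {
    placed <- FALSE
    for (try in 1:2000) {
      cand <- c(stats::runif(1, border, nr - border),
                stats::runif(1, border, nc - border))
      if (!nrow(centers) ||
          all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                             byrow = TRUE))^2)) >= min_sep)) {
        centers <- rbind(centers, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("placement failure: could not fit ", cfg$n_cells,
                      " nuclei in the image")
  }
  thetas <- stats::runif(cfg$n_cells, 0, pi)
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  nuc_labels <- matrix(0L, nr, nc)
  for (i in seq_len(cfg$n_cells)) {
    dy <- rowg - centers[i, 1]; dx <- colg - centers[i, 2]
    xr <- dx * cos(thetas[i]) + dy * sin(thetas[i])
    yr <- -dx * sin(thetas[i]) + dy * cos(thetas[i])
    inside <- (xr / a_px)^2 + (yr / b_px)^2 <= 1
    nuc_labels[inside] <- i
  }
  nuc_mask <- matrix(as.integer(nuc_labels > 0), nr, nc)

  dmap <- distance_map(nuc_mask, clip = Inf)
  # nearest-nucleus (cell) assignment for every pixel
  nearest <- matrix(1L, nr, nc)
  if (cfg$n_cells > 1) {
    best <- as_pixel_matrix(EBImage::distmap(1 - (nuc_labels == 1)))
    for (i in 2:cfg$n_cells) {
      di <- as_pixel_matrix(EBImage::distmap(1 - (nuc_labels == i)))
      upd <- di < best
      nearest[upd] <- i
      best[upd] <- di[upd]
    }
  }

  # --- vesicle placement geometry ---
  sigma_px <- cfg$vesicle_sigma_um / ps
  len_px <- if (cfg$vesicle_shape == "rod") cfg$vesicle_length_um / ps else 0
  jitter_rad <- 15 * pi / 180
  # radial half-extent of the half-maximum footprint (half-max radius of a
  # Gaussian is ~1.18 sigma), used as the placement margin inside each zone
  radial_extent_px <- if (cfg$vesicle_shape == "spot") {
    1.5 * sigma_px
  } else if (cfg$orientation == "tangential") {
    (len_px / 2) * sin(jitter_rad) + 1.5 * sigma_px
  } else {
    len_px / 2 + 1.5 * sigma_px
  }
  patch_half <- ceiling(len_px / 2 + 4 * sigma_px) + 2L
  margin_ok <- rowg > patch_half & rowg <= nr - patch_half &
    colg > patch_half & colg <= nc - patch_half
  b1 <- cfg$zone_boundaries_um[1]; b2 <- cfg$zone_boundaries_um[2]
  ext_um <- radial_extent_px * ps
  d_um <- dmap * ps
  zone_bands <- list(
    d_um > ext_um & d_um <= b1 - ext_um,
    d_um > b1 + ext_um & d_um <= b2 - ext_um,
    d_um > b2 + ext_um
  )
  sector_centers <- stats::runif(cfg$n_cells, 0, 2 * pi)
  sector_ok <- function(cell) {
    if (is.null(cfg$cluster_sector_deg)) return(TRUE)
    ang <- atan2(rowg - centers[cell, 1], colg - centers[cell, 2])
    d <- abs((ang - sector_centers[cell] + pi) %% (2 * pi) - pi)
    d <= cfg$cluster_sector_deg * pi / 360
  }
  sector_masks <- lapply(seq_len(cfg$n_cells), sector_ok)

  channel_names <- c("red", "green")[seq_len(cfg$n_vesicle_channels)]
  zones <- c("perinuclear", "intermediate", "periphery")
  min_sep_px <- cfg$min_separation_um / ps

  place_vesicle <- function(cell, zone, placed, extra_excl = NULL,
                            excl_dist_px = 0) {
    ok <- zone_bands[[zone]] & nearest == cell & margin_ok
    if (!isTRUE(sector_masks[[cell]])) ok <- ok & sector_masks[[cell]]
    cand <- which(ok)
    if (!length(cand)) {
      stop("placement failure: no room for a ", zones[zone],
           " vesicle of cell ", cell)
    }
    for (try in 1:400) {
      px <- cand[sample.int(length(cand), 1)]
      rr <- (px - 1) %% nr + 1
      cc <- (px - 1) %/% nr + 1
      pos <- c(rr + stats::runif(1, -0.5, 0.5), cc + stats::runif(1, -0.5, 0.5))
      if (nrow(placed) &&
          any(sqrt(rowSums((placed - matrix(pos, nrow(placed), 2,
                                            byrow = TRUE))^2)) < min_sep_px)) next
      if (!is.null(extra_excl) && nrow(extra_excl) &&
          any(sqrt(rowSums((extra_excl - matrix(pos, nrow(extra_excl), 2,
                                                byrow = TRUE))^2)) < excl_dist_px)) next
      return(pos)
    }
    stop("placement failure: could not satisfy separation constraints (",
         zones[zone], ", cell ", cell, ")")
  }

  orient_for <- function(pos, cell) {
    if (cfg$vesicle_shape == "spot") return(0)
    if (cfg$orientation == "random") return(stats::runif(1, 0, pi))
    radial <- atan2(pos[1] - centers[cell, 1], pos[2] - centers[cell, 2])
    radial + pi / 2 + stats::runif(1, -jitter_rad, jitter_rad)
  }

  n_per_zone <- largest_remainder_counts(cfg$n_vesicles_per_cell,
                                         cfg$zone_intensity_fractions)
  frac_sum <- sum(cfg$zone_intensity_fractions)

  vesicles <- list()
  coloc_pairs <- list()
  channel_imgs <- list()
  channel_truth <- list()
  red_positions <- matrix(numeric(0), 0, 2)
  red_rows <- NULL

  for (ch in channel_names) {
    img <- matrix(0, nr, nc)
    placed <- matrix(numeric(0), 0, 2)
    rows <- list()
    offset_px <- if (ch == "green") cfg$channel_offsets_um / ps else c(0, 0)

    add_vesicle <- function(pos, cell, pair_with = NA_integer_) {
      phi <- orient_for(pos, cell)
      rp <- render_vesicle_patch(cfg, pos[1], pos[2], phi)
      rpos <- pos + offset_px
      rr <- round(rpos[1]); cc <- round(rpos[2])
      rr <- min(max(rr, rp$half + 1), nr - rp$half)
      cc <- min(max(cc, rp$half + 1), nc - rp$half)
      img <<- blit_patch(img, rp$patch, rp$half, rr, cc)
      # actual rendered centre: patch carries pos's subpixel offset
      rendered <- c(rr + (pos[1] - round(pos[1])), cc + (pos[2] - round(pos[2])))
      # ground-truth Distance (Min): half-max footprint of this vesicle alone
      fp <- which(rp$patch >= max(rp$patch) / 2, arr.ind = TRUE)
      fr <- fp[, 1] + rr - rp$half - 1L
      fc <- fp[, 2] + cc - rp$half - 1L
      dmin <- min(dmap[cbind(fr, fc)])
      zone <- assign_zone(dmin, ps, cfg$zone_boundaries_um)
      list(channel = ch, cell = cell,
           row = rendered[1], col = rendered[2],
           intensity = sum(rp$patch), min_distance_px = dmin,
           zone = as.character(zone), pair_with = pair_with)
    }

    if (ch == "red" || cfg$n_vesicle_channels == 1) {
      for (cell in seq_len(cfg$n_cells)) {
        for (zone in 1:3) {
          for (v in seq_len(n_per_zone[zone])) {
            pos <- place_vesicle(cell, zone, placed)
            placed <- rbind(placed, pos)
            rows[[length(rows) + 1]] <- add_vesicle(pos, cell)
          }
        }
      }
      red_positions <- placed
      red_rows <- rows
    } else {
      # green channel: coloc_fraction of vesicles sit on red centres
      for (cell in seq_len(cfg$n_cells)) {
        cell_red <- which(vapply(red_rows, function(r) r$cell, 1L) == cell)
        n_cell <- cfg$n_vesicles_per_cell
        n_col <- round(cfg$coloc_fraction * n_cell)
        n_col <- min(n_col, length(cell_red))
        on_red <- if (n_col > 0) sample(cell_red, n_col) else integer(0)
        for (ri in on_red) {
          pos <- c(red_rows[[ri]]$row, red_rows[[ri]]$col)
          placed <- rbind(placed, pos)
          rows[[length(rows) + 1]] <- add_vesicle(pos, cell, pair_with = ri)
          coloc_pairs[[length(coloc_pairs) + 1]] <-
            c(red_index = ri, green_index = length(rows))
        }
        n_free <- n_cell - length(on_red)
        free_zone <- largest_remainder_counts(n_free,
                                              cfg$zone_intensity_fractions)
        for (zone in 1:3) {
          for (v in seq_len(free_zone[zone])) {
            pos <- place_vesicle(cell, zone, placed,
                                 extra_excl = red_positions,
                                 excl_dist_px = cfg$noncoloc_min_dist_um / ps)
            placed <- rbind(placed, pos)
            rows[[length(rows) + 1]] <- add_vesicle(pos, cell)
          }
        }
      }
    }

    # diffuse cytosolic component: remainder of the intensity budget
    ves_total <- if (length(rows)) {
      sum(vapply(rows, function(r) r$intensity, 1))
    } else 0
    diffuse_total <- 0
    d_target <- if (!is.null(cfg$diffuse_intensity)) {
      cfg$diffuse_intensity
    } else if (frac_sum > 0 && frac_sum < 1 && ves_total > 0) {
      ves_total * (1 - frac_sum) / frac_sum
    } else 0
    if (d_target > 0) {
      before <- sum(img)
      for (cell in seq_len(cfg$n_cells)) {
        img <- render_gaussian(img, centers[cell, 1], centers[cell, 2],
                               cfg$diffuse_sigma_um / ps,
                               d_target / cfg$n_cells)
      }
      diffuse_total <- sum(img) - before
    }

    channel_imgs[[ch]] <- img
    ztot <- vapply(zones, function(z) {
      sum(vapply(rows, function(r) if (r$zone == z) r$intensity else 0, 1))
    }, 1)
    denom <- ves_total + diffuse_total
    channel_truth[[ch]] <- data.frame(
      channel = ch, zone = zones, intensity = as.numeric(ztot),
      fraction = if (denom > 0) as.numeric(ztot) / denom else 0,
      vesicle_total = ves_total, diffuse_total = diffuse_total,
      row.names = NULL
    )
    vesicles <- c(vesicles, rows)
  }

  # --- assemble channels, apply noise ---
  maxval <- 2^cfg$bit_depth - 1
  nuc_img <- as_pixel_matrix(
    EBImage::gblur(nuc_mask * cfg$nucleus_intensity, sigma = 1)
  )
  clean <- c(list(dapi = nuc_img), channel_imgs)
  clean <- lapply(clean, function(x) x + cfg$background_level)
  noisy <- lapply(clean, function(x) {
    if (cfg$poisson) x <- matrix(stats::rpois(length(x), pmax(x, 0)),
                                 nrow(x), ncol(x))
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(length(x), 0, cfg$noise_sd)
    matrix(round(pmin(pmax(x, 0), maxval)), nrow(x), ncol(x))
  })

  ves_df <- if (length(vesicles)) {
    do.call(rbind, lapply(vesicles, function(r) {
      data.frame(channel = r$channel, cell = r$cell, row = r$row, col = r$col,
                 intensity = r$intensity, min_distance_px = r$min_distance_px,
                 zone = r$zone, pair_with = r$pair_with)
    }))
  } else {
    data.frame(channel = character(0), cell = integer(0), row = numeric(0),
               col = numeric(0), intensity = numeric(0),
               min_distance_px = numeric(0), zone = character(0),
               pair_with = integer(0))
  }
  truth <- list(
    vesicles = ves_df,
    cells = data.frame(cell = seq_len(cfg$n_cells),
                       row = centers[, 1], col = centers[, 2],
                       semi_major_px = a_px, semi_minor_px = b_px,
                       theta = thetas,
                       sector_center = sector_centers),
    coloc_pairs = if (length(coloc_pairs)) {
      as.data.frame(do.call(rbind, coloc_pairs))
    } else {
      data.frame(red_index = integer(0), green_index = integer(0))
    },
    zone_fractions = do.call(rbind, channel_truth),
    nucleus_mask = nuc_mask,
    config = cfg
  )
  image <- multichannel_image(noisy, ps, cfg$bit_depth,
                              provenance = list(seed = cfg$seed))
  list(image = image, truth = truth)
}

#' Recompute per-image zone fractions from the per-vesicle ground truth
#'
#' Invariant check: zone fractions stored in the ground truth are exactly
#' the per-zone sums of vesicle intensities divided by total channel signal
#' (vesicles plus diffuse component).
#'
#' @param truth ground-truth list from [generate_image()].
#' @return data.frame mirroring `truth$zone_fractions`.
#' @export
recompute_zone_fractions <- function(truth) {
  zf <- truth$zone_fractions
  out <- zf
  for (i in seq_len(nrow(zf))) {
    v <- truth$vesicles
    ztot <- sum(v$intensity[v$channel == zf$channel[i] & v$zone == zf$zone[i]])
    denom <- zf$vesicle_total[i] + zf$diffuse_total[i]
    out$intensity[i] <- ztot
    out$fraction[i] <- if (denom > 0) ztot / denom else 0
  }
  out
}

#' Approximate peak pixel amplitude of a rendered vesicle
#'
#' Used to express noise levels as a signal-to-noise ratio
#' (SNR = peak amplitude / read-noise sd) when choosing `noise_sd`.
#'
#' @param config a [synth_config()].
#' @return peak amplitude in counts (numeric scalar).
#' @export
vesicle_peak_amplitude <- function(config) {
  ps <- config$pixel_size_um
  sigma_px <- config$vesicle_sigma_um / ps
  w <- 2 * stats::pnorm(0.5 / sigma_px) - 1  # central-pixel 1-D mass
  if (config$vesicle_shape == "spot") {
    config$vesicle_intensity * w^2
  } else {
    len_px <- config$vesicle_length_um / ps
    config$vesicle_intensity * w / len_px
  }
}

#' Generate a group of synthetic images on disk
#'
#' Writes `n_repeats` directories of `n_images` multi-page TIFFs plus a
#' single vesicle-level ground-truth CSV and the configuration as YAML,
#' mimicking one experimental group of 5-10 wide-field images per
#' biological repeat. Per-image seeds are derived deterministically from
#' `seed`.
#'
#' @param config a [synth_config()] (its `seed` field is ignored here).
#' @param n_images images per repeat (>= 1).
#' @param n_repeats biological repeats (>= 1).
#' @param dir output directory (created; must be writable).
#' @param seed master seed.
#' @return manifest data.frame (path, repeat, image, seed), invisibly the
#'   ground-truth table is written to `dir/ground_truth.csv`.
#' @export
generate_group <- function(config, n_images, n_repeats, dir, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_images < 1 || n_repeats < 1) {
    stop("n_images and n_repeats must both be >= 1")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_images * n_repeats)
  manifest <- list()
  gt <- list()
  k <- 0
  for (rep_i in seq_len(n_repeats)) {
    rep_dir <- file.path(dir, sprintf("repeat_%d", rep_i))
    dir.create(rep_dir, showWarnings = FALSE)
    for (img_j in seq_len(n_images)) {
      k <- k + 1
      cfg <- config
      cfg$seed <- seeds[k]
      out <- generate_image(cfg)
      path <- file.path(rep_dir, sprintf("image_%d.tif", img_j))
      write_image(out$image, path)
      manifest[[k]] <- data.frame(path = path, repeat_id = rep_i,
                                  image_id = img_j, seed = seeds[k])
      v <- out$truth$vesicles
      if (nrow(v)) {
        v$repeat_id <- rep_i; v$image_id <- img_j
        zf <- out$truth$zone_fractions
        v$diffuse_total <- zf$diffuse_total[match(v$channel, zf$channel)]
        gt[[length(gt) + 1]] <- v
      }
    }
  }
  gt_df <- if (length(gt)) do.call(rbind, gt) else data.frame()
  utils::write.csv(gt_df, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  do.call(rbind, manifest)
}
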