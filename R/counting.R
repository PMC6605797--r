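#' Count vesicles per nucleus (Bernsen segmentation)
#'
#' Counting workflow for Weibel-Palade bodies: background subtraction,
#' median noise reduction, Bernsen local thresholding (15-pixel radius),
#' connected-component labeling, size filtering, and normalization by the
#' number of nuclei in the image.
#'
#' @param vesicle_channel numeric matrix.
#' @param nucleus_channel numeric matrix (same shape).
#' @param bernsen_radius_px local-threshold window radius (default 15).
#' @param contrast_threshold Bernsen low-contrast cutoff (default 15).
#' @param size_filter_px `c(min_area, max_area)` in pixels; objects outside
#'   the range are discarded (default `c(4, Inf)`: excludes single-pixel
#'   noise, keeps rods).
#' @param median_radius_px optional pre-threshold median filter radius
#'   (default 0 = off; the background subtraction already zeroes the noise
#'   floor and the size filter removes single-pixel survivors).
#' @param background_k similarity band for background subtraction.
#' @param nucleus_min_area_px minimum nucleus size in pixels.
#' @return list of class `count_result`: `n_particles`, `n_nuclei`,
#'   `particles_per_nucleus`, `size_filter_px`, `labels`.
#' @export
count_wpbs <- function(vesicle_channel, nucleus_channel,
                       bernsen_radius_px = 15, contrast_threshold = 15,
                       size_filter_px = c(4, Inf), median_radius_px = 0,
                       background_k = 4, nucleus_min_area_px = 50) {
  ves <- as_pixel_matrix(vesicle_channel)
  nucch <- as_pixel_matrix(nucleus_channel)
  if (!identical(dim(ves), dim(nucch))) {
    stop("vesicle and nucleus channels must have the same shape")
  }
  nuc <- nucleus_mask(nucch, min_area_px = nucleus_min_area_px)
  n_nuclei <- max(nuc$labels)
  if (n_nuclei == 0) stop("zero nuclei found: particles-per-nucleus undefined")

  sub <- subtract_background(ves, similarity_k = background_k)
  if (median_radius_px >= 1) sub <- median_filter(sub, median_radius_px)
  mask <- threshold_bernsen(sub, bernsen_radius_px, contrast_threshold)
  labels <- label_components(mask)
  n <- max(labels)
  if (n > 0) {
    areas <- tabulate(labels[labels > 0], nbins = n)
    drop <- which(areas < size_filter_px[1] | areas > size_filter_px[2])
    if (length(drop)) labels[labels %in% drop] <- 0L
    labels <- relabel_contiguous(labels)
  }
  structure(
    list(n_particles = max(labels), n_nuclei = n_nuclei,
         particles_per_nucleus = max(labels) / n_nuclei,
         size_filter_px = size_filter_px, labels = labels,
         nucleus_labels = nuc$labels),
    class = "count_result"
  )
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d particles / %d nuclei = %.2f per nucleus\n",
              x$n_particles, x$n_nuclei, x$particles_per_nucleus))
  invisible(x)
}

#' Fraction of cells positive for vesicle signal
#'
#' Automated proxy for manual positive-cell counting: each detected
#' particle is assigned to its nearest nucleus, and a cell is positive if
#' it owns at least `min_particles_per_cell` particles.
#'
#' @param vesicle_channel numeric matrix.
#' @param nucleus_channel numeric matrix (same shape).
#' @param min_particles_per_cell positivity threshold (default 1).
#' @param ... passed to [count_wpbs()].
#' @return list: `fraction_positive`, `n_positive`, `n_cells`,
#'   `particles_per_cell` (integer vector).
#' @export
count_positive_cells <- function(vesicle_channel, nucleus_channel,
                                 min_particles_per_cell = 1, ...) {
  cr <- count_wpbs(vesicle_channel, nucleus_channel, ...)
  n_cells <- cr$n_nuclei
  per_cell <- integer(n_cells)
  if (cr$n_particles > 0) {
    # nearest-nucleus assignment via per-nucleus distance maps
    dists <- lapply(seq_len(n_cells), function(i) {
      as_pixel_matrix(EBImage::distmap(1 - (cr$nucleus_labels == i)))
    })
    pt <- measure_particles(cr$labels, matrix(0, nrow(cr$labels), ncol(cr$labels)),
                            matrix(0, nrow(cr$labels), ncol(cr$labels)))
    for (p in seq_len(nrow(pt))) {
      rr <- round(pt$centroid_row[p]); cc <- round(pt$centroid_col[p])
      dvals <- vapply(dists, function(d) d[rr, cc], 1)
      owner <- which.min(dvals)
      per_cell[owner] <- per_cell[owner] + 1L
    }
  }
  n_pos <- sum(per_cell >= min_particles_per_cell)
  list(fraction_positive = n_pos / n_cells, n_positive = n_pos,
       n_cells = n_cells, particles_per_cell = per_cell)
}
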