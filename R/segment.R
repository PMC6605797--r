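#' Isodata ("Default") automatic threshold
#'
#' Iterative intermeans threshold as implemented by ImageJ's "Default"
#' auto-threshold: starting from the midpoint of the intensity range, the
#' threshold is repeatedly replaced by the average of the means of the two
#' classes it induces, until it stabilises. Foreground is `channel > T`.
#'
#' @param channel numeric matrix of pixel intensities.
#' @param tol convergence tolerance on the threshold value.
#' @return the threshold intensity `T` (numeric scalar).
#' @export
threshold_isodata <- function(channel, tol = 1e-6) {
  v <- as.vector(as_pixel_matrix(channel))
  if (length(unique(v)) < 2) {
    stop("isodata threshold undefined: channel is constant")
  }
  t_cur <- mean(range(v))
  for (i in 1:1000) {
    lo <- v[v <= t_cur]
    hi <- v[v > t_cur]
    if (!length(hi)) {  # everything below: nudge down to split off the max
      t_next <- (mean(lo[lo < max(v)]) + max(v)) / 2
    } else if (!length(lo)) {
      t_next <- (min(v) + mean(hi[hi > min(v)])) / 2
    } else {
      t_next <- (mean(lo) + mean(hi)) / 2
    }
    if (abs(t_next - t_cur) < tol) return(t_next)
    t_cur <- t_next
  }
  t_cur
}

#' Max Entropy (Kapur) threshold
#'
#' Global threshold maximising the sum of Shannon entropies of the
#' background and foreground classes of the intensity histogram
#' (Kapur-Sahoo-Wong). The histogram uses `n_bins` equal-width bins spanning
#' the channel's intensity range, mirroring ImageJ's treatment of 16-bit
#' images. Foreground is `channel > T`.
#'
#' @param channel numeric matrix of pixel intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold intensity `T`, located at a bin boundary.
#' @export
threshold_max_entropy <- function(channel, n_bins = 256) {
  v <- as.vector(as_pixel_matrix(channel))
  rng <- range(v)
  if (diff(rng) == 0) {
    stop("max entropy threshold undefined: channel is constant")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  p <- counts / sum(counts)
  cp <- cumsum(p)
  # cumulative entropy terms, with 0 log 0 = 0
  plogp <- ifelse(p > 0, p * log(p), 0)
  cplogp <- cumsum(plogp)
  total_plogp <- cplogp[n_bins]
  best <- -Inf
  best_t <- NA_integer_
  for (t in 1:(n_bins - 1)) {
    p0 <- cp[t]; p1 <- 1 - p0
    if (p0 <= 0 || p1 <= 0) next
    h0 <- log(p0) - cplogp[t] / p0
    h1 <- log(p1) - (total_plogp - cplogp[t]) / p1
    if (h0 + h1 > best) {
      best <- h0 + h1
      best_t <- t
    }
  }
  if (is.na(best_t)) stop("max entropy threshold undefined: degenerate histogram")
  breaks[best_t + 1]
}

#' Bernsen local threshold
#'
#' For every pixel, takes the minimum and maximum intensity within a disc of
#' `radius_px` (clipped at the image border). Where the local contrast
#' `max - min` is at least `contrast_threshold`, the pixel is foreground iff
#' its value exceeds the local midgray `(max + min) / 2`; low-contrast
#' neighbourhoods are assigned wholesale to the background class.
#'
#' @param channel numeric matrix.
#' @param radius_px disc radius of the local window (default 15, the radius
#'   used for Weibel-Palade body counting).
#' @param contrast_threshold minimum local contrast for a mixed window
#'   (default 15, the common ImageJ default).
#' @return integer 0/1 mask matrix.
#' @export
threshold_bernsen <- function(channel, radius_px = 15, contrast_threshold = 15) {
  m <- as_pixel_matrix(channel)
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (radius_px > max(dim(m))) {
    stop("Bernsen radius larger than the image")
  }
  lo <- local_extreme_disc(m, radius_px, "min")
  hi <- local_extreme_disc(m, radius_px, "max")
  mask <- (hi - lo >= contrast_threshold) & (m > (hi + lo) / 2)
  out <- matrix(0L, nrow(m), ncol(m))
  out[mask] <- 1L
  out
}

#' Median filter
#'
#' Replaces each pixel by the median over a disc-shaped window of
#' `radius_px`, with reflected (mirrored) image borders. Works on grayscale
#' channels and on binary masks alike.
#'
#' @param x numeric matrix (channel or 0/1 mask).
#' @param radius_px window radius (>= 1).
#' @return filtered matrix, same type semantics as the input.
#' @export
median_filter <- function(x, radius_px = 1) {
  m <- as_pixel_matrix(x)
  if (radius_px < 1) stop("radius_px must be >= 1")
  nr <- nrow(m); nc <- ncol(m)
  # reflected padding
  ri <- c(radius_px:1, 1:nr, nr:(nr - radius_px + 1))
  ci <- c(radius_px:1, 1:nc, nc:(nc - radius_px + 1))
  pad <- m[ri, ci]
  offs <- disc_offsets(radius_px)
  k <- nrow(offs)
  stack <- matrix(0, nr * nc, k)
  for (j in seq_len(k)) {
    stack[, j] <- as.vector(
      pad[(radius_px + 1 + offs[j, 1]):(radius_px + nr + offs[j, 1]),
          (radius_px + 1 + offs[j, 2]):(radius_px + nc + offs[j, 2])]
    )
  }
  out <- matrix(row_medians(stack), nr, nc)
  if (all(m %in% c(0, 1))) {
    # disc windows have an odd pixel count, so the median of a 0/1 window is
    # itself 0 or 1 and this is an exact majority vote
    return(matrix(as.integer(out >= 0.5), nr, nc))
  }
  out
}

#' Connected-component labeling
#'
#' Labels connected foreground regions of a binary mask. 8-connectivity
#' (the ImageJ particle-analysis default) is obtained by merging
#' diagonally-touching 4-connected components with a union-find pass.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels 0 (background), 1..n.
#' @importFrom EBImage bwlabel
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- stopifnot_mask(mask)
  lab <- as_pixel_matrix(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (connectivity == 4 || n <= 1) return(relabel_contiguous(lab))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    sh <- shift_matrix(lab, d[1], d[2], 0)
    touch <- lab > 0 & sh > 0 & lab != sh
    if (any(touch)) {
      pairs <- unique(cbind(as.integer(lab[touch]), as.integer(sh[touch])))
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[b] <- a
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab[lab > 0] <- root[lab[lab > 0]]
  relabel_contiguous(lab)
}

relabel_contiguous <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Watershed splitting of touching objects
#'
#' Splits touching convex blobs of a binary mask along the ridge of its
#' internal Euclidean distance transform, seeded at the transform's regional
#' maxima (classic binary watershed, as used to separate adjacent nuclei).
#'
#' @param mask 0/1 matrix.
#' @param tolerance minimum height of a regional maximum relative to its
#'   neighbourhood to seed an object (passed to [EBImage::watershed()]).
#' @return integer label matrix; an empty mask yields an all-zero labeling.
#' @importFrom EBImage watershed distmap
#' @export
watershed_split <- function(mask, tolerance = 1) {
  mask <- stopifnot_mask(mask)
  if (sum(mask) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  dt <- EBImage::distmap(mask)  # distance to background, inside objects
  lab <- as_pixel_matrix(EBImage::watershed(dt, tolerance = tolerance))
  storage.mode(lab) <- "integer"
  relabel_contiguous(lab)
}

#' Euclidean distance map from a nucleus mask
#'
#' Exact Euclidean distance (in pixels) from every pixel to the nearest
#' nucleus pixel: 0 on the nucleus itself, increasing outwards, clipped by
#' default at 255 to match the 0-255 range of 8-bit ImageJ distance maps.
#'
#' @param nucleus_mask 0/1 matrix with at least one foreground pixel.
#' @param clip upper clip value in px (default 255; use `Inf` for unclipped
#'   distances).
#' @return numeric matrix of distances.
#' @importFrom EBImage distmap
#' @export
distance_map <- function(nucleus_mask, clip = 255) {
  mask <- stopifnot_mask(nucleus_mask)
  if (sum(mask) == 0) stop("distance map undefined: empty nucleus mask")
  d <- as_pixel_matrix(EBImage::distmap(1 - mask))
  pmin(d, clip)
}

#' Processed nucleus mask
#'
#' The nucleus-segmentation chain of the distribution macro: isodata
#' ("Default") threshold on the nucleus channel, median filtering to remove
#' noise, and watershed splitting of touching nuclei.
#'
#' @param nucleus_channel numeric matrix (e.g. the DAPI channel).
#' @param median_radius_px median filter radius (default 2).
#' @param watershed apply watershed splitting (default TRUE).
#' @param min_area_px discard components smaller than this many pixels
#'   (default 50; rejects debris far below nuclear size).
#' @return list with `mask` (0/1 matrix) and `labels` (integer matrix).
#' @export
nucleus_mask <- function(nucleus_channel, median_radius_px = 2,
                         watershed = TRUE, min_area_px = 50) {
  ch <- as_pixel_matrix(nucleus_channel)
  thr <- threshold_isodata(ch)
  mask <- matrix(as.integer(ch > thr), nrow(ch), ncol(ch))
  mask <- median_filter(mask, median_radius_px)
  labels <- if (watershed) watershed_split(mask) else label_components(mask)
  if (max(labels) > 0 && min_area_px > 1) {
    areas <- tabulate(labels[labels > 0], nbins = max(labels))
    drop <- which(areas < min_area_px)
    if (length(drop)) labels[labels %in% drop] <- 0L
    labels <- relabel_contiguous(labels)
  }
  list(mask = matrix(as.integer(labels > 0), nrow(ch), ncol(ch)),
       labels = labels)
}
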