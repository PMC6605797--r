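# Internal pixel-grid helpers shared across modules. Images are plain numeric
# matrices (row = y, col = x), masks are 0/1 integer matrices.

#' @importFrom EBImage imageData
as_pixel_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

stopifnot_mask <- function(mask) {
  mask <- as_pixel_matrix(mask)
  if (!all(mask %in% c(0, 1))) stop("mask must contain only 0/1 values")
  mask
}

# Shift a matrix by (dr, dc), padding exposed cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Running extreme over the horizontal span [-w, w] via doubling. Built as the
# union of a backward window [c-w, c] and a forward window [c, c+w], so image
# borders clip the window instead of injecting fill values.
# `fill` must be the identity of `fun` (Inf for pmin, -Inf for pmax).
running_extreme_cols <- function(m, w, fun, fill) {
  one_sided <- function(sgn) {
    width <- w + 1L
    b <- m
    span <- 1L
    while (2L * span <= width) {
      b <- fun(b, shift_matrix(b, 0L, sgn * span, fill))
      span <- 2L * span
    }
    if (span < width) b <- fun(b, shift_matrix(b, 0L, sgn * (width - span), fill))
    b
  }
  if (w == 0L) return(m)
  fun(one_sided(1L), one_sided(-1L))
}

# Local min/max over a disc of radius r (window clipped at image borders).
local_extreme_disc <- function(m, radius, which = c("min", "max")) {
  which <- match.arg(which)
  fun <- if (which == "min") pmin else pmax
  fill <- if (which == "min") Inf else -Inf
  out <- matrix(fill, nrow(m), ncol(m))
  for (dr in -radius:radius) {
    w <- floor(sqrt(radius^2 - dr^2))
    row_band <- running_extreme_cols(m, w, fun, fill)
    out <- fun(out, shift_matrix(row_band, dr, 0L, fill))
  }
  out
}

# Offsets (dr, dc) of a disc of radius r, as a 2-column matrix.
disc_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE])
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
# Positions outside the grid return `outside`.
bilinear <- function(m, rows, cols, outside = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  # clamp exact bottom/right edge onto the last cell
  edge_r <- rows >= 1 & rows <= nr & abs(rows - nr) < 1e-9
  edge_c <- cols >= 1 & cols <= nc & abs(cols - nc) < 1e-9
  r0[edge_r] <- nr - 1; fr[edge_r] <- 1
  c0[edge_c] <- nc - 1; fc[edge_c] <- 1
  ok <- ok | (edge_r & cols >= 1 & cols <= nc) | (edge_c & rows >= 1 & rows <= nr)
  out <- rep(outside, length(rows))
  if (any(ok)) {
    i <- which(ok)
    r0i <- pmin(pmax(r0[i], 1), nr - 1); c0i <- pmin(pmax(c0[i], 1), nc - 1)
    fri <- rows[i] - r0i; fci <- cols[i] - c0i
    v00 <- m[cbind(r0i, c0i)]
    v10 <- m[cbind(r0i + 1, c0i)]
    v01 <- m[cbind(r0i, c0i + 1)]
    v11 <- m[cbind(r0i + 1, c0i + 1)]
    out[i] <- v00 * (1 - fri) * (1 - fci) + v10 * fri * (1 - fci) +
      v01 * (1 - fri) * fci + v11 * fri * fci
  }
  out
}

# Row-wise median of a matrix with an odd, small number of columns.
# Single order() call: sort values within rows, take the middle order statistic.
row_medians <- function(v) {
  n <- nrow(v); k <- ncol(v)
  o <- order(rep(seq_len(n), k), as.vector(v))
  sorted <- matrix(as.vector(v)[o], nrow = k)  # column j = sorted row j
  if (k %% 2L == 1L) {
    sorted[(k + 1L) / 2L, ]
  } else {
    (sorted[k / 2L, ] + sorted[k / 2L + 1L, ]) / 2
  }
}
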