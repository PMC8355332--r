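## Nematic order-parameter analysis of actin fluorescence images.
##
## Images are numeric matrices with rows = y (down) and columns = x, values
## in [0, 1].  Directors are axial (pi-periodic) angles from the +x axis.
## Orientation is estimated per overlapping block from the principal axis of
## the block's 2D power spectrum: a filament texture concentrates spectral
## energy perpendicular to the filaments, so the director is the axis
## orthogonal to the spectral major axis.

.as_image_matrix <- function(image) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a single-channel numeric matrix", call. = FALSE)
  unclass(image)
}

#' Build a boolean intensity mask of a fluorescence image
#'
#' Thresholds the image (Otsu's method or a fixed value) and removes
#' connected components smaller than `min_area_px`.
#'
#' @param image single-channel numeric matrix, values in `[0, 1]`.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold threshold for `method = "fixed"`.
#' @param min_area_px minimum connected-component area to keep, px.
#' @return logical matrix of the same shape.
#' @export
make_intensity_mask <- function(image, method = c("otsu", "fixed"),
                                threshold = NULL, min_area_px = 0) {
  img <- .as_image_matrix(image)
  method <- match.arg(method)
  thr <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(img), range = range(0, 1, img)),
    fixed = {
      if (is.null(threshold)) stop("'threshold' required for method = 'fixed'",
                                   call. = FALSE)
      threshold
    })
  mask <- img > thr
  if (min_area_px > 0 && any(mask)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= min_area_px)
    mask <- matrix(lab %in% keep, nrow = nrow(img))
  }
  if (!any(mask))
    stop("mask is empty: no component passes the threshold and area filter",
         call. = FALSE)
  mask
}

#' Block-wise local orientation (director) field of a filament image
#'
#' Segments the image into overlapping square blocks and estimates, per
#' block, the local filament orientation from the second-moment
#' eigen-analysis of the block's 2D power spectrum (Hann-tapered, DC bin
#' removed, radially windowed to below the Nyquist circle).  The director
#' is the axis orthogonal to the spectral major axis; coherence is the
#' normalised eigenvalue anisotropy in `[0, 1]`.  Blocks with fewer than
#' 50% in-mask pixels, or with no spectral energy, are unset (`NA`).
#'
#' @param image single-channel numeric matrix.
#' @param window block size, px; a power of two, at least 16 (default 32).
#' @param overlap block overlap fraction in `[0, 0.9]` (default 0.5).
#' @param mask optional logical matrix restricting analysis to cells.
#' @return an `orientation_field`: list with matrices `theta` (radians in
#'   `[0, pi)`), `coherence`, grids `block_x`/`block_y` (px centres), and
#'   the `window`/`overlap` used.
#' @export
local_orientation <- function(image, window = 32, overlap = 0.5,
                              mask = NULL) {
  img <- .as_image_matrix(image)
  if (window < 16 || bitwAnd(window, window - 1L) != 0)
    stop("'window' must be a power of two, at least 16", call. = FALSE)
  if (overlap < 0 || overlap > 0.9)
    stop("'overlap' must lie in [0, 0.9]", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  if (window > h || window > w)
    stop("'window' larger than the image", call. = FALSE)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  y0 <- seq(1L, h - window + 1L, by = step)
  x0 <- seq(1L, w - window + 1L, by = step)

  hann <- 0.5 * (1 - cos(2 * pi * (0:(window - 1)) / (window - 1)))
  taper <- outer(hann, hann)
  ## centred frequency coordinates of the unshifted FFT layout
  k <- 0:(window - 1)
  freq <- ifelse(k < window / 2, k, k - window)
  u <- matrix(freq, nrow = window, ncol = window, byrow = TRUE)  # x-freq
  v <- matrix(freq, nrow = window, ncol = window)                # y-freq
  r <- sqrt(u^2 + v^2)
  keep <- r >= 1 & r <= window / 2

  theta <- matrix(NA_real_, length(y0), length(x0))
  coher <- matrix(0, length(y0), length(x0))
  for (iy in seq_along(y0)) {
    for (ix in seq_along(x0)) {
      ys <- y0[iy]:(y0[iy] + window - 1L)
      xs <- x0[ix]:(x0[ix] + window - 1L)
      if (!is.null(mask) && mean(mask[ys, xs]) < 0.5) next
      blk <- img[ys, xs]
      blk <- (blk - mean(blk)) * taper
      P <- Mod(stats::fft(blk))^2
      P[!keep] <- 0
      tot <- sum(P)
      if (tot <= .Machine$double.eps) next     # constant block
      muu <- sum(P * u^2); mvv <- sum(P * v^2); muv <- sum(P * u * v)
      psi <- 0.5 * atan2(2 * muv, muu - mvv)   # spectral major axis
      theta[iy, ix] <- (psi + pi / 2) %% pi    # director: orthogonal axis
      coher[iy, ix] <- sqrt((muu - mvv)^2 + 4 * muv^2) / (muu + mvv)
    }
  }
  structure(list(theta = theta, coherence = coher,
                 block_x = x0 + (window - 1) / 2,
                 block_y = y0 + (window - 1) / 2,
                 window = window, overlap = overlap),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("orientation field: %d x %d blocks (window %d px, overlap %.0f%%), %d set\n",
              nrow(x$theta), ncol(x$theta), x$window, 100 * x$overlap,
              sum(!is.na(x$theta))))
  invisible(x)
}

#' Nematic order-parameter map of a director field
#'
#' For each set block \eqn{i}, computes
#' \eqn{q_i = \langle 2(\cos^2(\theta_i - \theta_j) - 1/2) \rangle_j}
#' over the set neighbour blocks \eqn{j} within a Chebyshev radius
#' (8-connected ring for `radius = 1`), the central block excluded.
#' `q = 1` for locally parallel directors, 0 on average for random ones.
#' Angle differences are axial, so only their value modulo pi matters.
#'
#' @param field an `orientation_field`.
#' @param radius neighbourhood Chebyshev radius in blocks (default 1).
#' @return a `q_map`: list with matrix `q` (`NA` where unset) and the
#'   `radius` used.
#' @export
order_parameter_map <- function(field, radius = 1) {
  stopifnot(inherits(field, "orientation_field"))
  th <- field$theta
  nr <- nrow(th); nc <- ncol(th)
  if (nr * nc < (2 * radius + 1)^2)
    stop("field too small for the requested neighbourhood radius",
         call. = FALSE)
  q <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(th[i, j])) next
      ii <- max(1, i - radius):min(nr, i + radius)
      jj <- max(1, j - radius):min(nc, j + radius)
      nb <- th[ii, jj]
      nb <- nb[!is.na(nb)]
      ## drop one copy of the centre from its own neighbourhood
      n_centre <- sum(ii == i) * sum(jj == j)  # == 1
      if (length(nb) <= n_centre) next
      d <- nb - th[i, j]
      q[i, j] <- (sum(cos(2 * d)) - n_centre) / (length(nb) - n_centre)
    }
  }
  structure(list(q = q, radius = radius), class = "q_map")
}

#' @export
print.q_map <- function(x, ...) {
  cat(sprintf("order-parameter map: %d x %d blocks, %d set, <q> = %.3f\n",
              nrow(x$q), ncol(x$q), sum(!is.na(x$q)),
              mean(x$q, na.rm = TRUE)))
  invisible(x)
}

#' Mean nematic order parameter of a q map
#'
#' @param qmap a `q_map` from [order_parameter_map()].
#' @return unweighted mean of the set block q values.
#' @export
mean_order_parameter <- function(qmap) {
  stopifnot(inherits(qmap, "q_map"))
  vals <- qmap$q[!is.na(qmap$q)]
  if (length(vals) == 0) stop("q map has no set blocks", call. = FALSE)
  mean(vals)
}

#' Mean fluorescence intensity over a mask
#'
#' @param image single-channel numeric matrix.
#' @param mask logical matrix of the same shape.
#' @return arithmetic mean grey value of the masked pixels.
#' @export
mean_intensity <- function(image, mask) {
  img <- .as_image_matrix(image)
  if (!identical(dim(img), dim(mask)))
    stop("'image' and 'mask' must have the same shape", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  mean(img[mask])
}

#' Cell viability from a live/dead two-channel image pair
#'
#' Counts connected components (cells) in each channel after intensity
#' masking and returns the viable percentage
#' 100 n_green / (n_green + n_red), the green fraction of all cells in a
#' Calcein AM/PI readout.
#'
#' @param green_image,red_image single-channel matrices of equal shape.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold when `threshold_method = "fixed"`.
#' @param min_area_px minimum cell area, px.
#' @return percent viable, with counts in `attr(, "counts")`.
#' @export
viability_from_channels <- function(green_image, red_image,
                                    threshold_method = c("otsu", "fixed"),
                                    threshold = NULL, min_area_px = 0) {
  g <- .as_image_matrix(green_image)
  r <- .as_image_matrix(red_image)
  if (!identical(dim(g), dim(r)))
    stop("channel images must have the same shape", call. = FALSE)
  threshold_method <- match.arg(threshold_method)
  count_cells <- function(img) {
    mask <- tryCatch(
      make_intensity_mask(img, method = threshold_method,
                          threshold = threshold, min_area_px = min_area_px),
      error = function(e) NULL)
    if (is.null(mask)) return(0L)
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    max(lab)
  }
  n_green <- count_cells(g)
  n_red <- count_cells(r)
  if (n_green + n_red == 0)
    stop("no cells detected in either channel", call. = FALSE)
  out <- 100 * n_green / (n_green + n_red)
  attr(out, "counts") <- c(green = n_green, red = n_red)
  out
}
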