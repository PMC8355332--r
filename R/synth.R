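## Seeded synthetic-data generators.  Each generator is a pure function of
## (parameters, seed), emits the same format its analysis module consumes,
## and records its ground truth (retrievable with ground_truth()) so that
## parameter-recovery tests can compare against known inputs.

#' Generate a synthetic AFM approach force curve
#'
#' Produces an idealised force-vs-piezo-position approach curve: a flat
#' zero-force baseline before the tip touches the cell at `contact_z0`,
#' followed by a Hertzian rise \eqn{F = \frac{4}{3}\frac{E}{1-\gamma^2}
#' \sqrt{R}\,\delta^{3/2}} up to an indentation of `max_depth`.  Gaussian
#' noise of standard deviation `noise_sd` is added to the force channel.
#' The contact point always falls exactly on the sampled z grid, so a
#' grid-search contact-point estimator can recover it without residual.
#'
#' @param E Young's modulus of the simulated cell, Pa.
#' @param contact_z0 piezo position of tip-sample contact, nm.
#' @param tip_radius spherical indenter radius, nm (default 10, i.e. a
#'   20 nm diameter probe).
#' @param poisson Poisson ratio of the cell, dimensionless (default 0.4).
#' @param noise_sd standard deviation of additive force noise, nN.
#' @param n_points number of samples along z.
#' @param max_depth maximum indentation depth, nm (default 500).
#' @param seed integer RNG seed.
#' @return a [force_curve] object; `ground_truth()` records `E` and
#'   `contact_z0`.
#' @examples
#' fc <- gen_force_curve(E = 2440, contact_z0 = 100, noise_sd = 0,
#'                       n_points = 200, seed = 1)
#' fit_hertz(fc)
#' @export
gen_force_curve <- function(E, contact_z0, tip_radius = 10, poisson = 0.4,
                            noise_sd = 0, n_points = 200, max_depth = 500,
                            seed = 1) {
  stopifnot_scalar_pos(E, "E")
  stopifnot_scalar_pos(tip_radius, "tip_radius")
  stopifnot_scalar_pos(max_depth, "max_depth")
  if (poisson < 0 || poisson >= 0.5)
    stop("'poisson' must lie in [0, 0.5)", call. = FALSE)
  if (contact_z0 < 0) stop("'contact_z0' must be non-negative", call. = FALSE)
  if (n_points < 20) stop("'n_points' must be at least 20", call. = FALSE)

  total <- contact_z0 + max_depth
  ## split points between baseline and indentation, keeping contact_z0 on
  ## the grid (last baseline sample) so noiseless recovery is exact
  n_pre <- max(2L, round(n_points * contact_z0 / total))
  n_pre <- min(n_pre, n_points - 10L)
  n_post <- n_points - n_pre
  z <- c(seq(0, contact_z0, length.out = n_pre),
         contact_z0 + seq(max_depth / n_post, max_depth, length.out = n_post))
  depth <- pmax(z - contact_z0, 0)
  force <- hertz_force(E, poisson = poisson, tip_radius = tip_radius,
                       depth = depth)
  if (noise_sd > 0)
    force <- force + with_seed(seed, stats::rnorm(n_points, 0, noise_sd))

  fc <- force_curve(z = z, force = force, tip_radius = tip_radius,
                    poisson = poisson)
  set_ground_truth(fc, "gen_force_curve",
                   list(E = E, contact_z0 = contact_z0,
                        tip_radius = tip_radius, poisson = poisson,
                        noise_sd = noise_sd, n_points = n_points,
                        max_depth = max_depth),
                   seed)
}

## Best & Fisher (1979) rejection sampler for the von Mises distribution,
## mean mu, concentration kappa, support [0, 2*pi).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-12) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Generate a synthetic actin-filament fluorescence image
#'
#' Draws `n_filaments` bright anti-aliased line segments on a dark
#' background.  Segment orientations follow a pi-periodic von Mises law
#' centred on `mean_angle` with concentration `kappa` (sampled as standard
#' von Mises on the doubled angle, then halved — the standard construction
#' for axial/director data).  `kappa = 0` gives uniformly random directors;
#' `kappa >= 1e6` is treated as perfectly aligned.  Gaussian background
#' noise with standard deviation `1/snr` (peak filament intensity is 1) is
#' added.
#'
#' @param width,height image size, px (at least 64).
#' @param n_filaments number of segments to draw (> 0).
#' @param kappa von Mises concentration of the director distribution.
#' @param mean_angle mean director, radians in `[0, pi)`.
#' @param line_width full width of the Gaussian line profile, px.
#' @param snr peak-signal-to-noise ratio; `Inf` for no noise.
#' @param filament_length segment length, px (default a third of the
#'   shorter image side).
#' @param seed integer RNG seed.
#' @return a numeric matrix in `[0, 1]` (rows = y, columns = x) of class
#'   `actin_image`; `ground_truth()` records the drawn angles and
#'   `attr(, "filament_mask")` the noise-free filament raster
#'   (pixels with pre-noise intensity >= 0.5).
#' @export
gen_filament_image <- function(width = 256, height = 256, n_filaments = 40,
                               kappa = 5, mean_angle = 0, line_width = 3,
                               snr = 10, filament_length = NULL, seed = 1) {
  if (width < 64 || height < 64)
    stop("image dimensions must be at least 64 px", call. = FALSE)
  if (n_filaments < 1)
    stop("'n_filaments' must be positive: an empty image is not a valid fixture",
         call. = FALSE)
  if (kappa < 0) stop("'kappa' must be non-negative", call. = FALSE)
  filament_length <- filament_length %||% (min(width, height) / 3)

  res <- with_seed(seed, {
    ang <- if (kappa >= 1e6) rep(mean_angle %% pi, n_filaments)
           else (mean_angle + rvonmises(n_filaments, 0, kappa) / 2) %% pi
    cx <- stats::runif(n_filaments, 1, width)
    cy <- stats::runif(n_filaments, 1, height)
    img <- matrix(0, nrow = height, ncol = width)
    s <- line_width / 2
    half <- filament_length / 2
    for (k in seq_len(n_filaments)) {
      dx <- cos(ang[k]); dy <- sin(ang[k])
      x1 <- cx[k] - half * dx; y1 <- cy[k] - half * dy
      x2 <- cx[k] + half * dx; y2 <- cy[k] + half * dy
      pad <- 3 * s
      xs <- max(1, floor(min(x1, x2) - pad)):min(width, ceiling(max(x1, x2) + pad))
      ys <- max(1, floor(min(y1, y2) - pad)):min(height, ceiling(max(y1, y2) + pad))
      px <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
      py <- matrix(ys, nrow = length(ys), ncol = length(xs))
      ## distance from each pixel centre to the segment
      vx <- x2 - x1; vy <- y2 - y1
      len2 <- vx^2 + vy^2
      tt <- pmin(pmax(((px - x1) * vx + (py - y1) * vy) / len2, 0), 1)
      d2 <- (px - (x1 + tt * vx))^2 + (py - (y1 + tt * vy))^2
      prof <- exp(-d2 / (2 * s^2))
      img[ys, xs] <- pmax(img[ys, xs], prof)
    }
    fil_mask <- img >= 0.5
    if (is.finite(snr) && snr > 0)
      img <- img + matrix(stats::rnorm(height * width, 0, 1 / snr),
                          nrow = height)
    img <- pmin(pmax(img, 0), 1)
    list(img = img, ang = ang, fil_mask = fil_mask)
  })
  img <- structure(res$img, class = c("actin_image", "matrix"))
  attr(img, "filament_mask") <- res$fil_mask
  set_ground_truth(img, "gen_filament_image",
                   list(width = width, height = height,
                        n_filaments = n_filaments, kappa = kappa,
                        mean_angle = mean_angle %% pi,
                        line_width = line_width, snr = snr,
                        angles = res$ang),
                   seed)
}

#' Generate a synthetic live/dead two-channel cell image pair
#'
#' Draws non-overlapping bright discs for viable (green channel) and dead
#' (red channel) cells on black backgrounds, emulating a Calcein AM/PI
#' stain readout where viability is the green fraction of all cells.
#'
#' @param n_green,n_red number of viable / dead cells.
#' @param width,height image size, px.
#' @param radius disc radius, px.
#' @param seed integer RNG seed.
#' @return list with matrices `green` and `red` (values in `[0, 1]`);
#'   `ground_truth()` records the counts and centres.
#' @export
gen_live_dead_images <- function(n_green, n_red, width = 256, height = 256,
                                 radius = 6, seed = 1) {
  n_tot <- n_green + n_red
  if (n_tot < 1) stop("at least one cell is required", call. = FALSE)
  res <- with_seed(seed, {
    ## rejection-place non-overlapping disc centres
    centres <- matrix(NA_real_, n_tot, 2)
    placed <- 0L
    tries <- 0L
    while (placed < n_tot) {
      p <- c(stats::runif(1, radius + 2, width - radius - 1),
             stats::runif(1, radius + 2, height - radius - 1))
      ok <- placed == 0L ||
        all(sqrt(colSums((t(centres[seq_len(placed), , drop = FALSE]) - p)^2)) >
              2 * radius + 2)
      if (ok) { placed <- placed + 1L; centres[placed, ] <- p }
      tries <- tries + 1L
      if (tries > 200L * n_tot)
        stop("could not place non-overlapping discs; reduce n or radius",
             call. = FALSE)
    }
    centres
  })
  draw <- function(idx) {
    img <- matrix(0, nrow = height, ncol = width)
    px <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
    py <- matrix(seq_len(height), nrow = height, ncol = width)
    for (i in idx) {
      d2 <- (px - res[i, 1])^2 + (py - res[i, 2])^2
      img <- pmax(img, as.numeric(d2 <= radius^2))
    }
    img
  }
  out <- list(green = draw(seq_len(n_green)),
              red = draw(if (n_red > 0) n_green + seq_len(n_red) else integer()))
  set_ground_truth(out, "gen_live_dead_images",
                   list(n_green = n_green, n_red = n_red, radius = radius,
                        centres = res),
                   seed)
}

#' Generate synthetic directed single-cell migration tracks
#'
#' Each cell advances along the channel axis (+x) at a per-cell speed drawn
#' from Normal(`mean_speed`, `speed_sd`) truncated at zero (negative speeds
#' are biologically meaningless), sampled every `dt` minutes for `duration`
#' hours, with isotropic Gaussian positional jitter.
#'
#' @param n_cells number of cells (> 0).
#' @param mean_speed cohort mean speed, um/h.
#' @param speed_sd between-cell speed standard deviation, um/h.
#' @param dt sampling interval, minutes.
#' @param duration track duration, hours.
#' @param jitter_sd isotropic positional jitter per sample, um.
#' @param seed integer RNG seed.
#' @return a [track_set] data frame (`cell_id`, `t_min`, `x_um`, `y_um`);
#'   `ground_truth()` records the per-cell speeds.
#' @export
gen_tracks <- function(n_cells, mean_speed, speed_sd = 0, dt = 10,
                       duration = 2, jitter_sd = 0, seed = 1) {
  if (n_cells < 1) stop("'n_cells' must be positive", call. = FALSE)
  stopifnot_scalar_pos(dt, "dt")
  stopifnot_scalar_pos(duration, "duration")
  if (mean_speed < 0) stop("'mean_speed' must be non-negative", call. = FALSE)

  t_min <- seq(0, duration * 60, by = dt)
  n_t <- length(t_min)
  res <- with_seed(seed, {
    speeds <- if (speed_sd == 0) rep(mean_speed, n_cells) else {
      ## truncate at 0 by rejection
      v <- stats::rnorm(n_cells, mean_speed, speed_sd)
      while (any(v < 0))
        v[v < 0] <- stats::rnorm(sum(v < 0), mean_speed, speed_sd)
      v
    }
    jit <- function() if (jitter_sd > 0)
      stats::rnorm(n_t * n_cells, 0, jitter_sd) else numeric(n_t * n_cells)
    list(speeds = speeds, jx = jit(), jy = jit())
  })
  x <- as.vector(outer(t_min / 60, res$speeds)) + res$jx
  y <- res$jy
  tr <- track_set(data.frame(
    cell_id = rep(seq_len(n_cells), each = n_t),
    t_min = rep(t_min, n_cells),
    x_um = x,
    y_um = y
  ))
  set_ground_truth(tr, "gen_tracks",
                   list(n_cells = n_cells, mean_speed = mean_speed,
                        speed_sd = speed_sd, dt = dt, duration = duration,
                        jitter_sd = jitter_sd, speeds = res$speeds),
                   seed)
}

#' Generate bivariate-normal collective-variable samples
#'
#' Draws `n` samples from a bivariate normal, emulating the fluctuations of
#' a pair of trajectory collective variables (e.g. a centre-of-mass
#' distance and a native-contact count) around a free-energy minimum.
#'
#' @param mean_xy length-2 centre.
#' @param cov 2x2 symmetric positive-definite covariance.
#' @param n number of samples (>= 1).
#' @param seed integer RNG seed.
#' @return an `n x 2` matrix (columns `x`, `y`); `ground_truth()` records
#'   `mean_xy` and `cov`.
#' @export
gen_cv_samples <- function(mean_xy, cov, n, seed = 1) {
  if (length(mean_xy) != 2) stop("'mean_xy' must have length 2", call. = FALSE)
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov))))
    stop("'cov' must be symmetric", call. = FALSE)
  ch <- tryCatch(chol(cov), error = function(e)
    stop("'cov' must be positive-definite", call. = FALSE))
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  z <- with_seed(seed, matrix(stats::rnorm(2 * n), ncol = 2))
  xy <- z %*% ch
  xy <- sweep(xy, 2, mean_xy, "+")
  colnames(xy) <- c("x", "y")
  set_ground_truth(xy, "gen_cv_samples",
                   list(mean_xy = mean_xy, cov = cov, n = n), seed)
}

#' Generate two-cluster bead frames at prescribed COM separations
#'
#' Builds one frame per requested separation: two rigid copies of a random
#' compact bead cluster whose centres of mass differ by exactly the
#' requested distance along +x under the minimum-image convention, placed
#' in a cubic periodic box and optionally jittered per bead.  Serves as a
#' ground-truth fixture for COM-distance, native-contact and energy
#' observables on actin-subunit-like bead groups.
#'
#' @param com_separations numeric vector of COM separations, nm (each
#'   `< box/2`).
#' @param beads_per_cluster beads per cluster.
#' @param cluster_radius cluster radius, nm.
#' @param box cubic box edge, nm (default 25).
#' @param jitter_sd per-bead positional jitter per frame, nm.
#' @param center_a centre of cluster A, nm (default box centre; place near
#'   an edge to exercise periodic wrapping).
#' @param seed integer RNG seed.
#' @return a `cg_trajectory`: list with `frames` (list of [bead_frame]) and
#'   `topology` (groups `actinA`/`actinB`, types `P1`, zero charge);
#'   `ground_truth()` records the separations.
#' @export
gen_dimer_frames <- function(com_separations, beads_per_cluster = 20,
                             cluster_radius = 1, box = 25, jitter_sd = 0,
                             center_a = NULL, seed = 1) {
  stopifnot_scalar_pos(box, "box")
  if (any(com_separations >= box / 2))
    stop("separations must be below box/2 (minimum-image ambiguity)",
         call. = FALSE)
  if (any(com_separations <= 0))
    stop("separations must be positive", call. = FALSE)
  center_a <- center_a %||% rep(box / 2, 3)
  n <- beads_per_cluster
  res <- with_seed(seed, {
    ## uniform points in a sphere, recentred so the cluster COM is exactly 0
    pts <- matrix(stats::rnorm(3 * n), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2)) * cluster_radius *
      stats::runif(n)^(1 / 3)
    pts <- sweep(pts, 2, colMeans(pts))
    jit <- lapply(seq_along(com_separations), function(i)
      if (jitter_sd > 0) matrix(stats::rnorm(6 * n, 0, jitter_sd), ncol = 3)
      else matrix(0, 2 * n, 3))
    list(pts = pts, jit = jit)
  })
  frames <- lapply(seq_along(com_separations), function(i) {
    sep <- com_separations[i]
    a <- sweep(res$pts, 2, center_a, "+")
    b <- sweep(res$pts, 2, center_a + c(sep, 0, 0), "+")
    pos <- rbind(a, b) + res$jit[[i]]
    bead_frame(pos %% box, box = box, time = i - 1)
  })
  topo <- topology(data.frame(
    bead_index = seq_len(2 * n),
    type = "P1",
    charge_e = 0,
    group = rep(c("actinA", "actinB"), each = n)
  ))
  traj <- structure(list(frames = frames, topology = topo),
                    class = "cg_trajectory")
  set_ground_truth(traj, "gen_dimer_frames",
                   list(com_separations = com_separations,
                        beads_per_cluster = beads_per_cluster,
                        cluster_radius = cluster_radius, box = box,
                        jitter_sd = jitter_sd, center_a = center_a),
                   seed)
}
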