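## Hertz-model analysis of AFM force-distance curves.
##
## Internally every fit is carried out in SI units (Pa, m, N); curves are
## held in the instrument-natural nm/nN and converted at the boundary, since
## the spherical-indenter Hertz equation is unit-homogeneous only in SI.

#' Construct an AFM force curve
#'
#' @param z piezo position, nm; monotone non-decreasing approach segment.
#' @param force cantilever force, nN (deflection already multiplied by the
#'   spring constant).
#' @param spring_constant cantilever spring constant, N/m (metadata).
#' @param tip_radius spherical tip radius, nm.
#' @param poisson Poisson ratio, dimensionless.
#' @return an object of class `force_curve`.
#' @export
force_curve <- function(z, force, spring_constant = 0.02, tip_radius = 10,
                        poisson = 0.4) {
  z <- as.numeric(z); force <- as.numeric(force)
  if (length(z) != length(force))
    stop("'z' and 'force' must have equal length", call. = FALSE)
  if (length(z) < 20)
    stop("a force curve needs at least 20 samples", call. = FALSE)
  if (is.unsorted(z))
    stop("'z' must be monotone non-decreasing (approach segment)",
         call. = FALSE)
  stopifnot_scalar_pos(tip_radius, "tip_radius")
  structure(list(z = z, force = force, spring_constant = spring_constant,
                 tip_radius = tip_radius, poisson = poisson),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("AFM force curve: %d samples, z %.1f..%.1f nm, F max %.4g nN\n",
              length(x$z), min(x$z), max(x$z), max(x$force)))
  invisible(x)
}

#' Hertz force for a spherical indenter
#'
#' Evaluates the Hertz contact model
#' \eqn{F = \frac{4}{3}\frac{E}{1-\gamma^2}\sqrt{R}\,\delta^{3/2}}
#' for a rigid sphere of radius \eqn{R} indenting an elastic half-space of
#' Young's modulus \eqn{E} and Poisson ratio \eqn{\gamma} to depth
#' \eqn{\delta}.  The force is linear in `E` and scales as `depth^1.5`.
#'
#' @param E Young's modulus, Pa.
#' @param poisson Poisson ratio (default 0.4).
#' @param tip_radius indenter radius, nm (default 10).
#' @param depth indentation depth, nm; vectorised.
#' @return force in nN.
#' @examples
#' hertz_force(2440, 0.4, 10, 500)   # ~0.137 nN
#' @export
hertz_force <- function(E, poisson = 0.4, tip_radius = 10, depth) {
  stopifnot_scalar_pos(E, "E")
  stopifnot_scalar_pos(tip_radius, "tip_radius")
  if (any(depth < 0)) stop("'depth' must be non-negative", call. = FALSE)
  R_m <- tip_radius * 1e-9
  d_m <- depth * 1e-9
  F_N <- (4 / 3) * E / (1 - poisson^2) * sqrt(R_m) * d_m^1.5
  F_N * 1e9
}

## residual sum of squares of the piecewise baseline+Hertz model for a
## candidate contact index; closed-form 2-parameter least squares
.piecewise_rss <- function(z, force, i) {
  x <- pmax(z - z[i], 0)^1.5
  sx <- sum(x); sxx <- sum(x * x); sf <- sum(force); sxf <- sum(x * force)
  n <- length(z)
  det <- n * sxx - sx * sx
  if (det <= .Machine$double.eps * n * sxx) {         # degenerate: flat model
    b <- mean(force); cc <- 0
  } else {
    cc <- (n * sxf - sx * sf) / det
    b <- (sf - cc * sx) / n
    if (cc < 0) { b <- mean(force); cc <- 0 }         # no negative stiffness
  }
  sum((force - b - cc * x)^2)
}

#' Estimate the tip-sample contact point of a force curve
#'
#' Fits, for every candidate contact position on the sampled z grid, a
#' piecewise model — flat baseline before contact, Hertzian rise
#' \eqn{b + c\,(z - z_0)^{3/2}} after — by closed-form least squares, and
#' returns the candidate minimising the total residual sum of squares.
#' The exhaustive grid search is deterministic and needs no optimiser
#' tuning; on a noiseless synthetic curve whose grid contains the true
#' contact sample it recovers it exactly.
#'
#' @param curve a [force_curve].
#' @return contact z position in nm.  If the best candidate is the first
#'   grid point the curve starts already in contact; the result then
#'   carries `attr(, "boundary") = TRUE` and a warning is issued.
#' @export
estimate_contact_point <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z; force <- curve$force
  n <- length(z)
  ## noise level from successive baseline differences; rising-segment check
  nb <- max(10L, n %/% 5L)
  base <- force[seq_len(nb)]
  noise_sd <- stats::sd(diff(base)) / sqrt(2)
  if (max(force) - mean(base) <= 3 * noise_sd)
    stop("no contact detected: maximum force does not exceed baseline by 3 noise SD",
         call. = FALSE)
  cand <- seq_len(n - 10L)
  rss <- vapply(cand, function(i) .piecewise_rss(z, force, i), numeric(1))
  best <- cand[which.min(rss)]
  z0 <- z[best]
  if (best == 1L) {
    attr(z0, "boundary") <- TRUE
    warning("contact point at first sample: curve may begin in contact",
            call. = FALSE)
  }
  z0
}

#' Fit the Hertz model to a force curve and extract Young's modulus
#'
#' Estimates the contact point (unless supplied), subtracts the pre-contact
#' baseline, forms the indentation \eqn{\delta = z - z_0} (optionally
#' corrected for cantilever deflection, \eqn{\delta = (z - z_0) - F/k}, for
#' deflection-mode files), and fits \eqn{F = c\,\delta^{3/2}} by linear
#' least squares over the depth window \eqn{0 < \delta \le}`max_depth`.
#' Young's modulus follows as \eqn{E = 3c(1-\gamma^2)/(4\sqrt{R})} in SI.
#'
#' @param curve a [force_curve].
#' @param max_depth depth window, nm (default 500).
#' @param contact_z0 optional known contact point, nm; estimated with
#'   [estimate_contact_point()] if `NULL`.
#' @param deflection_correction apply `delta = (z - z0) - F/k` for curves
#'   whose abscissa is raw piezo travel rather than tip-sample distance
#'   (default `FALSE`: force-mode files).
#' @return a `hertz_fit` list: `young_modulus` (Pa), `contact_z0` (nm),
#'   `depth_used` (nm), `rss` (nN^2), `n_points_fit`.
#' @examples
#' fc <- gen_force_curve(E = 1320, contact_z0 = 150, noise_sd = 0, seed = 2)
#' fit_hertz(fc)$young_modulus   # 1320
#' @export
fit_hertz <- function(curve, max_depth = 500, contact_z0 = NULL,
                      deflection_correction = FALSE) {
  stopifnot(inherits(curve, "force_curve"))
  stopifnot_scalar_pos(max_depth, "max_depth")
  z0 <- contact_z0 %||% as.numeric(estimate_contact_point(curve))
  z <- curve$z; force <- curve$force
  pre <- z <= z0
  baseline <- if (any(pre)) mean(force[pre]) else 0
  f0 <- force - baseline
  delta <- z - z0
  if (deflection_correction)
    delta <- delta - f0 / curve$spring_constant  # nN / (N/m) = nm
  sel <- delta > 0 & delta <= max_depth
  if (sum(sel) < 10)
    stop("insufficient data: fewer than 10 points in the depth window",
         call. = FALSE)
  ## linear LS through the origin in SI units
  d_m <- delta[sel] * 1e-9
  F_N <- f0[sel] * 1e-9
  x <- d_m^1.5
  cc <- sum(F_N * x) / sum(x * x)
  E <- 3 * cc * (1 - curve$poisson^2) / (4 * sqrt(curve$tip_radius * 1e-9))
  if (E <= 0)
    stop("fit produced a non-positive modulus; curve has no Hertzian rise",
         call. = FALSE)
  resid_nN <- f0[sel] - cc * x * 1e9
  structure(list(young_modulus = E,
                 contact_z0 = z0,
                 depth_used = max(delta[sel]),
                 rss = sum(resid_nN^2),
                 n_points_fit = sum(sel)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz fit: E = %.4g kPa, contact at %.1f nm, %d points (depth <= %.0f nm)\n",
              x$young_modulus / 1e3, x$contact_z0, x$n_points_fit,
              x$depth_used))
  invisible(x)
}

#' Per-group Young's modulus summary with percent change versus control
#'
#' @param fits_by_group named list; each element is a list of `hertz_fit`
#'   objects or a numeric vector of moduli in kPa.
#' @param control name of the control group.
#' @return data frame with `group`, `n`, `mean_E_kpa`, `sd_E_kpa`, and
#'   `percent_change` = 100 (E_ctrl - E_grp) / E_ctrl.
#' @export
group_stiffness_summary <- function(fits_by_group, control) {
  if (!is.list(fits_by_group) || is.null(names(fits_by_group)) ||
      any(!nzchar(names(fits_by_group))))
    stop("'fits_by_group' must be a named list", call. = FALSE)
  if (!control %in% names(fits_by_group))
    stop(sprintf("control group '%s' not present", control), call. = FALSE)
  e_kpa <- lapply(fits_by_group, function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    vapply(g, function(f) f$young_modulus / 1e3, numeric(1))
  })
  if (any(lengths(e_kpa) == 0))
    stop("every group must be non-empty", call. = FALSE)
  mean_e <- vapply(e_kpa, mean, numeric(1))
  sd_e <- vapply(e_kpa, function(v) if (length(v) > 1) stats::sd(v) else 0,
                 numeric(1))
  ctrl <- mean_e[[control]]
  data.frame(group = names(e_kpa),
             n = lengths(e_kpa),
             mean_E_kpa = unname(mean_e),
             sd_E_kpa = unname(sd_e),
             percent_change = unname(100 * (ctrl - mean_e) / ctrl),
             row.names = NULL)
}
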