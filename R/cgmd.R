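## Coarse-grained graphene-oxide sheet construction and trajectory
## observables: periodic geometry, COM distances, native contacts,
## nonbonded energies, and 2D free-energy landscapes.
##
## Lengths in nm, energies in kJ/mol, charges in e.  Coordinates live in a
## cubic periodic box and are wrapped into [0, box).

#' Construct a periodic bead frame
#'
#' @param positions N x 3 numeric matrix, nm; wrapped into `[0, box)`.
#' @param box cubic box edge, nm (default 25).
#' @param time frame time, ns.
#' @return a `bead_frame`.
#' @export
bead_frame <- function(positions, box = 25, time = 0) {
  stopifnot_scalar_pos(box, "box")
  positions <- as.matrix(positions)
  if (ncol(positions) != 3)
    stop("'positions' must be an N x 3 matrix", call. = FALSE)
  structure(list(positions = positions %% box, box = box, time = time),
            class = "bead_frame")
}

#' @export
print.bead_frame <- function(x, ...) {
  cat(sprintf("bead frame: %d beads, box %.2f nm, t = %g ns\n",
              nrow(x$positions), x$box, x$time))
  invisible(x)
}

#' Construct a bead topology table
#'
#' @param df data frame with columns `bead_index`, `type`, `charge_e`,
#'   `group` (e.g. `actinA`, `actinB`, `GO`).
#' @return a `topology` data frame.
#' @export
topology <- function(df) {
  need <- c("bead_index", "type", "charge_e", "group")
  if (!all(need %in% names(df)))
    stop("topology needs columns bead_index, type, charge_e, group",
         call. = FALSE)
  df <- df[order(df$bead_index), need, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("topology", "data.frame"))
}

#' Construct a symmetric Lennard-Jones parameter table
#'
#' @param df data frame with columns `type_a`, `type_b`, `sigma_nm`,
#'   `epsilon_kjmol`; one row per unordered type pair.
#' @return an `lj_table` data frame (both orderings stored).
#' @export
lj_table <- function(df) {
  need <- c("type_a", "type_b", "sigma_nm", "epsilon_kjmol")
  if (!all(need %in% names(df)))
    stop("LJ table needs columns type_a, type_b, sigma_nm, epsilon_kjmol",
         call. = FALSE)
  sw <- df[df$type_a != df$type_b, , drop = FALSE]
  if (nrow(sw) > 0) {
    names(sw)[1:2] <- c("type_b", "type_a")
    df <- rbind(df[need], sw[need])
  }
  df <- unique(df[need])
  structure(df, class = c("lj_table", "data.frame"))
}

.lj_lookup <- function(tab, ta, tb) {
  key <- paste(tab$type_a, tab$type_b)
  idx <- match(paste(ta, tb), key)
  if (any(is.na(idx)))
    stop(sprintf("missing LJ parameters for type pair(s): %s",
                 paste(unique(paste(ta, tb)[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  list(sigma = tab$sigma_nm[idx], eps = tab$epsilon_kjmol[idx])
}

#' Build a coarse-grained graphene-oxide sheet
#'
#' Places `2 * n_cells_x * n_cells_y` beads on a honeycomb (graphene)
#' lattice with constant nearest-neighbour spacing and randomly relabels
#' exactly `round(oxidation_fraction * N)` of them, chosen uniformly
#' without replacement, as oxidised SP1 beads (epoxy/hydroxyl groups); the
#' rest remain graphene SG4 beads.  Nearest-neighbour pairs form the bond
#' list, whose graph is connected.
#'
#' @param n_cells_x,n_cells_y lattice cells per direction (>= 1).
#' @param oxidation_fraction fraction of SP1 beads in `[0, 1]`
#'   (default 0.48).
#' @param lattice_spacing nearest-neighbour bead distance, nm
#'   (default 0.24, a 2:1 mapping of the graphene C-C bond).
#' @param seed integer RNG seed for the SP1 placement.
#' @return a `go_sheet`: list with `positions` (N x 3, nm, z = 0), `types`
#'   (`"SG4"`/`"SP1"`), `bonds` (2-column index matrix),
#'   `oxidation_fraction`, `lattice_spacing`.
#' @examples
#' sh <- build_go_sheet(50, 100, 0.48, seed = 1)
#' sum(sh$types == "SP1")   # exactly 4800 of 10000
#' @export
build_go_sheet <- function(n_cells_x, n_cells_y, oxidation_fraction = 0.48,
                           lattice_spacing = 0.24, seed = 1) {
  if (n_cells_x < 1 || n_cells_y < 1)
    stop("lattice dimensions must be at least 1", call. = FALSE)
  if (oxidation_fraction < 0 || oxidation_fraction > 1)
    stop("'oxidation_fraction' must lie in [0, 1]", call. = FALSE)
  a <- lattice_spacing
  ## honeycomb: cell (i, j) holds sublattice beads A and B; B bonds to the
  ## A beads of cells (i, j), (i-1, j) and (i, j-1), all at distance a
  ij <- expand.grid(i = 0:(n_cells_x - 1), j = 0:(n_cells_y - 1))
  ox <- ij$i * sqrt(3) * a + ij$j * sqrt(3) / 2 * a
  oy <- ij$j * 1.5 * a
  pos <- rbind(cbind(ox, oy),                          # A sublattice
               cbind(ox + sqrt(3) / 2 * a, oy + a / 2)) # B sublattice
  n_cells <- nrow(ij)
  n <- 2L * n_cells
  idx_a <- function(i, j) j * n_cells_x + i + 1L
  idx_b <- function(i, j) n_cells + j * n_cells_x + i + 1L
  bonds <- cbind(idx_b(ij$i, ij$j), idx_a(ij$i, ij$j))
  b2 <- ij[ij$i > 0, ]
  if (nrow(b2) > 0)
    bonds <- rbind(bonds, cbind(idx_b(b2$i - 1L, b2$j), idx_a(b2$i, b2$j)))
  b3 <- ij[ij$j > 0, ]
  if (nrow(b3) > 0)
    bonds <- rbind(bonds, cbind(idx_b(b3$i, b3$j - 1L), idx_a(b3$i, b3$j)))
  n_sp1 <- round(oxidation_fraction * n)
  types <- rep("SG4", n)
  if (n_sp1 > 0)
    types[with_seed(seed, sample.int(n, n_sp1))] <- "SP1"
  sheet <- structure(list(positions = cbind(pos, 0),
                          types = types,
                          bonds = bonds,
                          oxidation_fraction = oxidation_fraction,
                          lattice_spacing = a),
                     class = "go_sheet")
  set_ground_truth(sheet, "build_go_sheet",
                   list(n_cells_x = n_cells_x, n_cells_y = n_cells_y,
                        oxidation_fraction = oxidation_fraction,
                        lattice_spacing = a, n_sp1 = n_sp1),
                   seed)
}

#' @export
print.go_sheet <- function(x, ...) {
  cat(sprintf("GO sheet: %d beads (%d SP1, %d SG4), %d bonds, spacing %.3f nm\n",
              length(x$types), sum(x$types == "SP1"),
              sum(x$types == "SG4"), nrow(x$bonds), x$lattice_spacing))
  invisible(x)
}

#' Minimum-image distance in a cubic periodic box
#'
#' @param a,b positions (length-3 vectors or N x 3 matrices), nm.
#' @param box cubic box edge, nm.
#' @return Euclidean distance(s) under the minimum-image convention.
#' @export
min_image_distance <- function(a, b, box) {
  stopifnot_scalar_pos(box, "box")
  d <- rbind(a) - rbind(b)
  d <- d - box * round(d / box)
  unname(sqrt(rowSums(d^2)))
}

#' Centre of mass of a bead group under periodic boundaries
#'
#' Unwraps the group's beads relative to its first bead by the
#' minimum-image convention, averages (equal bead masses, or topology
#' masses with `mass_weighted = TRUE` and a `mass` column), and re-wraps
#' into the box — so a compact cluster straddling the boundary gets a COM
#' inside the cluster, not in mid-box.
#'
#' @param frame a [bead_frame].
#' @param topology a [topology] aligned with the frame's bead order.
#' @param group group label to average over.
#' @param mass_weighted use a `mass` column of the topology as weights.
#' @return length-3 position, nm, in `[0, box)`.
#' @export
group_com <- function(frame, topology, group, mass_weighted = FALSE) {
  stopifnot(inherits(frame, "bead_frame"))
  idx <- which(topology$group == group)
  if (length(idx) == 0)
    stop(sprintf("group '%s' is empty", group), call. = FALSE)
  pos <- frame$positions[idx, , drop = FALSE]
  box <- frame$box
  d <- sweep(pos, 2, pos[1, ])
  d <- d - box * round(d / box)
  span <- apply(d, 2, function(v) diff(range(v)))
  if (any(span > box / 2))
    stop(sprintf("group '%s' spans more than box/2 after unwrapping: COM ambiguous",
                 group), call. = FALSE)
  w <- if (mass_weighted) {
    if (is.null(topology$mass))
      stop("mass_weighted = TRUE requires a 'mass' topology column",
           call. = FALSE)
    topology$mass[idx]
  } else rep(1, length(idx))
  com <- pos[1, ] + colSums(d * w) / sum(w)
  unname(com %% box)
}

#' Per-frame COM distance between two bead groups
#'
#' @param traj a `cg_trajectory` (list with `frames` and `topology`) or a
#'   plain list of [bead_frame]s.
#' @param topology a [topology]; defaults to the trajectory's own.
#' @param groupA,groupB group labels.
#' @return data frame with `frame`, `time`, `distance` (nm).
#' @export
com_distance_series <- function(traj, topology = NULL, groupA = "actinA",
                                groupB = "actinB") {
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else traj
  topology <- topology %||%
    (if (inherits(traj, "cg_trajectory")) traj$topology else NULL)
  if (is.null(topology)) stop("a topology is required", call. = FALSE)
  d <- vapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    tryCatch(
      min_image_distance(group_com(fr, topology, groupA),
                         group_com(fr, topology, groupB), fr$box),
      error = function(e)
        stop(sprintf("frame %d: %s", i, conditionMessage(e)), call. = FALSE))
  }, numeric(1))
  data.frame(frame = seq_along(frames),
             time = vapply(frames, function(f) f$time, numeric(1)),
             distance = d)
}

.pair_indices <- function(topology, groupA, groupB) {
  ia <- which(topology$group == groupA)
  ib <- which(topology$group == groupB)
  if (length(ia) == 0 || length(ib) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (length(intersect(ia, ib)) > 0)
    stop("groups must be disjoint", call. = FALSE)
  list(ia = ia, ib = ib)
}

.pair_distances <- function(frame, i, j) {
  d <- frame$positions[i, , drop = FALSE] - frame$positions[j, , drop = FALSE]
  d <- d - frame$box * round(d / frame$box)
  sqrt(rowSums(d^2))
}

#' Reference (native) inter-group contacts
#'
#' All inter-group bead pairs whose minimum-image distance in the reference
#' frame is below `cutoff` — the native-contact list against which later
#' frames are scored.
#'
#' @param ref_frame a [bead_frame] (the reference structure).
#' @param topology a [topology].
#' @param groupA,groupB disjoint group labels.
#' @param cutoff contact distance, nm (default 0.6).
#' @return a `contact_set`: data frame (`i`, `j`, `ref_distance`) sorted by
#'   (`i`, `j`), with the `cutoff` as attribute.
#' @export
reference_contacts <- function(ref_frame, topology, groupA = "actinA",
                               groupB = "actinB", cutoff = 0.6) {
  p <- .pair_indices(topology, groupA, groupB)
  pairs <- expand.grid(i = p$ia, j = p$ib)
  d <- .pair_distances(ref_frame, pairs$i, pairs$j)
  sel <- d < cutoff
  if (!any(sel))
    warning("no native contacts below the cutoff in the reference frame",
            call. = FALSE)
  cs <- data.frame(i = pairs$i[sel], j = pairs$j[sel], ref_distance = d[sel])
  cs <- cs[order(cs$i, cs$j), , drop = FALSE]
  rownames(cs) <- NULL
  structure(cs, class = c("contact_set", "data.frame"), cutoff = cutoff)
}

#' Count retained native contacts in a frame
#'
#' @param frame a [bead_frame].
#' @param contacts a `contact_set` from [reference_contacts()].
#' @param cutoff counting distance, nm (defaults to the reference cutoff).
#' @return number of reference pairs currently closer than `cutoff`.
#' @export
count_contacts <- function(frame, contacts, cutoff = NULL) {
  cutoff <- cutoff %||% attr(contacts, "cutoff")
  if (nrow(contacts) == 0) return(0L)
  if (max(contacts$i, contacts$j) > nrow(frame$positions))
    stop("contact indices out of range for this frame", call. = FALSE)
  sum(.pair_distances(frame, contacts$i, contacts$j) < cutoff)
}

## GROMACS-style force-switch shift of an r^-p term on [r1, rc]:
## V(r) = r^-p - A/3 (r-r1)^3 - B/4 (r-r1)^4 - C   (r1 < r <= rc)
##      = r^-p - C                                  (r <= r1)
.switched_power <- function(r, p, r1, rc) {
  A <- -p * ((p + 4) * rc - (p + 1) * r1) / (rc^(p + 2) * (rc - r1)^2)
  B <-  p * ((p + 3) * rc - (p + 1) * r1) / (rc^(p + 2) * (rc - r1)^3)
  C <- 1 / rc^p - A / 3 * (rc - r1)^3 - B / 4 * (rc - r1)^4
  out <- r^(-p) - C
  sw <- r > r1
  out[sw] <- out[sw] - A / 3 * (r[sw] - r1)^3 - B / 4 * (r[sw] - r1)^4
  out
}

#' Inter-group Lennard-Jones energy of a frame
#'
#' Sums \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} over all
#' minimum-image inter-group pairs with `r < r_cut`.  Modes: `"plain"`
#' (bare truncation, for closed-form checks), `"plain_shift"` (potential
#' shifted to zero at the cutoff; default), `"force_switch"` (force
#' smoothly switched to zero on `[r_switch, r_cut]` with the matching
#' potential offset, the scheme used with a 1.2 nm Martini cutoff).
#'
#' @param frame a [bead_frame].
#' @param topology a [topology].
#' @param lj a [lj_table] covering every in-scope type pair.
#' @param groupA,groupB disjoint group labels.
#' @param r_cut cutoff, nm (default 1.2).
#' @param mode `"plain_shift"`, `"force_switch"` or `"plain"`.
#' @param r_switch switch-on radius for `"force_switch"`, nm (default 0.9).
#' @return total energy, kJ/mol.
#' @export
lj_energy <- function(frame, topology, lj, groupA = "actinA",
                      groupB = "actinB", r_cut = 1.2,
                      mode = c("plain_shift", "force_switch", "plain"),
                      r_switch = 0.9) {
  mode <- match.arg(mode)
  p <- .pair_indices(topology, groupA, groupB)
  pairs <- expand.grid(i = p$ia, j = p$ib)
  r <- .pair_distances(frame, pairs$i, pairs$j)
  sel <- r < r_cut
  if (!any(sel)) return(0)
  r <- r[sel]
  prm <- .lj_lookup(lj, topology$type[pairs$i[sel]],
                    topology$type[pairs$j[sel]])
  sig <- prm$sigma; eps <- prm$eps
  v <- switch(mode,
    plain = {
      sr6 <- (sig / r)^6
      4 * eps * (sr6^2 - sr6)
    },
    plain_shift = {
      sr6 <- (sig / r)^6
      src6 <- (sig / r_cut)^6
      4 * eps * (sr6^2 - sr6) - 4 * eps * (src6^2 - src6)
    },
    force_switch = {
      t12 <- .switched_power(r, 12, r_switch, r_cut)
      t6 <- .switched_power(r, 6, r_switch, r_cut)
      4 * eps * (sig^12 * t12 - sig^6 * t6)
    })
  sum(v)
}

#' Inter-group Coulomb energy of a frame
#'
#' Screened Coulomb sum \eqn{f q_i q_j / (\epsilon_r r)} over minimum-image
#' inter-group pairs with `r < r_cut`, with
#' \eqn{f = 138.935} kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}.  The default
#' reaction-field mode adds the correction
#' \eqn{k_{rf} r^2 - c_{rf}} (conducting boundary,
#' \eqn{k_{rf} = 1/(2 r_c^3)}, \eqn{c_{rf} = 3/(2 r_c)}), which vanishes at
#' the cutoff — the Martini convention with \eqn{\epsilon_r = 15}.  A
#' `"plain"` mode gives the bare screened sum for closed-form checks.
#'
#' @param frame a [bead_frame].
#' @param topology a [topology] with a `charge_e` column.
#' @param groupA,groupB disjoint group labels.
#' @param r_cut cutoff, nm (default 1.2).
#' @param eps_r relative dielectric constant (default 15).
#' @param mode `"reaction_field"` (default) or `"plain"`.
#' @return total energy, kJ/mol.
#' @export
coulomb_energy <- function(frame, topology, groupA = "actinA",
                           groupB = "actinB", r_cut = 1.2, eps_r = 15,
                           mode = c("reaction_field", "plain")) {
  mode <- match.arg(mode)
  if (eps_r <= 0) stop("'eps_r' must be positive", call. = FALSE)
  f_elec <- 138.935
  p <- .pair_indices(topology, groupA, groupB)
  pairs <- expand.grid(i = p$ia, j = p$ib)
  r <- .pair_distances(frame, pairs$i, pairs$j)
  qq <- topology$charge_e[pairs$i] * topology$charge_e[pairs$j]
  sel <- r < r_cut & qq != 0
  if (!any(sel)) return(0)
  r <- r[sel]; qq <- qq[sel]
  v <- switch(mode,
    plain = f_elec * qq / (eps_r * r),
    reaction_field = {
      k_rf <- 1 / (2 * r_cut^3)
      c_rf <- 1 / r_cut + k_rf * r_cut^2
      f_elec * qq / eps_r * (1 / r + k_rf * r^2 - c_rf)
    })
  sum(v)
}

#' 2D free-energy landscape from collective-variable samples
#'
#' Bins the samples on a regular 2D grid, converts counts to probabilities
#' and applies Boltzmann inversion \eqn{F = -k_B T \ln(P / P_{max})}, so
#' the minimum over occupied bins is exactly zero.  Empty bins carry `NA`
#' (never interpolated).  \eqn{k_B = 0.0083145} kJ/(mol K).
#'
#' @param x_samples,y_samples equal-length sample vectors (n >= 100).
#' @param x_bins,y_bins scalar bin width, or a vector of bin edges.
#' @param temperature K (default 300).
#' @return an `fe_landscape`: list with `x_edges`, `y_edges`, `x_centers`,
#'   `y_centers`, matrix `F` (kJ/mol, x along rows), `counts`, `kT`.
#' @export
free_energy_2d <- function(x_samples, y_samples, x_bins, y_bins,
                           temperature = 300) {
  if (length(x_samples) != length(y_samples))
    stop("sample vectors must have equal length", call. = FALSE)
  n <- length(x_samples)
  if (n < 100) stop("at least 100 samples are required", call. = FALSE)
  edges <- function(v, b) {
    if (length(b) > 1) return(b)
    stopifnot_scalar_pos(b, "bin width")
    b * (floor(min(v) / b):ceiling(max(v) / b + 1e-9))
  }
  xe <- edges(x_samples, x_bins)
  ye <- edges(y_samples, y_bins)
  xi <- findInterval(x_samples, xe, rightmost.closed = TRUE,
                     all.inside = TRUE)
  yi <- findInterval(y_samples, ye, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, length(xe) - 1, length(ye) - 1)
  tab <- table(factor(xi, levels = seq_len(nrow(counts))),
               factor(yi, levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  if (sum(counts > 0) == 1)
    warning("degenerate landscape: all samples fall in one bin",
            call. = FALSE)
  kT <- 0.0083145 * temperature
  F <- matrix(NA_real_, nrow(counts), ncol(counts))
  occ <- counts > 0
  F[occ] <- -kT * log(counts[occ] / max(counts))
  structure(list(x_edges = xe, y_edges = ye,
                 x_centers = (xe[-1] + xe[-length(xe)]) / 2,
                 y_centers = (ye[-1] + ye[-length(ye)]) / 2,
                 F = F, counts = counts, kT = kT,
                 temperature = temperature),
            class = "fe_landscape")
}

#' @export
print.fe_landscape <- function(x, ...) {
  cat(sprintf("free-energy landscape: %d x %d bins, %d occupied, kT = %.3f kJ/mol\n",
              nrow(x$F), ncol(x$F), sum(!is.na(x$F)), x$kT))
  invisible(x)
}

#' Detect local minima of a 2D free-energy landscape
#'
#' Candidate bins are occupied bins whose full 8-neighbourhood is occupied
#' and strictly higher (isolated tail bins with empty neighbourhoods never
#' qualify).  Candidates are then filtered by topographic prominence:
#' walking up from a candidate, the lowest saddle connecting it to any
#' deeper basin must lie at least `depth_threshold` above it, so the
#' shallow dips that finite-sample counting noise carves into the tails of
#' a well are merged into their parent basin rather than reported.
#' Implemented by flood-filling the occupied bins below
#' `F + depth_threshold` from each candidate (8-connected), in ascending
#' order of `F`, and rejecting candidates whose flood region reaches an
#' already-accepted deeper minimum.
#'
#' @param landscape an `fe_landscape`.
#' @param depth_threshold minimum prominence, kJ/mol (default 1).
#' @return data frame (`x_center`, `y_center`, `F`) sorted by `F`
#'   ascending; may be empty (e.g. for a flat landscape).
#' @export
find_minima <- function(landscape, depth_threshold = 1.0) {
  stopifnot(inherits(landscape, "fe_landscape"))
  F <- landscape$F
  if (sum(!is.na(F)) < 9)
    stop("landscape needs at least 9 occupied bins", call. = FALSE)
  nr <- nrow(F); nc <- ncol(F)
  cand <- list()
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      f0 <- F[i, j]
      if (is.na(f0)) next
      nb <- F[(i - 1):(i + 1), (j - 1):(j + 1)][-5]
      ## <= admits exact ties at a well bottom (the flood filter merges
      ## them); requiring one strict inequality keeps flat regions out
      if (anyNA(nb) || !all(f0 <= nb) || !any(f0 < nb)) next
      cand[[length(cand) + 1]] <- c(i, j, f0)
    }
  }
  if (length(cand) == 0)
    return(data.frame(x_center = numeric(), y_center = numeric(),
                      F = numeric()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  accepted <- matrix(numeric(0), 0, 3)
  flood_reaches <- function(i0, j0, level, targets) {
    ## 8-connected flood over occupied bins with F < level
    seen <- matrix(FALSE, nr, nc)
    stack <- list(c(i0, j0))
    seen[i0, j0] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (nrow(targets) > 0 &&
          any(targets[, 1] == p[1] & targets[, 2] == p[2]))
        return(TRUE)
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (seen[ii, jj] || is.na(F[ii, jj]) || F[ii, jj] >= level) next
        seen[ii, jj] <- TRUE
        stack[[length(stack) + 1]] <- c(ii, jj)
      }
    }
    FALSE
  }
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]; f0 <- cand[k, 3]
    if (!flood_reaches(i, j, f0 + depth_threshold,
                       accepted[, 1:2, drop = FALSE]))
      accepted <- rbind(accepted, cand[k, ])
  }
  out <- data.frame(x_center = landscape$x_centers[accepted[, 1]],
                    y_center = landscape$y_centers[accepted[, 2]],
                    F = accepted[, 3])
  out[order(out$F), , drop = FALSE]
}
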