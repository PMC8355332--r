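# Coarse-grained observables against brute-force pair-loop / 27-image
# oracles, plus sheet composition and free-energy landscapes.

test_that("GO sheet composition follows the rounding rule exactly", {
  sh <- build_go_sheet(50, 100, oxidation_fraction = 0.48, seed = 1)
  expect_equal(length(sh$types), 10000)
  expect_equal(sum(sh$types == "SP1"), 4800)
  expect_equal(sum(build_go_sheet(7, 9, 0, seed = 1)$types == "SP1"), 0)
  expect_equal(sum(build_go_sheet(7, 9, 1, seed = 1)$types == "SG4"), 0)
  # arbitrary N and fraction: count is round(fraction * N)
  for (frac in c(0.1, 0.333, 0.48, 0.77)) {
    sh2 <- build_go_sheet(11, 13, frac, seed = 2)
    expect_equal(sum(sh2$types == "SP1"), round(frac * 2 * 11 * 13))
  }
})

test_that("GO sheet lattice has constant spacing and a connected bond graph", {
  sh <- build_go_sheet(6, 5, 0.48, lattice_spacing = 0.24, seed = 3)
  d <- sqrt(rowSums((sh$positions[sh$bonds[, 1], ] -
                     sh$positions[sh$bonds[, 2], ])^2))
  expect_equal(d, rep(0.24, nrow(sh$bonds)), tolerance = 1e-12)
  # bond graph connectivity (independent graph library as oracle)
  g <- igraph::graph_from_edgelist(sh$bonds, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
  # single row and single column sheets stay connected too
  for (dims in list(c(8, 1), c(1, 8))) {
    shl <- build_go_sheet(dims[1], dims[2], 0.48, seed = 4)
    gl <- igraph::graph_from_edgelist(shl$bonds, directed = FALSE)
    expect_equal(igraph::components(gl)$no, 1)
  }
})

test_that("minimum-image distances agree with the 27-image oracle", {
  expect_equal(min_image_distance(c(1, 0, 0), c(24, 0, 0), 25), 2)
  expect_equal(min_image_distance(c(3, 3, 3), c(3, 3, 3), 25), 0)
  set.seed(31)
  for (k in 1:50) {
    a <- runif(3, 0, 25); b <- runif(3, 0, 25)
    expect_equal(min_image_distance(a, b, 25), oracle_min_image(a, b, 25),
                 tolerance = 1e-12)
  }
})

test_that("group COM unwraps clusters across the periodic boundary", {
  topo <- topology(data.frame(bead_index = 1:3, type = "P1", charge_e = 0,
                              group = "A"))
  # single bead: its own position
  single <- topology(data.frame(bead_index = 1, type = "P1", charge_e = 0,
                                group = "A"))
  fr1 <- bead_frame(matrix(c(3, 4, 5), 1), box = 25)
  expect_equal(group_com(fr1, single, "A"), c(3, 4, 5))

  # compact cluster straddling the boundary: COM inside the cluster
  fr <- bead_frame(rbind(c(24.6, 1, 1), c(0.2, 1, 1), c(24.9, 1, 1)),
                   box = 25)
  com <- group_com(fr, topo, "A")
  expect_equal(com, c((24.6 + 25.2 + 24.9) / 3 %% 25, 1, 1),
               tolerance = 1e-12)

  # translating all beads translates the COM (mod box)
  shift <- c(7.3, -4.1, 11.9)
  fr2 <- bead_frame(sweep(fr$positions, 2, shift, "+") %% 25, box = 25)
  com2 <- group_com(fr2, topo, "A")
  expect_equal(min_image_distance(com2, (com + shift) %% 25, 25), 0,
               tolerance = 1e-9)

  # a group spanning more than half the box is ambiguous
  wide <- bead_frame(rbind(c(0, 0, 0), c(13, 0, 0), c(7, 0, 0)), box = 25)
  expect_error(group_com(wide, topo, "A"), "ambiguous")
})

test_that("COM distance series matches dimer ground truth and sampling bounds", {
  tr <- gen_dimer_frames(c(3.22, 3.5), jitter_sd = 0, seed = 1)
  expect_equal(com_distance_series(tr)$distance, c(3.22, 3.5),
               tolerance = 1e-9)
  # identical groups give zero distance
  topoAA <- tr$topology
  d <- min_image_distance(group_com(tr$frames[[1]], topoAA, "actinA"),
                          group_com(tr$frames[[1]], topoAA, "actinA"), 25)
  expect_equal(d, 0)
  # jittered frames: mean within 3 SE of the set separation
  trj <- gen_dimer_frames(rep(3.5, 100), beads_per_cluster = 20,
                          jitter_sd = 0.05, seed = 2)
  dj <- com_distance_series(trj)$distance
  expect_lt(abs(mean(dj) - 3.5), 3 * sd(dj) / sqrt(100) + 1e-3)
})

test_that("native contacts match the brute-force pair loop", {
  fx <- contact_fixture(50, 50, box = 25, seed = 41)
  cs <- reference_contacts(fx$frame, fx$topo, "A", "B", cutoff = 0.6)
  expect_gt(nrow(cs), 0)
  expect_equal(nrow(cs), oracle_contacts(fx$frame, fx$topo, "A", "B", 0.6))
  expect_false(any(duplicated(cs[c("i", "j")])))
  expect_true(all(cs$ref_distance < 0.6))
  # the reference frame retains every native contact
  expect_equal(count_contacts(fx$frame, cs), nrow(cs))
  # recounts on jittered frames agree with the oracle
  set.seed(5)
  jit <- bead_frame(fx$frame$positions +
                      matrix(rnorm(300, 0, 0.05), ncol = 3), box = 25)
  oracle_n <- 0L
  for (k in seq_len(nrow(cs)))
    if (oracle_min_image(jit$positions[cs$i[k], ],
                         jit$positions[cs$j[k], ], 25) < 0.6)
      oracle_n <- oracle_n + 1L
  expect_equal(count_contacts(jit, cs), oracle_n)

  # translating group B 10 nm away empties the count
  moved <- fx$frame$positions
  moved[fx$topo$group == "B", 1] <-
    (moved[fx$topo$group == "B", 1] + 10) %% 25
  expect_equal(count_contacts(bead_frame(moved, box = 25), cs), 0)

  # two beads 0.5 nm apart, cutoff 0.6: one pair; far groups: none
  two <- bead_frame(rbind(c(1, 1, 1), c(1.5, 1, 1)), box = 25)
  tt <- topology(data.frame(bead_index = 1:2, type = "P1", charge_e = 0,
                            group = c("A", "B")))
  expect_equal(nrow(reference_contacts(two, tt, "A", "B", 0.6)), 1)
  far <- bead_frame(rbind(c(1, 1, 1), c(6, 1, 1)), box = 25)
  expect_warning(e <- reference_contacts(far, tt, "A", "B", 0.6),
                 "no native contacts")
  expect_equal(nrow(e), 0)
})

test_that("LJ energies match the double-loop oracle and the LJ minimum", {
  lj <- lj_table(lj_fixture_table())
  # two beads at the potential minimum r = 2^(1/6) sigma give -epsilon
  sig <- 0.47; eps <- 3.5
  two <- bead_frame(rbind(c(1, 1, 1), c(1 + 2^(1 / 6) * sig, 1, 1)),
                    box = 25)
  tt <- topology(data.frame(bead_index = 1:2, type = "SG4", charge_e = 0,
                            group = c("A", "B")))
  expect_equal(lj_energy(two, tt, lj, "A", "B", mode = "plain"), -eps,
               tolerance = 1e-12)
  # beyond the cutoff nothing contributes
  apart <- bead_frame(rbind(c(1, 1, 1), c(2.4, 1, 1)), box = 25)
  expect_equal(lj_energy(apart, tt, lj, "A", "B"), 0)

  # 20-bead random frame vs brute force, 1e-10 relative
  fx <- random_cg_fixture(10, 10, box = 4, seed = 51)
  mine <- lj_energy(fx$frame, fx$topo, lj, "A", "B", mode = "plain")
  ora <- oracle_lj_plain(fx$frame, fx$topo, lj_fixture_table(), "A", "B",
                         1.2)
  expect_equal(mine, ora, tolerance = 1e-10)

  # missing type-pair parameters are an error
  lj_small <- lj_table(data.frame(type_a = "SG4", type_b = "SG4",
                                  sigma_nm = 0.47, epsilon_kjmol = 3.5))
  mixed <- bead_frame(rbind(c(1, 1, 1), c(1.5, 1, 1)), box = 25)
  tmix <- topology(data.frame(bead_index = 1:2, type = c("SG4", "SP1"),
                              charge_e = 0, group = c("A", "B")))
  expect_error(lj_energy(mixed, tmix, lj_small, "A", "B"), "missing LJ")
})

test_that("shifted and force-switched LJ modes vanish smoothly at the cutoff", {
  lj <- lj_table(lj_fixture_table())
  tt <- topology(data.frame(bead_index = 1:2, type = "SG4", charge_e = 0,
                            group = c("A", "B")))
  e_at <- function(r, mode) lj_energy(
    bead_frame(rbind(c(1, 1, 1), c(1 + r, 1, 1)), box = 25),
    tt, lj, "A", "B", r_cut = 1.2, mode = mode, r_switch = 0.9)
  # both modes go to zero at the cutoff
  expect_lt(abs(e_at(1.2 - 1e-9, "plain_shift")), 1e-6)
  expect_lt(abs(e_at(1.2 - 1e-9, "force_switch")), 1e-6)
  # force switch: potential continuous at r_switch and force (slope)
  # continuous at the cutoff
  expect_equal(e_at(0.9 - 1e-7, "force_switch"),
               e_at(0.9 + 1e-7, "force_switch"), tolerance = 1e-5)
  slope_end <- (e_at(1.2 - 1e-5, "force_switch") -
                e_at(1.2 - 2e-5, "force_switch")) / 1e-5
  expect_lt(abs(slope_end), 1e-2)
  # below the switch radius the force equals the bare LJ force
  h <- 1e-6
  f_sw <- (e_at(0.8 + h, "force_switch") - e_at(0.8 - h, "force_switch"))
  f_pl <- (e_at(0.8 + h, "plain") - e_at(0.8 - h, "plain"))
  expect_equal(f_sw, f_pl, tolerance = 1e-6)
})

test_that("Coulomb energies match hand arithmetic and the oracle", {
  tt <- topology(data.frame(bead_index = 1:2, type = "P1",
                            charge_e = c(1, 1), group = c("A", "B")))
  pair_at <- function(r) bead_frame(rbind(c(1, 1, 1), c(1 + r, 1, 1)),
                                    box = 25)
  # f/(eps_r * r) with f = 138.935, eps_r = 15, r = 1 nm
  expect_equal(coulomb_energy(pair_at(1), tt, "A", "B", mode = "plain"),
               138.935 / 15, tolerance = 1e-12)
  # reaction-field correction vanishes at the cutoff
  expect_lt(abs(coulomb_energy(pair_at(1.2 - 1e-9), tt, "A", "B")), 1e-6)
  # beyond the cutoff and for neutral beads: zero
  expect_equal(coulomb_energy(pair_at(1.5), tt, "A", "B"), 0)
  ttn <- topology(data.frame(bead_index = 1:2, type = "P1", charge_e = 0,
                             group = c("A", "B")))
  expect_equal(coulomb_energy(pair_at(0.5), ttn, "A", "B"), 0)

  fx <- random_cg_fixture(10, 10, box = 4, seed = 61)
  expect_equal(coulomb_energy(fx$frame, fx$topo, "A", "B", mode = "plain"),
               oracle_coulomb_plain(fx$frame, fx$topo, "A", "B", 1.2, 15),
               tolerance = 1e-10)
  expect_error(coulomb_energy(fx$frame, fx$topo, "A", "B", eps_r = -1),
               "positive")
})

test_that("pairwise observables are invariant under global translation", {
  lj <- lj_table(lj_fixture_table())
  fx <- random_cg_fixture(15, 15, box = 5, seed = 71)
  shift <- c(2.2, -1.7, 3.9)
  fr2 <- bead_frame(sweep(fx$frame$positions, 2, shift, "+") %% 5, box = 5)
  cs <- reference_contacts(fx$frame, fx$topo, "A", "B", cutoff = 1.8)
  expect_equal(count_contacts(fr2, cs), nrow(cs))
  expect_equal(lj_energy(fr2, fx$topo, lj, "A", "B"),
               lj_energy(fx$frame, fx$topo, lj, "A", "B"),
               tolerance = 1e-10)
  expect_equal(coulomb_energy(fr2, fx$topo, "A", "B"),
               coulomb_energy(fx$frame, fx$topo, "A", "B"),
               tolerance = 1e-10)
  d1 <- min_image_distance(group_com(fx$frame, fx$topo, "A"),
                           group_com(fx$frame, fx$topo, "B"), 5)
  d2 <- min_image_distance(group_com(fr2, fx$topo, "A"),
                           group_com(fr2, fx$topo, "B"), 5)
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("free-energy landscapes are Boltzmann inversions anchored at zero", {
  xy <- gen_cv_samples(c(3.22, 3.23), diag(0.1^2, 2), n = 1e5, seed = 1)
  L <- free_energy_2d(xy[, 1], xy[, 2], 0.02, 0.02)
  occ <- !is.na(L$F)
  expect_equal(min(L$F[occ]), 0)
  expect_true(all(L$F[occ] >= 0))
  # global-minimum bin contains the generating centre (within one bin)
  gm <- which(L$F == 0, arr.ind = TRUE)[1, ]
  expect_lt(abs(L$x_centers[gm[1]] - 3.22), 0.02 + 1e-9)
  expect_lt(abs(L$y_centers[gm[2]] - 3.23), 0.02 + 1e-9)

  # quadratic-form recovery on well-sampled bins
  well <- which(L$counts >= 100, arr.ind = TRUE)
  model <- 0.5 * L$kT * ((L$x_centers[well[, 1]] - mean(xy[, 1]))^2 +
                         (L$y_centers[well[, 2]] - mean(xy[, 2]))^2) / 0.1^2
  resid <- L$F[well] - model
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.2 * L$kT)

  # uniform samples: occupied-bin spread bounded by multinomial noise
  set.seed(3)
  u <- matrix(runif(2e4), ncol = 2)
  Lu <- free_energy_2d(u[, 1], u[, 2], 0.1, 0.1)
  n_per_bin <- 1e4 / 100
  expect_lt(max(Lu$F, na.rm = TRUE) - min(Lu$F, na.rm = TRUE),
            2 * 3 * sqrt(1 / n_per_bin) * Lu$kT)

  expect_error(free_energy_2d(1:50, 1:50, 1, 1), "100 samples")
  expect_warning(free_energy_2d(rep(1, 200), rep(1, 200), 1, 1),
                 "degenerate")
})

test_that("minima detection finds the generating basins and only them", {
  # single Gaussian: exactly one minimum, at the centre bin
  xy <- gen_cv_samples(c(3.22, 3.23), diag(0.1^2, 2), n = 1e5, seed = 1)
  L <- free_energy_2d(xy[, 1], xy[, 2], 0.02, 0.02)
  m <- find_minima(L)
  expect_equal(nrow(m), 1)
  expect_lt(abs(m$x_center - 3.22), 0.02 + 1e-9)
  expect_lt(abs(m$y_center - 3.23), 0.02 + 1e-9)

  # balanced well-separated two-Gaussian mixture: exactly two minima
  a <- gen_cv_samples(c(750, 1300), diag(30^2, 2), n = 5e4, seed = 2)
  b <- gen_cv_samples(c(850, 1400), diag(30^2, 2), n = 5e4, seed = 3)
  L2 <- free_energy_2d(c(a[, 1], b[, 1]), c(a[, 2], b[, 2]), 10, 10)
  m2 <- find_minima(L2)
  expect_equal(nrow(m2), 2)
  m2 <- m2[order(m2$x_center), ]
  expect_lt(abs(m2$x_center[1] - 750), 10 + 1e-9)
  expect_lt(abs(m2$y_center[1] - 1300), 10 + 1e-9)
  expect_lt(abs(m2$x_center[2] - 850), 10 + 1e-9)
  expect_lt(abs(m2$y_center[2] - 1400), 10 + 1e-9)

  # an exactly flat landscape has no strict minima
  flat <- free_energy_2d(rep(seq(0.5, 9.5, 1), each = 10),
                         rep(seq(0.5, 9.5, 1), times = 10), 1, 1)
  expect_equal(nrow(find_minima(flat)), 0)
})
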