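## Independent brute-force oracles.  These deliberately avoid the package's
## vectorised code paths: distances are minimised over all 27 periodic
## image translations and energies are accumulated in explicit double
## loops, so agreement is a genuine cross-check.

oracle_min_image <- function(a, b, box) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)) * box
  min(sqrt(rowSums(sweep(shifts, 2, b - a, "+")^2)))
}

oracle_contacts <- function(frame, topo, gA, gB, cutoff) {
  ia <- which(topo$group == gA)
  ib <- which(topo$group == gB)
  hits <- 0L
  for (i in ia) for (j in ib) {
    r <- oracle_min_image(frame$positions[i, ], frame$positions[j, ],
                          frame$box)
    if (r < cutoff) hits <- hits + 1L
  }
  hits
}

oracle_lj_plain <- function(frame, topo, lj_df, gA, gB, r_cut) {
  ia <- which(topo$group == gA)
  ib <- which(topo$group == gB)
  e <- 0
  for (i in ia) for (j in ib) {
    r <- oracle_min_image(frame$positions[i, ], frame$positions[j, ],
                          frame$box)
    if (r >= r_cut) next
    row <- lj_df[(lj_df$type_a == topo$type[i] & lj_df$type_b == topo$type[j]) |
                 (lj_df$type_a == topo$type[j] & lj_df$type_b == topo$type[i]), ]
    sr6 <- (row$sigma_nm[1] / r)^6
    e <- e + 4 * row$epsilon_kjmol[1] * (sr6^2 - sr6)
  }
  e
}

oracle_coulomb_plain <- function(frame, topo, gA, gB, r_cut, eps_r) {
  ia <- which(topo$group == gA)
  ib <- which(topo$group == gB)
  e <- 0
  for (i in ia) for (j in ib) {
    r <- oracle_min_image(frame$positions[i, ], frame$positions[j, ],
                          frame$box)
    if (r >= r_cut) next
    e <- e + 138.935 * topo$charge_e[i] * topo$charge_e[j] / (eps_r * r)
  }
  e
}

## random frame + topology fixture for the pairwise-observable oracles
random_cg_fixture <- function(n_a, n_b, box = 5, spread = 1.5, seed = 1,
                              types = c("SG4", "SP1"), charged = TRUE) {
  set.seed(seed)
  pos <- rbind(
    matrix(stats::rnorm(3 * n_a, box / 3, spread / 3), ncol = 3),
    matrix(stats::rnorm(3 * n_b, 2 * box / 3, spread / 3), ncol = 3)
  )
  frame <- bead_frame(pos, box = box)
  topo <- topology(data.frame(
    bead_index = seq_len(n_a + n_b),
    type = sample(types, n_a + n_b, replace = TRUE),
    charge_e = if (charged) sample(c(-1, 0, 1), n_a + n_b, replace = TRUE)
               else 0,
    group = rep(c("A", "B"), c(n_a, n_b))
  ))
  list(frame = frame, topo = topo)
}

## dense fixture for contact counting: both groups share a small cube that
## straddles the periodic boundary, so many pairs sit below a 0.6 nm cutoff
## and wrapping is exercised
contact_fixture <- function(n_a, n_b, box = 25, side = 2, seed = 1) {
  set.seed(seed)
  pos <- matrix(stats::runif(3 * (n_a + n_b), box - side / 2,
                             box + side / 2), ncol = 3) %% box
  frame <- bead_frame(pos, box = box)
  topo <- topology(data.frame(
    bead_index = seq_len(n_a + n_b),
    type = "P1",
    charge_e = 0,
    group = rep(c("A", "B"), c(n_a, n_b))
  ))
  list(frame = frame, topo = topo)
}

lj_fixture_table <- function() {
  data.frame(type_a = c("SG4", "SG4", "SP1"),
             type_b = c("SG4", "SP1", "SP1"),
             sigma_nm = c(0.47, 0.43, 0.41),
             epsilon_kjmol = c(3.5, 2.7, 2.3))
}

## directly-constructed orientation field (bypasses image analysis) for
## order-parameter unit tests
field_from_theta <- function(theta) {
  structure(list(theta = theta,
                 coherence = ifelse(is.na(theta), 0, 1),
                 block_x = seq_len(ncol(theta)),
                 block_y = seq_len(nrow(theta)),
                 window = 32, overlap = 0.5),
            class = "orientation_field")
}
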