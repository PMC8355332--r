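# File formats round-trip within their precision, and the stage runner
# composes the tested operations deterministically.

test_that("force-curve text files round-trip at full precision", {
  fc <- gen_force_curve(E = 1500, contact_z0 = 80, noise_sd = 0.002,
                        seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_force_curve(fc, path)
  back <- parse_force_curve_file(path)
  expect_equal(back$z, fc$z, tolerance = 1e-9)
  expect_equal(back$force, fc$force, tolerance = 1e-9)

  # hand-written three-line fixture
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", paste(0:19, c(rep(0, 15), 1:5 / 10))), p2)
  expect_length(parse_force_curve_file(p2)$z, 20)

  # comment-only and malformed files fail with the offending line
  p3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# a", "# b"), p3)
  expect_error(parse_force_curve_file(p3), "no data")
  p4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste(1:19, 0), "5 x"), p4)
  expect_error(parse_force_curve_file(p4), "line 20")
  p5 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste(1:19, 0), "1 2 3"), p5)
  expect_error(parse_force_curve_file(p5), "2 columns")
})

test_that("TIFF, track-CSV and ground-truth writers round-trip", {
  img <- gen_filament_image(64, 64, 8, kappa = 2, seed = 4)
  pt <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img, pt)
  back <- read_image_tiff(pt)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - unclass(img))), 1 / 65535 + 1e-9)  # 16-bit

  tr <- gen_tracks(5, 12, 2, seed = 3)
  pc <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, pc)
  tr2 <- read_tracks(pc)
  expect_equal(tr2$x_um, tr$x_um, tolerance = 1e-9)
  expect_equal(cohort_stats(tr2)$mean, cohort_stats(tr)$mean,
               tolerance = 1e-9)

  pg <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(tr, pg)
  gt <- jsonlite::read_json(pg, simplifyVector = TRUE)
  expect_equal(gt$generator_name, "gen_tracks")
  expect_equal(gt$parameters$mean_speed, 12)
})

test_that("GRO files obey the fixed-column contract", {
  # hand-written two-bead fixture
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("two beads",
               "    2",
               "    1GO     SG4    1   1.000   2.000   3.000",
               "    1GO     SP1    2   4.500   5.250   6.125",
               "   25.00000  25.00000  25.00000"), p)
  g <- parse_gro(p)
  expect_equal(g$frame$positions[1, ], c(1, 2, 3))
  expect_equal(g$frame$positions[2, ], c(4.5, 5.25, 6.125))
  expect_equal(g$frame$box, 25)
  expect_equal(g$atom_names, c("SG4", "SP1"))

  # round-trip preserves coordinates to the format's 3 decimals
  fr <- bead_frame(matrix(runif(30, 0, 25), ncol = 3), box = 25)
  p2 <- withr::local_tempfile(fileext = ".gro")
  write_gro(fr, p2)
  back <- parse_gro(p2)
  expect_equal(back$frame$positions, fr$positions, tolerance = 5.1e-4)
  expect_equal(back$frame$box, 25)

  # missing box line
  p3 <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "    1", "    1GO     SG4    1   1.000   2.000   3.000"),
             p3)
  expect_error(parse_gro(p3), "box")
})

test_that("XYZ trajectories round-trip at full precision", {
  tr <- gen_dimer_frames(c(2.5, 3.25), jitter_sd = 0.01, seed = 6)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, p)
  frames <- read_xyz(p)
  expect_length(frames, 2)
  for (k in 1:2) {
    expect_equal(frames[[k]]$positions, tr$frames[[k]]$positions,
                 tolerance = 1e-9)
    expect_equal(frames[[k]]$box, 25)
  }
  pt <- withr::local_tempfile(fileext = ".csv")
  write_topology(tr$topology, pt)
  topo <- read_topology(pt)
  expect_equal(as.data.frame(topo), as.data.frame(tr$topology))
})

test_that("run configurations validate stages and keys", {
  expect_error(run_config("frobnicate"), "unknown stage")
  expect_error(run_config("afm-fit", params = list(bogus = 1)),
               "unknown parameter")
  cfg <- run_config("afm-fit", params = list(gamma = 0.45))
  expect_equal(cfg$params$gamma, 0.45)
  expect_equal(cfg$params$max_depth_nm, 500)   # defaults preserved

  # YAML round trip with flag override
  py <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("stage: go-build",
               "seed: 7",
               "params:",
               "  nx: 5",
               "  ny: 4"), py)
  cfg2 <- read_run_config(py, overrides = list(fraction = 0.5))
  expect_equal(cfg2$stage, "go-build")
  expect_equal(cfg2$params$nx, 5)
  expect_equal(cfg2$params$fraction, 0.5)
  expect_equal(cfg2$seed, 7L)
})

test_that("run_stage composes the tested operations end to end", {
  out1 <- withr::local_tempdir()
  # generate a noiseless curve, then refit it through the stage runner
  sim <- run_stage(run_config("simulate",
                              params = list(generator = "gen_force_curve",
                                            E = 2440, contact_z0 = 100,
                                            noise_sd = 0),
                              outdir = file.path(out1, "sim"), seed = 1))
  curve_file <- file.path(out1, "sim", "gen_force_curve.txt")
  expect_true(file.exists(curve_file))

  rep1 <- run_stage(run_config("afm-fit",
                               inputs = list(control = curve_file),
                               params = list(control = "control"),
                               outdir = file.path(out1, "fit"), seed = 1))
  expect_equal(rep1$result$summary$mean_E_kpa, 2.44, tolerance = 1e-6)
  expect_true(file.exists(file.path(out1, "fit", "report.json")))

  # identical config + seed => identical report
  rep2 <- run_stage(run_config("afm-fit",
                               inputs = list(control = curve_file),
                               params = list(control = "control"),
                               outdir = file.path(out1, "fit2"), seed = 1))
  expect_equal(rep1$result, rep2$result)

  # go-build stage reports the exact SP1 composition
  rep3 <- run_stage(run_config("go-build",
                               params = list(nx = 10, ny = 10),
                               outdir = file.path(out1, "go"), seed = 2))
  expect_equal(rep3$result$n_beads, 200)
  expect_equal(rep3$result$n_sp1, round(0.48 * 200))

  # migration stage computes cohort means and inhibition
  ctrl <- gen_tracks(30, 18.4, 0, seed = 1)
  trt <- gen_tracks(30, 11.2, 0, seed = 2)
  pc <- file.path(out1, "ctrl.csv"); write_tracks(ctrl, pc)
  ptr <- file.path(out1, "trt.csv"); write_tracks(trt, ptr)
  rep4 <- run_stage(run_config("migration-stats",
                               inputs = list(control = pc, treated = ptr),
                               outdir = file.path(out1, "mig"), seed = 1))
  expect_equal(rep4$result$control$mean, 18.4, tolerance = 1e-9)
  expect_equal(rep4$result$inhibition_percent,
               100 * (18.4 - 11.2) / 18.4, tolerance = 1e-9)
})
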