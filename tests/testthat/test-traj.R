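test_that("trajectories validate their invariants", {
  coords <- array(0, dim = c(3, 4, 3))
  atoms <- data.frame(element = c("C", "C", "C", "O"))
  expect_s3_class(trajectory(coords, 0:2, atoms), "trajectory")
  expect_error(trajectory(coords, c(0, 0, 1), atoms), "strictly increasing")
  coords[2, 1, 1] <- NA
  expect_error(trajectory(coords, 0:2, atoms), "finite")
})

test_that("RMSD is zero for exact and rigidly transformed copies", {
  withr::local_seed(71)
  ref <- matrix(rnorm(30), 10, 3)
  n_frames <- 5
  coords <- array(0, dim = c(n_frames, 10, 3))
  coords[1, , ] <- ref
  for (f in 2:n_frames) {
    R <- random_rotation()
    coords[f, , ] <- sweep(ref %*% R, 2, runif(3, -10, 10), `+`)
  }
  tj <- trajectory(coords, seq_len(n_frames) - 1,
                   data.frame(element = rep("C", 10)),
                   selections = list(ligand = 8:10, calpha = 1:7))
  rs <- rmsd_series(tj)
  expect_lt(max(rs$rmsd), 1e-9)
  rs_all <- rmsd_series(tj, measure_selection = 1:10,
                        superpose_selection = 1:10)
  expect_lt(max(rs_all$rmsd), 1e-9)
})

test_that("a locked alignment reports the displaced atom's distance", {
  # superposition atoms identical across frames; one measured atom moved 2 A
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(1, 1, 1))
  moved <- ref; moved[4, ] <- moved[4, ] + c(0, 0, 2)
  coords <- array(0, dim = c(2, 4, 3))
  coords[1, , ] <- ref; coords[2, , ] <- moved
  tj <- trajectory(coords, 0:1, data.frame(element = rep("C", 4)))
  rs <- rmsd_series(tj, measure_selection = 4, superpose_selection = 1:3)
  expect_equal(rs$rmsd[2], 2, tolerance = 1e-9)
})

test_that("RMSD matches the quaternion superposition oracle on random toys", {
  withr::local_seed(72)
  for (k in 1:12) {
    ref <- matrix(rnorm(30, sd = 3), 10, 3)
    frame <- ref + matrix(rnorm(30, sd = 0.8), 10, 3)
    R <- random_rotation()
    frame <- sweep(frame %*% R, 2, runif(3, -5, 5), `+`)
    coords <- array(0, dim = c(2, 10, 3))
    coords[1, , ] <- ref; coords[2, , ] <- frame
    tj <- trajectory(coords, 0:1, data.frame(element = rep("C", 10)))
    fit_idx <- 1:6; measure_idx <- 7:10
    rs <- rmsd_series(tj, measure_selection = measure_idx,
                      superpose_selection = fit_idx)
    want <- oracle_superpose_rmsd(ref, frame, fit_idx, measure_idx)$rmsd
    expect_equal(rs$rmsd[2], want, tolerance = 1e-9)
  }
})

test_that("superposition never increases the fitted-selection RMSD", {
  withr::local_seed(73)
  for (k in 1:6) {
    ref <- matrix(rnorm(24, sd = 2), 8, 3)
    frame <- sweep((ref + matrix(rnorm(24, sd = 0.5), 8, 3)) %*%
                     random_rotation(), 2, runif(3, -3, 3), `+`)
    coords <- array(0, dim = c(2, 8, 3))
    coords[1, , ] <- ref; coords[2, , ] <- frame
    tj <- trajectory(coords, 0:1, data.frame(element = rep("C", 8)))
    fitted <- rmsd_series(tj, measure_selection = 1:8,
                          superpose_selection = 1:8)$rmsd[2]
    raw <- sqrt(mean(rowSums((frame - ref)^2)))
    expect_lte(fitted, raw + 1e-12)
  }
})

test_that("hydrogen bonds follow the distance-and-angle criterion", {
  # linear D-H...A at D..A 2.8 A -> one bond
  mk <- function(apos) {
    coords <- array(0, dim = c(1, 3, 3))
    coords[1, 1, ] <- c(0, 0, 0)      # donor
    coords[1, 2, ] <- c(1, 0, 0)      # hydrogen
    coords[1, 3, ] <- apos            # acceptor
    trajectory(coords, 0, data.frame(element = c("N", "H", "O")),
               selections = list(donors = data.frame(d = 1, h = 2),
                                 acceptors = 3))
  }
  expect_equal(hbond_series(mk(c(2.8, 0, 0)))$count, 1)
  expect_equal(hbond_series(mk(c(4.5, 0, 0)))$count, 0)   # too far
  expect_equal(hbond_series(mk(c(-2.8, 0, 0)))$count, 0)  # wrong side: 0 deg
  # D-H...A angle just above the 130-degree limit counts, just below not;
  # the acceptor at direction phi from H gives an angle of 180 - phi
  at_angle <- function(theta) {
    phi <- (180 - theta) * pi / 180
    c(1, 0, 0) + 2 * c(cos(phi), sin(phi), 0)
  }
  expect_equal(hbond_series(mk(at_angle(130.5)))$count, 1)
  expect_equal(hbond_series(mk(at_angle(129.5)))$count, 0)
})

test_that("hydrogen-bond counts match triple enumeration on random frames", {
  withr::local_seed(74)
  for (k in 1:8) {
    n <- 20
    xyz <- matrix(runif(n * 3, 0, 8), n, 3)
    coords <- array(0, dim = c(1, n, 3))
    coords[1, , ] <- xyz
    donors <- data.frame(d = c(1, 4, 7), h = c(2, 5, 8))
    acceptors <- c(10, 12, 14, 16)
    tj <- trajectory(coords, 0, data.frame(element = rep("C", n)),
                     selections = list(donors = donors,
                                       acceptors = acceptors))
    crit <- hbond_criteria(d_max = 4.5, angle_min = 100)
    expect_identical(hbond_series(tj, crit)$count[1],
                     oracle_hbond_count(xyz, donors, acceptors, 4.5, 100))
  }
})

test_that("hydrogen-bond counts are invariant under rigid motion", {
  withr::local_seed(75)
  xyz <- matrix(runif(30, 0, 6), 10, 3)
  R <- random_rotation()
  moved <- sweep(xyz %*% R, 2, c(5, -3, 2), `+`)
  sel <- list(donors = data.frame(d = 1, h = 2), acceptors = c(5, 7, 9))
  count_of <- function(m) {
    coords <- array(0, dim = c(1, 10, 3)); coords[1, , ] <- m
    hbond_series(trajectory(coords, 0, data.frame(element = rep("C", 10)),
                            selections = sel),
                 hbond_criteria(4.0, 110))$count[1]
  }
  expect_identical(count_of(xyz), count_of(moved))
})

test_that("FES reconstruction matches the closed form for single hills", {
  h <- hills_log(data.frame(time = 1, center = 1.0, sigma = 0.1,
                            height = 2.0))
  fes <- reconstruct_fes(h, grid = seq(0, 2, length.out = 2001))
  i <- which.min(fes$grid$free_energy)
  expect_equal(fes$grid$s[i], 1.0, tolerance = 1e-3)
  expect_equal(min(fes$grid$free_energy), -2.0, tolerance = 1e-9)
  shifted <- reconstruct_fes(h, grid = seq(0, 2, length.out = 2001),
                             zero_min = TRUE)
  expect_equal(min(shifted$grid$free_energy), 0)
})

test_that("two equal hills give a symmetric surface", {
  h <- hills_log(data.frame(time = 1:2, center = c(-1, 1), sigma = 0.2,
                            height = 1.5))
  grid <- seq(-2, 2, length.out = 401)
  f <- reconstruct_fes(h, grid = grid)$grid$free_energy
  expect_equal(f, rev(f), tolerance = 1e-12)
})

test_that("FES reconstruction is linear in the hills", {
  a <- generate_hills(40, seed = 1)$entries
  b <- generate_hills(40, seed = 2)$entries
  grid <- seq(-3, 3, length.out = 301)
  fa <- reconstruct_fes(hills_log(a), grid = grid)$grid$free_energy
  fb <- reconstruct_fes(hills_log(b), grid = grid)$grid$free_energy
  fab <- reconstruct_fes(hills_log(rbind(a, b)),
                         grid = grid)$grid$free_energy
  expect_equal(fab, fa + fb, tolerance = 1e-12)
})

test_that("HILLS files parse and surfaces write as two-column text", {
  tf <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# time center sigma height", "1 0.5 0.1 1.2",
               "2 0.8 0.15 0.9", "", "3 -0.2 0.1 1.0"), tf)
  h <- read_hills(tf)
  expect_equal(nrow(h$entries), 3)
  expect_equal(h$entries$center, c(0.5, 0.8, -0.2))
  fes <- reconstruct_fes(h, n_points = 64)
  out <- withr::local_tempfile(fileext = ".dat")
  write_fes(fes, out)
  back <- read.table(out)
  expect_equal(nrow(back), 64)
  expect_equal(back[[2]], fes$grid$free_energy, tolerance = 1e-12)
  expect_error(hills_log(data.frame(time = 1, center = 0, sigma = 0,
                                    height = 1)), "positive")
})

test_that("stability ranking orders candidates by mean RMSD", {
  series <- list(noisy = c(2, 3, 2.5), flat = c(0, 0, 0),
                 mid = c(1, 1.2, 0.8))
  expect_equal(stability_rank(series, 1), "flat")
  expect_equal(stability_rank(series, 3), c("flat", "mid", "noisy"))
  expect_error(stability_rank(series, 4), "exceeds")
  stable <- rmsd_series(generate_trajectory("stable", n_frames = 30,
                                            seed = 5))
  drifting <- rmsd_series(generate_trajectory("drifting", n_frames = 30,
                                              seed = 5))
  expect_equal(stability_rank(list(s = stable, d = drifting), 1), "s")
})

test_that("XYZ trajectories read back frame by frame", {
  traj <- generate_trajectory("stable", n_frames = 4, seed = 6)
  tf <- withr::local_tempfile(fileext = ".xyz")
  con <- file(tf, "w")
  n_atoms <- dim(traj$coords)[2]
  for (f in 1:4) {
    writeLines(c(as.character(n_atoms),
                 sprintf("frame %d time=%g", f, traj$times[f])), con)
    xyz <- traj$coords[f, , ]
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$atoms$element, xyz[, 1],
                       xyz[, 2], xyz[, 3]), con)
  }
  close(con)
  back <- read_trajectory_xyz(tf)
  expect_equal(dim(back$coords), dim(traj$coords))
  expect_equal(back$times, traj$times)
  expect_equal(back$coords, traj$coords, tolerance = 1e-5)
  expect_equal(back$atoms$element, traj$atoms$element)
})

test_that("multi-model PDB trajectories read through bio3d", {
  traj <- generate_trajectory("stable", n_frames = 3, seed = 7)
  tf <- withr::local_tempfile(fileext = ".pdb")
  con <- file(tf, "w")
  for (f in 1:3) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- traj$coords[f, , ]
    writeLines(sprintf(
      "ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(xyz)), substr(traj$atoms$name, 1, 3), "TOY",
      traj$atoms$resno, xyz[, 1], xyz[, 2], xyz[, 3],
      traj$atoms$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  back <- read_trajectory_pdb(tf, dt = 2)
  expect_equal(dim(back$coords), dim(traj$coords))
  expect_equal(back$times, c(0, 2, 4))
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
})
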