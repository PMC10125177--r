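# Analysis estimators: Rg, SASA, component-core distance, RDF, summaries.

test_that("radius of gyration reproduces closed forms", {
  pt <- cluster_model(data.frame(element = "C", x = 5, y = -1, z = 2,
                                 molecule_id = 1L, component = "OL"))
  expect_equal(radius_of_gyration(pt), 0, tolerance = 1e-12)
  # two equal masses 2 nm apart -> d/2 = 1 nm
  two <- cluster_model(data.frame(element = c("C", "C"), x = c(0, 20),
                                  y = 0, z = 0, molecule_id = 1:2,
                                  component = "OL"))
  expect_equal(radius_of_gyration(two), 1)
  expect_equal(radius_of_gyration(two, weights = "uniform"), 1)
  # unequal masses: analytic weighted formula
  au_h <- cluster_model(data.frame(element = c("Au", "H"), x = c(0, 10),
                                   y = 0, z = 0, molecule_id = 1:2,
                                   component = "OL"))
  mAu <- element_property("Au", "mass")
  mH <- element_property("H", "mass")
  mu <- mH * 10 / (mAu + mH)
  expected <- sqrt((mAu * mu^2 + mH * (10 - mu)^2) / (mAu + mH)) / 10
  expect_equal(radius_of_gyration(au_h), expected)
  expect_error(radius_of_gyration(two, selection = integer(0)), "empty")
})

test_that("Rg is invariant under rigid motions", {
  toy <- make_toy_cluster(3, seed = 1)
  r0 <- radius_of_gyration(toy)
  set.seed(21)
  for (k in 1:5) {
    R <- aushell:::random_rotation()
    xyz <- aushell:::model_xyz(toy) %*% t(R) + 7
    m2 <- toy
    m2$atoms$x <- xyz[, 1]; m2$atoms$y <- xyz[, 2]; m2$atoms$z <- xyz[, 3]
    expect_equal(radius_of_gyration(m2), r0, tolerance = 1e-9)
  }
})

test_that("SASA matches the isolated-sphere closed form within 1%", {
  m <- cluster_model(data.frame(element = "C", x = 0, y = 0, z = 0,
                                molecule_id = 1L, component = "OL"))
  s <- sasa_by_component(m)
  exact <- 4 * pi * (0.170 + 0.140)^2
  expect_equal(s$total, exact, tolerance = 0.01)
  # convergence: doubling the point count moves the result by < 0.5%
  s2 <- sasa_by_component(m, config = analysis_config(n_sphere_points = 1920))
  expect_lt(abs(s2$total - s$total) / s$total, 0.005)
  expect_no_error(sasa_by_component(
    m, config = analysis_config(radii_table = c(N = 0.15))))
})

test_that("two overlapping spheres match the analytic cap formula", {
  for (d in c(1.0, 2.0, 3.0)) {
    m <- cluster_model(data.frame(element = c("C", "C"), x = c(0, d),
                                  y = 0, z = 0, molecule_id = 1:2,
                                  component = "OL"))
    s <- sasa_by_component(m)
    R <- 3.1  # (0.17 + 0.14) nm in Angstrom
    exact <- (4 * pi * R^2 + 2 * pi * R * d) / 100
    expect_equal(s$total, exact, tolerance = 0.01)
  }
})

test_that("SASA is additive over components and separated molecules", {
  toy <- make_toy_cluster(2, seed = 1)
  s <- sasa_by_component(toy)
  expect_equal(sum(s$components), s$total, tolerance = 1e-12)
  # two copies far apart have the sum of isolated areas
  a <- toy$atoms
  b <- a
  b$x <- b$x + 100
  b$molecule_id <- b$molecule_id + max(a$molecule_id)
  both <- cluster_model(rbind(a, b))
  expect_equal(sasa_by_component(both)$total, 2 * s$total,
               tolerance = 1e-6)
})

test_that("missing vdW radius for an element is reported by name", {
  m <- cluster_model(data.frame(element = "C", x = 0, y = 0, z = 0,
                                molecule_id = 1L, component = "OL"))
  m$atoms$element <- "Xq"  # bypass constructor validation on purpose
  expect_error(sasa_by_component(m), "Xq")
})

test_that("component-core distance recovers constructed geometry", {
  # one gold core atom at origin, one 'ligand' copy fixed 2.00 nm away
  atoms <- data.frame(element = c("Au", "C"), x = c(0, 20), y = 0, z = 0,
                      molecule_id = 1:2, component = c("GOLD_CORE", "PL"))
  frames <- lapply(1:10, function(f) rbind(c(0, 0, 0), c(20, 0, 0)))
  traj <- trajectory(atoms, frames, times = seq(0, 90, by = 10))
  d <- component_core_distance(traj, "PL",
                               config = analysis_config(
                                 equilibration_cutoff = 30))
  expect_equal(d$mean, 2.00, tolerance = 1e-12)
  expect_equal(d$sd, 0)
  expect_equal(d$frames_used, 7)
  # coincident centers of mass give exactly zero
  atoms0 <- data.frame(element = c("Au", "C"), x = 0, y = 0, z = 0,
                       molecule_id = 1:2, component = c("GOLD_CORE", "PL"))
  traj0 <- trajectory(atoms0, lapply(1:3, function(f) matrix(0, 2, 3)),
                      times = c(30, 40, 50))
  d0 <- component_core_distance(traj0, "PL")
  expect_equal(d0$mean, 0)
  expect_equal(d0$sd, 0)
})

test_that("time series summary slices at the cutoff", {
  s <- time_series_summary(c(1, 2, 3), c(31, 32, 33), 30)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(time_series_summary(rep(5, 4), 1:4, 0)$sd, 0)
  # transient ramp excluded: equals recomputation on the suffix
  v <- c(10, 8, 6, 1.1, 0.9, 1.0)
  t <- c(0, 10, 20, 30, 40, 50)
  s2 <- time_series_summary(v, t, 30)
  expect_equal(s2$mean, mean(v[4:6]))
  expect_equal(s2$sd, sd(v[4:6]))
  expect_error(time_series_summary(1:3, 1:3, 99), "no samples")
})

test_that("RDF of an ideal gas is flat at one", {
  gas <- make_toy_trajectory("ideal_gas", dir = tempdir(), seed = 8,
                             n_frames = 20)
  traj <- gas$trajectory
  cfg <- analysis_config(equilibration_cutoff = 0, rdf_bin = 0.02)
  r <- rdf(traj, 1:150, 151:300, cfg)
  sel <- r$bin_centers > 0.4  # skip sparsely populated small-r bins
  expect_lt(abs(mean(r$g[sel]) - 1), 0.02)
  expect_true(all(r$g >= 0))
  # total pair count equals direct counting within rmax
  count <- 0
  rmax <- max(r$bin_centers) + 0.01
  box <- traj$box
  for (f in seq_along(traj$frames)) {
    xyz <- traj$frames[[f]]
    dx <- outer(xyz[1:150, 1], xyz[151:300, 1], "-")
    dy <- outer(xyz[1:150, 2], xyz[151:300, 2], "-")
    dz <- outer(xyz[1:150, 3], xyz[151:300, 3], "-")
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
    count <- count + sum(sqrt(dx^2 + dy^2 + dz^2) < rmax * 10)
  }
  expect_equal(r$n_pairs, count)
})

test_that("RDF recovers a constructed shell peak at 0.27 nm", {
  sh <- make_toy_trajectory("ion_shell", dir = tempdir(), seed = 6)
  traj <- sh$trajectory
  cfg <- analysis_config(equilibration_cutoff = 0, rdf_rmax = 1.5)
  r <- rdf(traj, which(traj$atoms$element == "S"),
           which(traj$atoms$element == "Na"), cfg)
  mode_bin <- r$bin_centers[which.max(r$g)]
  expect_lt(abs(mode_bin - 0.27), 0.002)  # the mode bin contains 0.27 nm
})

test_that("RDF validates groups and box geometry", {
  gas <- make_toy_trajectory("ideal_gas", dir = tempdir(), seed = 2,
                             n_frames = 2)
  cfg0 <- analysis_config(equilibration_cutoff = 0)
  expect_error(rdf(gas$trajectory, 1:10, 5:20, cfg0), "disjoint")
  expect_error(rdf(gas$trajectory, 1:10, 11:20,
                   analysis_config(equilibration_cutoff = 0,
                                   rdf_rmax = 3.9)),
               "half the smallest box edge")
  expect_error(rdf(gas$trajectory, 1:10, 11:20,
                   analysis_config(equilibration_cutoff = 99)),
               "no frames")
})

test_that("trajectory files round trip through multi-model PDB", {
  rt <- make_toy_trajectory("rigid_translation", dir = tempdir(), seed = 12)
  back <- read_trajectory(rt$pdb)
  expect_length(back$frames, length(rt$trajectory$frames))
  expect_lt(max(abs(back$frames[[3]] - rt$trajectory$frames[[3]])), 1e-2)
  rg <- radius_of_gyration(back)
  expect_lt(diff(range(rg)), 1e-4)  # limited by PDB 3-decimal precision
  expect_equal(mean(rg), rt$truth$rg_mass_nm, tolerance = 1e-3)
})

test_that("concatenated XYZ trajectories parse with times and box", {
  toy <- make_toy_cluster(2, seed = 3)
  path <- tempfile(fileext = ".xyz")
  lines <- character(0)
  for (f in 1:3) {
    m <- toy
    m$atoms$x <- m$atoms$x + f
    m$box <- c(40, 40, 40)
    tmp <- tempfile(fileext = ".xyz")
    write_structure(m, tmp)
    fl <- readLines(tmp)
    fl[2] <- paste(fl[2], sprintf("time=%g", f * 0.5))
    lines <- c(lines, fl)
  }
  writeLines(lines, path)
  traj <- read_trajectory(path)
  expect_length(traj$frames, 3)
  expect_equal(traj$times, c(0.5, 1.0, 1.5))
  expect_equal(traj$box, c(40, 40, 40))
  expect_equal(traj$frames[[2]][, 1] - traj$frames[[1]][, 1],
               rep(1, nrow(toy$atoms)), tolerance = 1e-9)
})
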