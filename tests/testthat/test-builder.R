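# Site selection, placement sampling, full builds, distances, enumeration.

test_that("site selection is uniform, seeded and one-ligand-per-unit", {
  toy <- make_toy_cluster(6, seed = 1)
  s1 <- select_exchange_sites(toy, 4, seed = 5)
  s2 <- select_exchange_sites(toy, 4, seed = 5)
  expect_identical(s1, s2)
  expect_length(unique(vapply(s1, `[[`, integer(1), "unit")), 4)
  expect_length(select_exchange_sites(toy, 0), 0)
  expect_error(select_exchange_sites(toy, 7), "exceeds the number")
  # chi-square uniformity of unit choice over many seeded draws
  counts <- integer(6)
  lig_counts <- integer(2)
  for (s in 1:2000) {
    sel <- select_exchange_sites(toy, 1, seed = s)
    counts[sel[[1]]$unit] <- counts[sel[[1]]$unit] + 1L
    lig_counts[sel[[1]]$ligand_choice] <-
      lig_counts[sel[[1]]$ligand_choice] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 1e-4)
  expect_gt(chisq.test(lig_counts)$p.value, 1e-4)
})

test_that("an unobstructed dummy template is accepted at the first trial", {
  toy <- make_toy_cluster(1, seed = 2)
  site <- select_exchange_sites(toy, 1, seed = 1)[[1]]
  # single-sulfur dummy: coincides with the original sulfur position, and a
  # far-out axis carbon to define the rotation axes
  dummy <- ligand_template(
    data.frame(element = c("S", "C"), x = 0, y = 0, z = c(0, 30)),
    bonds = rbind(c(1, 2)), anchor_sulfur = 1, axis_carbon = 2,
    name = "probe")
  tr <- attempt_placement(toy, site, dummy, builder_config(n_exchange = 1))
  expect_true(tr$success)
  expect_equal(tr$trials, 1L)
  expect_equal(unname(tr$accepted_angles), c(0, 0))
})

test_that("placement equals exhaustive enumeration on reference sites", {
  ref <- ref_cluster()
  conj <- default_conjugates()
  cfg <- builder_config(seed = 3)
  sites <- select_exchange_sites(ref, 3, seed = 3)
  for (k in 1:3) {
    fast <- attempt_placement(ref, sites[[k]], conj$peptide, cfg)
    slow <- brute_force_placement(ref, sites[[k]], conj$peptide, cfg)
    expect_identical(fast$success, slow$success)
    expect_identical(unname(fast$accepted_angles), slow$angles)
    expect_identical(fast$trials, slow$trials)
  }
})

test_that("placement equals enumeration on a walled single-survivor site", {
  # obstruct a toy site with a shell of atoms pierced by one opening, so
  # only a narrow angular window survives; the analytic search must find
  # exactly the same first surviving grid orientation as the literal loops
  toy <- make_toy_cluster(1, seed = 3)
  site <- select_exchange_sites(toy, 1, seed = 1)[[1]]
  atoms <- toy$atoms
  s_idx <- site$staple$sulfurs[site$ligand_choice]
  s_pos <- as.numeric(atoms[s_idx, c("x", "y", "z")])
  axis_dir <- aushell:::site_axis_direction(atoms, s_idx)
  # ring of blockers around the axis at the probe tip radius, one gap
  perp <- aushell:::unit(aushell:::cross3(axis_dir, c(0, 0, 1)))
  perp2 <- aushell:::cross3(axis_dir, perp)
  wall <- NULL
  for (ang in seq(0, 330, by = 30)) {
    if (ang %in% c(120, 150)) next  # the opening
    dir <- cos(ang * pi / 180) * perp + sin(ang * pi / 180) * perp2
    wall <- rbind(wall, s_pos + 6 * axis_dir + 2.5 * dir)
  }
  blocked <- cluster_model(rbind(
    atoms,
    data.frame(element = "C", x = wall[, 1], y = wall[, 2], z = wall[, 3],
               molecule_id = max(atoms$molecule_id) + 1L,
               component = "OL")))
  blocked$staples <- detect_protective_units(blocked)
  site2 <- list(unit = site$unit, staple = blocked$staples[[site$unit]],
                ligand_choice = site$ligand_choice)
  probe <- ligand_template(
    data.frame(element = c("S", "C", "C"),
               x = c(0, 0, 1.4), y = 0, z = c(0, 3, 6)),
    bonds = rbind(c(1, 2), c(2, 3)), anchor_sulfur = 1, axis_carbon = 2,
    name = "bent-probe")
  cfg <- builder_config(n_exchange = 1)
  fast <- attempt_placement(blocked, site2, probe, cfg)
  slow <- brute_force_placement(blocked, site2, probe, cfg)
  expect_identical(fast$success, slow$success)
  if (fast$success) {
    expect_identical(unname(fast$accepted_angles), slow$angles)
    expect_identical(fast$trials, slow$trials)
  }
  expect_lte(fast$trials, 36 * 100)
})

test_that("raising d_min never enlarges the acceptable orientation set", {
  toy <- make_toy_cluster(3, seed = 5)
  site <- select_exchange_sites(toy, 1, seed = 2)[[1]]
  conj <- default_conjugates()
  count_acceptable <- function(d_min) {
    staple <- site$staple
    s_idx <- staple$sulfurs[site$ligand_choice]
    s_pos <- as.numeric(toy$atoms[s_idx, c("x", "y", "z")])
    apex <- as.numeric(toy$atoms[staple$apex_gold, c("x", "y", "z")])
    axis_dir <- aushell:::site_axis_direction(toy$atoms, s_idx)
    base <- aushell:::instantiate_ligand(conj$drug, s_pos, axis_dir)
    bxyz <- cbind(base$x, base$y, base$z)
    keep <- toy$atoms$molecule_id != toy$atoms$molecule_id[s_idx]
    env <- aushell:::model_xyz(toy)[keep, , drop = FALSE]
    acc <- 0L
    for (a_sau in seq(0, 300, by = 60)) {
      x1 <- aushell:::rotate_about(bxyz, s_pos, s_pos - apex, a_sau)
      cs_axis <- x1[conj$drug$axis_carbon, ] - s_pos
      for (a_cs in seq(0, 324, by = 36)) {
        x2 <- aushell:::rotate_about(x1, s_pos, cs_axis, a_cs)
        if (aushell:::min_cross_distance(x2, env) >= d_min) acc <- acc + 1L
      }
    }
    acc
  }
  counts <- vapply(c(1.0, 1.75, 2.5), count_acceptable, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("default build yields 45 original plus 15 incoming ligands", {
  ref <- ref_cluster()
  conj <- default_conjugates()
  form <- formulation_spec("QS13", "TOR", c(2, 1), 15)
  res <- build_functionalized_cluster(ref, form, conj$peptide, conj$drug,
                                      builder_config(seed = 1))
  mols <- res$model$atoms[!duplicated(res$model$atoms$molecule_id), ]
  expect_equal(sum(mols$component == "OL"), 45)
  expect_equal(sum(mols$component == "PL"), 10)
  expect_equal(sum(mols$component == "DL"), 5)
  # gold conserved, one replacement per staple
  expect_equal(sum(res$model$atoms$element == "Au"), 144)
  au0 <- aushell:::model_xyz(ref)[ref$atoms$element == "Au", ]
  au1 <- aushell:::model_xyz(res$model)[res$model$atoms$element == "Au", ]
  expect_equal(au0[order(au0[, 1], au0[, 2], au0[, 3]), ],
               au1[order(au1[, 1], au1[, 2], au1[, 3]), ])
  repl <- vapply(res$model$staples, function(u) sum(u$replaced), integer(1))
  expect_true(all(repl <= 1))
  expect_equal(sum(repl), 15)
  # acceptance soundness re-verified post hoc
  expect_gte(min_external_distance(res$model), 1.75)
  for (tr in res$traces) expect_lte(tr$trials, 3600)
})

test_that("builds are deterministic and zero exchange is the identity", {
  ref <- ref_cluster()
  conj <- default_conjugates()
  form <- formulation_spec("QS13", "TOR", c(2, 1), 15)
  r1 <- build_functionalized_cluster(ref, form, conj$peptide, conj$drug,
                                     builder_config(seed = 2))
  r2 <- build_functionalized_cluster(ref, form, conj$peptide, conj$drug,
                                     builder_config(seed = 2))
  expect_identical(r1$model$atoms, r2$model$atoms)
  f0 <- formulation_spec("QS13", "TOR", c(2, 1), 0)
  r0 <- build_functionalized_cluster(ref, f0, conj$peptide, conj$drug,
                                     builder_config(n_exchange = 0))
  expect_identical(r0$model$atoms, ref$atoms)
})

test_that("min_external_distance matches a plain double loop", {
  # two single-atom molecules 3 A apart
  m <- cluster_model(data.frame(
    element = c("C", "C"), x = c(0, 3), y = 0, z = 0,
    molecule_id = 1:2, component = c("PL", "OL")))
  expect_equal(min_external_distance(m, "PL"), 3.0)
  # toy decorated cluster, relabelled so some ligands count as incoming
  toy <- make_toy_cluster(6, seed = 2)
  toy$atoms$component[toy$atoms$molecule_id %in% c(3L, 8L)] <- "PL"
  brute <- min_external_distance(toy, "PL", method = "brute")
  cells <- min_external_distance(toy, "PL", method = "cells")
  expect_equal(brute, cells, tolerance = 1e-12)
  # independent slow loop
  xyz <- aushell:::model_xyz(toy)
  ins <- toy$atoms$molecule_id == 3L
  d3 <- slow_min_cross(xyz[ins, , drop = FALSE], xyz[!ins, , drop = FALSE])
  ins8 <- toy$atoms$molecule_id == 8L
  d8 <- slow_min_cross(xyz[ins8, , drop = FALSE],
                       xyz[!ins8, , drop = FALSE])
  expect_equal(brute, min(d3, d8), tolerance = 1e-12)
  expect_error(min_external_distance(toy, "DL"), "no molecules")
})

test_that("formulation enumeration reproduces the 28-system design", {
  specs <- enumerate_formulations()
  expect_length(specs, 28)
  keys <- vapply(specs, function(s) {
    paste(s$peptide, s$drug, paste(s$ratio, collapse = ":"))
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(keys, sort(keys) [order(order(keys))])  # deterministic
  # ratio arithmetic at n_exchange = 15
  s12 <- formulation_spec("QS13", "5FU", c(1, 2), 15)
  expect_equal(s12$n_peptide, 5)
  expect_equal(s12$n_drug, 10)
  s21 <- formulation_spec("QS13", "5FU", c(2, 1), 15)
  expect_equal(s21$n_peptide, 10)
  expect_equal(s21$n_drug, 5)
  expect_length(enumerate_formulations("A", "B", list(c(1, 2)), 15), 1)
  expect_error(formulation_spec("A", "B", c(1, 1), 15), "whole counts")
})

test_that("builder_config validates its constants", {
  expect_error(builder_config(step_cs = 7), "divide 360")
  expect_error(builder_config(d_min = 0), "positive")
  cfg <- builder_config()
  expect_equal(cfg$n_exchange, 15L)
  expect_equal(cfg$step_cs, 3.6)
  expect_equal(cfg$step_sau, 10)
  expect_equal(cfg$d_min, 1.75)
})
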