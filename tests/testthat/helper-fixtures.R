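# Shared fixtures, built once per test run.

# the default reference cluster is deterministic and moderately expensive;
# generate it once and reuse
ref_cluster <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_reference_cluster()
    cache
  }
})

# elongated default conjugates (long linker + peptide, short linker + drug)
default_conjugates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        peptide = elongate_conformer(
          conjugate_payload(make_peg_linker(6, 11),
                            synthetic_peptide_payload())),
        drug = elongate_conformer(
          conjugate_payload(make_peg_linker(3, 11),
                            synthetic_drug_payload())))
    }
    cache
  }
})

write_water_xyz <- function(path) {
  writeLines(c("3", "water", "O 0.000 0.000 0.000",
               "H 0.957 0.000 0.000", "H -0.240 0.927 0.000"), path)
  path
}

# minimum distance between two coordinate sets by plain double loop
slow_min_cross <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# reference placement search: literal nested loops over the angular grid in
# the documented order, first clash-free orientation wins
brute_force_placement <- function(model, site, template, config) {
  staple <- site$staple
  choice <- site$ligand_choice
  atoms <- model$atoms
  s_idx <- staple$sulfurs[choice]
  s_pos <- as.numeric(atoms[s_idx, c("x", "y", "z")])
  apex <- as.numeric(atoms[staple$apex_gold, c("x", "y", "z")])
  axis_dir <- aushell:::site_axis_direction(atoms, s_idx)
  other_s <- staple$sulfurs[3 - choice]
  tangent <- as.numeric(atoms[other_s, c("x", "y", "z")]) - s_pos
  base <- aushell:::instantiate_ligand(
    template, s_pos, axis_dir,
    ref_tangent = if (sqrt(sum(tangent^2)) > 1e-8)
      tangent / sqrt(sum(tangent^2)) else NULL)
  bxyz <- cbind(base$x, base$y, base$z)
  keep <- atoms$molecule_id != atoms$molecule_id[s_idx]
  env <- aushell:::model_xyz(model)[keep, , drop = FALSE]
  sau_axis <- s_pos - apex
  trials <- 0L
  for (a_sau in seq(0, 360 - config$step_sau, by = config$step_sau)) {
    x1 <- aushell:::rotate_about(bxyz, s_pos, sau_axis, a_sau)
    cs_axis <- x1[template$axis_carbon, ] - s_pos
    for (a_cs in seq(0, 360 - config$step_cs, by = config$step_cs)) {
      trials <- trials + 1L
      x2 <- aushell:::rotate_about(x1, s_pos, cs_axis, a_cs)
      if (aushell:::min_cross_distance(x2, env) >= config$d_min) {
        return(list(success = TRUE, angles = c(a_sau, a_cs),
                    trials = trials))
      }
    }
  }
  list(success = FALSE, trials = trials)
}
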