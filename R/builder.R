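# Ligand-exchange model construction: random site selection (one ligand per
# RS-Au-SR unit), placement of incoming conjugates by nested rotational
# sampling around the S-Au and S-C bonds with a hard minimum-distance clash
# criterion, full-restart semantics, and formulation enumeration.

#' Builder configuration
#'
#' All algorithm constants of the ligand-exchange construction. Defaults are
#' the study conditions: 15 exchanged ligands, 3.6 degree steps around the
#' S-C bond, 10 degree steps around the S-Au bond, and a 1.75 Angstrom
#' minimum-distance criterion applied between every atom of an incoming
#' ligand and all atoms outside it.
#'
#' @param n_exchange number of ligands to exchange (default 15).
#' @param ratio integer peptide:drug pair, `c(1, 2)` or `c(2, 1)`.
#' @param step_cs rotational step around the S-C bond, degrees (default 3.6).
#' @param step_sau rotational step around the S-Au bond, degrees (default 10).
#' @param d_min clash criterion in Angstrom (default 1.75).
#' @param seed RNG seed for site selection (default 1).
#' @param max_restarts maximum full-build restarts on placement failure
#'   (default 100).
#' @return an object of class `builder_config`.
#' @export
builder_config <- function(n_exchange = 15, ratio = c(2, 1), step_cs = 3.6,
                           step_sau = 10, d_min = 1.75, seed = 1,
                           max_restarts = 100) {
  for (s in c(step_cs, step_sau)) {
    if (s <= 0 || abs(360 / s - round(360 / s)) > 1e-6) {
      stop("angle step ", s, " does not divide 360 degrees")
    }
  }
  if (d_min <= 0) stop("d_min must be positive")
  stopifnot(n_exchange >= 0, length(ratio) == 2, all(ratio > 0),
            max_restarts >= 1)
  structure(list(n_exchange = as.integer(n_exchange),
                 ratio = as.integer(ratio),
                 step_cs = step_cs, step_sau = step_sau, d_min = d_min,
                 seed = as.integer(seed),
                 max_restarts = as.integer(max_restarts)),
            class = "builder_config")
}

#' Formulation specification
#'
#' One design point of the formulation space: a targeting peptide, a drug,
#' and the peptide:drug ratio splitting the exchanged ligands.
#'
#' @param peptide peptide name.
#' @param drug drug name.
#' @param ratio integer peptide:drug pair (e.g. `c(1, 2)` or `c(2, 1)`).
#' @param n_exchange total exchanged ligands (default 15); must split into
#'   whole peptide/drug counts under `ratio`.
#' @return an object of class `formulation_spec` with `n_peptide` and
#'   `n_drug` derived as ratio shares of `n_exchange`.
#' @export
formulation_spec <- function(peptide, drug, ratio, n_exchange = 15) {
  stopifnot(length(ratio) == 2, all(ratio > 0))
  tot <- sum(ratio)
  if ((n_exchange * ratio[1]) %% tot != 0) {
    stop("ratio ", ratio[1], ":", ratio[2], " does not split n_exchange = ",
         n_exchange, " into whole counts")
  }
  structure(list(peptide = peptide, drug = drug,
                 ratio = as.integer(ratio),
                 n_peptide = as.integer(n_exchange * ratio[1] / tot),
                 n_drug = as.integer(n_exchange * ratio[2] / tot)),
            class = "formulation_spec")
}

#' Enumerate the formulation design space
#'
#' Cartesian product of peptides, drugs and ratios in deterministic
#' lexicographic order (peptides outermost, then drugs, then ratios). The
#' study design of 2 peptides x 7 drugs x 2 ratios yields 28 formulations.
#'
#' @param peptides character vector of peptide names (default the study's
#'   QS13 and RGD4C).
#' @param drugs character vector of drug names (default the study's seven).
#' @param ratios list of integer peptide:drug pairs (default `1:2` and
#'   `2:1`).
#' @param n_exchange total exchanged ligands per formulation (default 15).
#' @return a list of [formulation_spec()] objects.
#' @export
enumerate_formulations <- function(peptides = c("QS13", "RGD4C"),
                                   drugs = c("5FU", "EPI", "LIN", "TAN",
                                             "TAS", "CAP", "TOR"),
                                   ratios = list(c(1, 2), c(2, 1)),
                                   n_exchange = 15) {
  stopifnot(length(peptides) > 0, length(drugs) > 0, length(ratios) > 0)
  out <- list()
  for (p in peptides) {
    for (d in drugs) {
      for (r in ratios) {
        out[[length(out) + 1]] <- formulation_spec(p, d, r, n_exchange)
      }
    }
  }
  out
}

#' @export
print.formulation_spec <- function(x, ...) {
  cat(sprintf("formulation: %s + %s, ratio %d:%d (%d peptide + %d drug)\n",
              x$peptide, x$drug, x$ratio[1], x$ratio[2], x$n_peptide,
              x$n_drug))
  invisible(x)
}

#' Select ligand-exchange sites
#'
#' Samples `n_sites` distinct protective units uniformly without
#' replacement, and within each unit chooses one of the two ligands
#' uniformly — the one-ligand-per-unit restriction of the exchange
#' procedure. Reproducible given `seed`.
#'
#' @param model a [cluster_model()]; protective units are detected if not
#'   already attached.
#' @param n_sites number of sites.
#' @param seed RNG seed.
#' @return list of sites, each a list with `unit` (index into the staple
#'   list), `staple` (the staple unit) and `ligand_choice` (1 or 2).
#' @export
select_exchange_sites <- function(model, n_sites, seed = 1) {
  staples <- model$staples
  if (is.null(staples)) staples <- detect_protective_units(model)
  if (n_sites > length(staples)) {
    stop("n_sites (", n_sites, ") exceeds the number of protective units (",
         length(staples), ")")
  }
  if (n_sites == 0) return(list())
  with_seed(seed, {
    units <- sample.int(length(staples), n_sites, replace = FALSE)
    choices <- sample.int(2, n_sites, replace = TRUE)
    lapply(seq_len(n_sites), function(k) {
      list(unit = units[k], staple = staples[[units[k]]],
           ligand_choice = choices[k])
    })
  })
}

# S -> first-carbon direction of the ligand currently occupying a site
site_axis_direction <- function(atoms, s_idx) {
  mol <- atoms$molecule_id[s_idx]
  cand <- which(atoms$molecule_id == mol & atoms$element == "C")
  if (length(cand) == 0) stop("replaced ligand has no carbon bonded to its sulfur")
  sp <- as.numeric(atoms[s_idx, c("x", "y", "z")])
  d <- sqrt((atoms$x[cand] - sp[1])^2 + (atoms$y[cand] - sp[2])^2 +
              (atoms$z[cand] - sp[3])^2)
  c1 <- cand[which.min(d)]
  unit(as.numeric(atoms[c1, c("x", "y", "z")]) - sp)
}

#' Attempt placement of an incoming ligand at one exchange site
#'
#' Implements the three-phase placement: (1) the incoming template's anchor
#' sulfur is superposed on the original ligand's sulfur and its S-C axis
#' aligned with the original bonding direction; (2) spatially free
#' orientations are searched by rotational sampling — an outer loop over
#' S-Au rotations (about the axis through the unit's apex gold and the
#' anchor sulfur) in `step_sau` increments, and an inner loop over S-C
#' rotations in `step_cs` increments repeated per outer trial; (3) the first
#' orientation in which every template atom is at least `d_min` from every
#' atom outside the template is accepted and sampling terminates
#' immediately, which favors spatially open orientations close to the
#' natural bonding direction. Both loops start at 0 degrees and increase.
#'
#' @param model a [cluster_model()].
#' @param site a site from [select_exchange_sites()].
#' @param template an elongated [ligand_template()].
#' @param config a [builder_config()].
#' @param extra_xyz optional matrix of additional environment coordinates
#'   (e.g. ligands placed earlier in the same build but not yet merged).
#' @param drop_molecules molecule ids to exclude from the environment in
#'   addition to the replaced ligand (ligands already replaced this build).
#' @return a placement trace (list with `unit`, `replaced_ligand`,
#'   `accepted_angles` = c(theta_sau, theta_cs), `trials`, `atoms`, and
#'   `success = TRUE`), or a failure result (`success = FALSE`, full trial
#'   count) if the whole angular grid is exhausted.
#' @export
attempt_placement <- function(model, site, template, config = builder_config(),
                              extra_xyz = NULL, drop_molecules = integer(0)) {
  staple <- site$staple
  choice <- site$ligand_choice
  if (isTRUE(staple$replaced[choice])) {
    stop("site ligand is already replaced")
  }
  atoms <- model$atoms
  s_idx <- staple$sulfurs[choice]
  mol_out <- c(atoms$molecule_id[s_idx], drop_molecules)
  s_pos <- as.numeric(atoms[s_idx, c("x", "y", "z")])
  apex <- as.numeric(atoms[staple$apex_gold, c("x", "y", "z")])
  axis_dir <- site_axis_direction(atoms, s_idx)
  # deterministic base spin reference: the staple's S-S tangent
  other_s <- staple$sulfurs[3 - choice]
  tangent <- as.numeric(atoms[other_s, c("x", "y", "z")]) - s_pos
  base <- instantiate_ligand(template, s_pos, axis_dir,
                             ref_tangent = if (vec_norm(tangent) > 1e-8)
                               unit(tangent) else NULL)
  base_xyz <- cbind(base$x, base$y, base$z)
  anchor_row <- template$anchor_sulfur
  # environment: everything outside the template's future molecule
  keep <- !(atoms$molecule_id %in% mol_out)
  env <- model_xyz(model)[keep, , drop = FALSE]
  if (!is.null(extra_xyz) && nrow(extra_xyz) > 0) env <- rbind(env, extra_xyz)
  # prune to a sphere that can possibly matter for the clash criterion
  reach <- max(sqrt(rowSums(sweep(base_xyz, 2, s_pos)^2)))
  d_env <- sqrt(rowSums(sweep(env, 2, s_pos)^2))
  env <- env[d_env <= reach + config$d_min + 1e-6, , drop = FALSE]
  sau_axis <- s_pos - apex
  th_sau <- seq(0, 360 - config$step_sau, by = config$step_sau)
  th_cs <- seq(0, 360 - config$step_cs, by = config$step_cs)
  trials <- 0L
  for (a_sau in th_sau) {
    xyz1 <- if (a_sau == 0) base_xyz else
      rotate_about(base_xyz, s_pos, sau_axis, a_sau)
    cs_axis <- unit(xyz1[template$axis_carbon, ] - s_pos)
    # The inner rotation moves each template atom on a circle about the S-C
    # axis, so its axial coordinate and axis distance are invariant. A
    # template/environment pair can only ever violate d_min if the circle's
    # closest approach sqrt((rho_t - rho_e)^2 + (z_t - z_e)^2) is below
    # d_min; pruning on that bound is exact and leaves few live pairs.
    t_rel <- sweep(xyz1, 2, s_pos)
    z_t <- as.numeric(t_rel %*% cs_axis)
    rho_t <- sqrt(pmax(rowSums(t_rel^2) - z_t^2, 0))
    e_rel <- sweep(env, 2, s_pos)
    z_e <- as.numeric(e_rel %*% cs_axis)
    rho_e <- sqrt(pmax(rowSums(e_rel^2) - z_e^2, 0))
    feasible <- (outer(rho_t, rho_e, "-")^2 + outer(z_t, z_e, "-")^2) <
      config$d_min^2
    accept_cs <- NA
    if (!any(feasible)) {
      accept_cs <- 1L  # nothing can ever clash: first inner angle wins
    } else {
      # For a live pair (t, e), the distance along the circle is
      # d^2(a) = |v|^2 + r_t^2 - 2 (P cos a + Q sin a) with v = e - c_t,
      # P = v . r1, Q = v . (axis x r1); the clash condition d < d_min is a
      # single closed arc per pair, evaluated in closed form for the whole
      # inner grid at once.
      pair <- which(feasible, arr.ind = TRUE)
      ti <- pair[, 1]; ei <- pair[, 2]
      c_t <- matrix(s_pos, length(ti), 3, byrow = TRUE) + z_t[ti] %o% cs_axis
      r1 <- xyz1[ti, , drop = FALSE] - c_t
      v <- env[ei, , drop = FALSE] - c_t
      P <- rowSums(v * r1)
      ax_r1 <- cbind(cs_axis[2] * r1[, 3] - cs_axis[3] * r1[, 2],
                     cs_axis[3] * r1[, 1] - cs_axis[1] * r1[, 3],
                     cs_axis[1] * r1[, 2] - cs_axis[2] * r1[, 1])
      Q <- rowSums(v * ax_r1)
      C <- (rowSums(v^2) + rho_t[ti]^2 - config$d_min^2) / 2
      R <- sqrt(P^2 + Q^2)
      phi <- atan2(Q, P) * 180 / pi
      blocked <- rep(FALSE, length(th_cs))
      const <- R < 1e-9  # distance independent of the angle
      if (any(const & C < 0) || any(!const & C < -R)) {
        blocked[] <- TRUE  # some pair clashes at every angle
      } else {
        act <- !const & C < R  # pairs with a non-empty forbidden arc
        if (any(act)) {
          w <- acos(pmin(pmax(C[act] / R[act], -1), 1)) * 180 / pi
          dphi <- abs((outer(th_cs, phi[act], "-") + 180) %% 360 - 180)
          blocked <- rowSums(dphi < matrix(w, length(th_cs), sum(act),
                                           byrow = TRUE)) > 0
        }
      }
      open <- which(!blocked)
      if (length(open) > 0) accept_cs <- open[1]
    }
    if (!is.na(accept_cs)) {
      a_cs <- th_cs[accept_cs]
      trials <- trials + accept_cs
      xyz2 <- if (a_cs == 0) xyz1 else
        rotate_about(xyz1, s_pos, cs_axis, a_cs)
      placed <- base
      placed$x <- xyz2[, 1]; placed$y <- xyz2[, 2]; placed$z <- xyz2[, 3]
      return(list(success = TRUE, unit = site$unit,
                  replaced_ligand = choice,
                  replaced_molecule = atoms$molecule_id[s_idx],
                  accepted_angles = c(sau = a_sau, cs = a_cs),
                  trials = trials, atoms = placed,
                  component = template$component,
                  template = template$name))
    }
    trials <- trials + length(th_cs)
  }
  list(success = FALSE, unit = site$unit, replaced_ligand = choice,
       replaced_molecule = atoms$molecule_id[s_idx],
       accepted_angles = NULL, trials = trials)
}

#' Build a functionalized cluster by ligand exchange
#'
#' Replaces `n_peptide + n_drug` original thiolates with incoming PEG
#' conjugates: exchange sites are drawn at random (one ligand per
#' protective unit), all peptide conjugates are placed before the drug
#' conjugates in site-selection order, and each placement uses
#' [attempt_placement()]'s nested rotational sampling under the minimum
#' distance criterion. If any placement exhausts its angular grid, the
#' whole build restarts with fresh random sites (seed advanced by one),
#' up to `max_restarts` times. Gold atoms are never moved.
#'
#' @param model a [cluster_model()] with protective units.
#' @param formulation a [formulation_spec()].
#' @param peptide_template,drug_template [ligand_template()] conjugates;
#'   elongated with [elongate_conformer()] before use.
#' @param config a [builder_config()]; `config$n_exchange` must equal
#'   `formulation$n_peptide + formulation$n_drug`.
#' @return a list with `model` (the functionalized [cluster_model()]),
#'   `traces` (placement traces in placement order) and `restarts`.
#' @export
build_functionalized_cluster <- function(model, formulation,
                                         peptide_template, drug_template,
                                         config = builder_config()) {
  stopifnot(inherits(model, "cluster_model"),
            inherits(formulation, "formulation_spec"))
  n_total <- formulation$n_peptide + formulation$n_drug
  if (n_total != config$n_exchange) {
    stop("formulation counts (", n_total, ") do not match config$n_exchange (",
         config$n_exchange, ")")
  }
  if (is.null(model$staples)) model$staples <- detect_protective_units(model)
  if (n_total == 0) {
    return(list(model = model, traces = list(), restarts = 0L))
  }
  pep <- elongate_conformer(peptide_template)
  drg <- elongate_conformer(drug_template)
  fail_count <- integer(length(model$staples))
  for (restart in 0:(config$max_restarts - 1)) {
    sites <- select_exchange_sites(model, n_total,
                                   seed = config$seed + restart)
    templates <- c(rep(list(pep), formulation$n_peptide),
                   rep(list(drg), formulation$n_drug))
    traces <- list()
    extra <- matrix(numeric(0), 0, 3)
    dropped <- integer(0)
    ok <- TRUE
    for (k in seq_len(n_total)) {
      tr <- attempt_placement(model, sites[[k]], templates[[k]], config,
                              extra_xyz = extra, drop_molecules = dropped)
      if (!tr$success) {
        fail_count[sites[[k]]$unit] <- fail_count[sites[[k]]$unit] + 1L
        ok <- FALSE
        break
      }
      traces[[k]] <- tr
      extra <- rbind(extra, cbind(tr$atoms$x, tr$atoms$y, tr$atoms$z))
      dropped <- c(dropped, tr$replaced_molecule)
    }
    if (ok) {
      out <- assemble_build(model, traces)
      # post-hoc soundness scan of the full assembled model
      gap <- min_external_distance(out, c("PL", "DL"))
      if (gap < config$d_min - 1e-9) {
        stop(sprintf(
          "internal error: assembled build violates d_min (%.3f < %.3f)",
          gap, config$d_min))
      }
      return(list(model = out, traces = traces, restarts = restart))
    }
  }
  worst <- which.max(fail_count)
  stop("max_restarts (", config$max_restarts, ") exhausted; most-blocked ",
       "protective unit: ", worst, " (apex gold atom ",
       model$staples[[worst]]$apex_gold, ", ", fail_count[worst],
       " failures)")
}

# merge accepted placements into a new cluster_model: original atoms minus
# replaced ligand molecules, incoming ligands appended in placement order
assemble_build <- function(model, traces) {
  atoms <- model$atoms
  replaced <- vapply(traces, `[[`, integer(1), "replaced_molecule")
  keep <- !(atoms$molecule_id %in% replaced)
  kept <- atoms[keep, , drop = FALSE]
  next_id <- max(atoms$molecule_id) + 1L
  new_rows <- list()
  for (k in seq_along(traces)) {
    a <- traces[[k]]$atoms
    a$molecule_id <- next_id
    a$component <- traces[[k]]$component
    next_id <- next_id + 1L
    new_rows[[k]] <- a
  }
  all_atoms <- rbind(kept[names(new_rows[[1]])], do.call(rbind, new_rows))
  out <- cluster_model(all_atoms,
                       provenance = paste0(model$provenance,
                                           "; functionalized (",
                                           length(traces), " exchanged)"))
  out$staples <- detect_protective_units(out)
  comp_of_mol <- tapply(out$atoms$component, out$atoms$molecule_id,
                        function(z) z[1])
  for (i in seq_along(out$staples)) {
    lig <- out$staples[[i]]$ligands
    out$staples[[i]]$replaced <-
      comp_of_mol[as.character(lig)] %in% c("PL", "DL")
  }
  out
}

#' Minimum external distance of incoming ligands
#'
#' For each incoming ligand molecule whose component tag is in `components`,
#' computes the minimum distance between its atoms and every atom outside
#' that molecule, and returns the global minimum — the quantity bounded
#' below by the builder's clash criterion. The brute-force double loop and
#' the cell-accelerated path give identical results.
#'
#' @param model a [cluster_model()] with at least one matching molecule.
#' @param components component tags defining "incoming" (default PL and DL).
#' @param method `"brute"` (vectorized double loop) or `"cells"`
#'   (cutoff-doubling cell list).
#' @return minimum distance in Angstrom.
#' @export
min_external_distance <- function(model, components = c("PL", "DL"),
                                  method = c("brute", "cells")) {
  method <- match.arg(method)
  a <- model$atoms
  mols <- unique(a$molecule_id[a$component %in% components])
  if (length(mols) == 0) {
    stop("no molecules with component in {",
         paste(components, collapse = ", "), "}")
  }
  xyz <- model_xyz(model)
  best <- Inf
  for (m in mols) {
    inside <- a$molecule_id == m
    if (method == "brute") {
      d <- min_cross_distance(xyz[inside, , drop = FALSE],
                              xyz[!inside, , drop = FALSE])
    } else {
      d <- min_cross_distance_cells(xyz[inside, , drop = FALSE],
                                    xyz[!inside, , drop = FALSE])
    }
    if (d < best) best <- d
  }
  best
}

# exact set-to-set minimum distance via a cutoff-doubling cell list: if any
# cross pair lies within the cutoff, the smallest such pair is the answer
min_cross_distance_cells <- function(xyz_a, xyz_b, cutoff = 3.0) {
  if (nrow(xyz_a) == 0 || nrow(xyz_b) == 0) return(Inf)
  all_xyz <- rbind(xyz_a, xyz_b)
  na <- nrow(xyz_a)
  repeat {
    p <- pairs_within(all_xyz, cutoff)
    cross <- p[(p[, 1] <= na) != (p[, 2] <= na), , drop = FALSE]
    if (nrow(cross) > 0) {
      return(min(sqrt(rowSums((all_xyz[cross[, 1], , drop = FALSE] -
                               all_xyz[cross[, 2], , drop = FALSE])^2))))
    }
    cutoff <- cutoff * 2
    # guaranteed to terminate: the sets' bounding box is finite
    if (cutoff > 10 * (max(all_xyz) - min(all_xyz) + 1)) {
      return(min_cross_distance(xyz_a, xyz_b))
    }
  }
}
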