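# Seeded synthetic fixtures: small staple-decorated clusters and toy
# trajectories with analytically known radius of gyration / SASA / RDF
# ground truth, so every estimator and the placement algorithm can be
# exercised without external data.

#' Methylthiolate ligand template
#'
#' The smallest thiolate (S-CH3), used by the toy cluster fixture.
#'
#' @return a [ligand_template()].
#' @export
methylthiolate_template <- function() {
  s <- c(0, 0, 0)
  c1 <- c(0, 0, 1.82)
  h <- NULL
  for (ph in c(0, 120, 240) * pi / 180) {
    h <- rbind(h, c1 + 1.09 * c(sin(1.911) * cos(ph), sin(1.911) * sin(ph),
                                cos(1.911)))
  }
  atoms <- data.frame(element = c("S", "C", "H", "H", "H"),
                      x = c(s[1], c1[1], h[, 1]),
                      y = c(s[2], c1[2], h[, 2]),
                      z = c(s[3], c1[3], h[, 3]), stringsAsFactors = FALSE)
  bonds <- rbind(c(1, 2), c(2, 3), c(2, 4), c(2, 5))
  ligand_template(atoms, bonds, anchor_sulfur = 1, axis_carbon = 2,
                  component = "OL", name = "SCH3")
}

#' Generate a toy staple-decorated cluster
#'
#' A 13-atom icosahedral gold core (center plus 12 vertices) decorated with
#' `k_staples` clash-free RS-Au-SR units bearing methylthiolate ligands.
#' Staple directions are drawn (seeded) from the 30 icosahedral
#' edge-midpoint directions, so unit placements vary with the seed while
#' counts stay fixed.
#'
#' @param k_staples number of protective units (0 to 30).
#' @param seed RNG seed.
#' @return a [cluster_model()] with `k_staples` detected units.
#' @export
make_toy_cluster <- function(k_staples = 3, seed = 1) {
  stopifnot(k_staples >= 0)
  v <- icosahedron_vertices()
  edges <- icosahedron_edges(v)
  dirs <- t(apply(edges, 1, function(e) unit(v[e[1], ] + v[e[2], ])))
  tans <- t(apply(edges, 1, function(e) unit(v[e[2], ] - v[e[1], ])))
  if (k_staples > nrow(dirs)) {
    stop("k_staples (", k_staples, ") exceeds the ", nrow(dirs),
         " clash-free staple directions of the toy core")
  }
  r_core <- 2.85
  core <- rbind(c(0, 0, 0), r_core * v)
  core_atoms <- data.frame(element = "Au", x = core[, 1], y = core[, 2],
                           z = core[, 3], molecule_id = 1L,
                           component = "GOLD_CORE", stringsAsFactors = FALSE)
  if (k_staples == 0) {
    model <- cluster_model(core_atoms, provenance = sprintf(
      "toy cluster: 13 Au core, 0 staples, seed %d", seed))
    model$staples <- list()
    return(model)
  }
  lig <- methylthiolate_template()
  tilt <- 7.5 * pi / 180
  r_apex <- r_core + 2.8
  # staple subsets are seeded draws; clashing draws (adjacent edges crowd
  # the small core) are re-drawn deterministically a bounded number of times
  for (attempt in 0:24) {
    atoms <- core_atoms
    # prefer vertex-disjoint edges: staples on edges sharing a vertex crowd
    # their sulfurs on the small core
    pick <- with_seed(seed + 1000L * attempt, {
      ord <- sample.int(nrow(dirs))
      chosen <- integer(0)
      used_v <- integer(0)
      for (e in ord) {
        if (length(chosen) == k_staples) break
        if (!any(edges[e, ] %in% used_v)) {
          chosen <- c(chosen, e)
          used_v <- c(used_v, edges[e, ])
        }
      }
      c(chosen, setdiff(ord, chosen))[seq_len(k_staples)]
    })
    next_mol <- 2L
    for (k in pick) {
      u <- dirs[k, ]; tv <- tans[k, ]
      apex <- r_apex * u
      atoms <- rbind(atoms, data.frame(
        element = "Au", x = apex[1], y = apex[2], z = apex[3],
        molecule_id = 1L, component = "GOLD_CORE", stringsAsFactors = FALSE))
      for (sgn in c(-1, 1)) {
        s_pos <- apex + 2.33 * (sgn * cos(tilt) * tv - sin(tilt) * u)
        at <- instantiate_ligand(lig, s_pos, unit(s_pos), ref_tangent = tv)
        at$molecule_id <- next_mol
        at$component <- "OL"
        atoms <- rbind(atoms, at)
        next_mol <- next_mol + 1L
      }
    }
    model <- cluster_model(atoms, provenance = sprintf(
      "toy cluster: 13 Au core, %d staples, seed %d", k_staples, seed))
    if (reference_min_intermolecular(model) >= 1.75) {
      staples <- tryCatch(detect_protective_units(model),
                          error = function(e) NULL)
      if (!is.null(staples) && length(staples) == k_staples) {
        model$staples <- staples
        return(model)
      }
    }
  }
  stop("could not place ", k_staples,
       " clash-free staples on the toy core (try a smaller k)")
}

#' Generate a toy trajectory with known ground truth
#'
#' Emits a multi-model PDB plus a sidecar JSON of ground-truth values for
#' one of three analytically controlled cases:
#' \describe{
#'   \item{`rigid_translation`}{a toy cluster rigidly translated each frame:
#'     the radius of gyration is identical across frames.}
#'   \item{`ion_shell`}{fixed reference atoms, each surrounded by ions at
#'     exactly `shell_radius` nm: the RDF mode bin contains `shell_radius`.}
#'   \item{`ideal_gas`}{two uniform random atom groups in a periodic box:
#'     g(r) is flat at 1 up to sampling noise.}
#' }
#' Outputs are reproducible byte-for-byte given the same spec and seed.
#'
#' @param kind one of `"rigid_translation"`, `"ion_shell"`, `"ideal_gas"`.
#' @param dir output directory (created if needed).
#' @param n_frames number of frames (default 10).
#' @param shell_radius ion-shell radius in nm (default 0.27; `ion_shell`).
#' @param box cubic box edge in nm (default 4).
#' @param n_ions ions per reference atom (`ion_shell`) or per group
#'   (`ideal_gas`; default 24 / 150).
#' @param seed RNG seed.
#' @return a list with `pdb` and `json` file paths, `truth` (the ground
#'   truth list) and `trajectory` (the in-memory [trajectory()]).
#' @export
make_toy_trajectory <- function(kind = c("rigid_translation", "ion_shell",
                                         "ideal_gas"),
                                dir = tempdir(), n_frames = 10,
                                shell_radius = 0.27, box = 4,
                                n_ions = NULL, seed = 1) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  box_a <- rep(box * 10, 3)
  truth <- list(kind = kind, seed = seed, n_frames = n_frames,
                box_nm = box)
  if (kind == "rigid_translation") {
    base <- make_toy_cluster(3, seed = seed)
    xyz0 <- model_xyz(base)
    xyz0 <- sweep(xyz0, 2, colMeans(xyz0))
    frames <- with_seed(seed, {
      lapply(seq_len(n_frames), function(f) {
        sweep(xyz0, 2, stats::runif(3, 10, box_a[1] - 10), "+")
      })
    })
    traj <- trajectory(base$atoms, frames, box = box_a, periodic = FALSE)
    truth$rg_mass_nm <- radius_of_gyration(base, weights = "mass")
    truth$rg_uniform_nm <- radius_of_gyration(base, weights = "uniform")
  } else if (kind == "ion_shell") {
    n_centers <- 4
    if (is.null(n_ions)) n_ions <- 24
    # reference atoms on a wide lattice, well separated
    cen <- box_a[1] * cbind(c(.25, .25, .75, .75), c(.25, .75, .25, .75),
                            c(.25, .75, .75, .25))
    atoms <- data.frame(
      element = c(rep("S", n_centers), rep("Na", n_centers * n_ions)),
      x = 0, y = 0, z = 0,
      molecule_id = seq_len(n_centers + n_centers * n_ions),
      component = c(rep("OL", n_centers),
                    rep("ION", n_centers * n_ions)),
      stringsAsFactors = FALSE)
    frames <- with_seed(seed, {
      lapply(seq_len(n_frames), function(f) {
        ion <- NULL
        for (c_i in seq_len(n_centers)) {
          u <- matrix(stats::rnorm(3 * n_ions), ncol = 3)
          u <- u / sqrt(rowSums(u^2))
          ion <- rbind(ion, sweep(u * shell_radius * 10, 2, cen[c_i, ], "+"))
        }
        rbind(cen, ion)
      })
    })
    traj <- trajectory(atoms, frames, box = box_a, periodic = TRUE)
    truth$shell_radius_nm <- shell_radius
    truth$group_a <- "element S"; truth$group_b <- "element Na"
  } else {
    if (is.null(n_ions)) n_ions <- 150
    atoms <- data.frame(
      element = c(rep("Na", n_ions), rep("Cl", n_ions)),
      x = 0, y = 0, z = 0,
      molecule_id = seq_len(2 * n_ions),
      component = "ION", stringsAsFactors = FALSE)
    frames <- with_seed(seed, {
      lapply(seq_len(n_frames), function(f) {
        matrix(stats::runif(6 * n_ions, 0, box_a[1]), ncol = 3)
      })
    })
    traj <- trajectory(atoms, frames, box = box_a, periodic = TRUE)
    truth$expected_g <- 1
  }
  pdb <- file.path(dir, sprintf("toy_%s_seed%d.pdb", kind, seed))
  json <- file.path(dir, sprintf("toy_%s_seed%d.json", kind, seed))
  write_trajectory_pdb(traj, pdb)
  jsonlite::write_json(truth, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(pdb = pdb, json = json, truth = truth, trajectory = traj)
}
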