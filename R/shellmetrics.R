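# Ligand-shell analysis estimators over structures and trajectories:
# radius of gyration, Shrake-Rupley SASA attributed per shell component,
# component-to-core distance time series, and radial distribution
# functions. Coordinates are Angstrom internally; results are reported in
# nm / nm^2, the units used at the analysis boundary.

#' Analysis configuration
#'
#' @param probe_radius solvent probe radius in nm (default 0.14, a water
#'   probe).
#' @param n_sphere_points Shrake-Rupley test points per atom (default 960;
#'   minimum 12).
#' @param rdf_bin RDF bin width in nm (default 0.002).
#' @param rdf_rmax RDF range in nm; default half the smallest box edge.
#' @param equilibration_cutoff discard frames before this time in ns when
#'   summarizing trajectories (default 30, where shell observables level
#'   off).
#' @param radii_table optional named vector of van der Waals radii in nm per
#'   element, overriding the built-in Bondi values.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(probe_radius = 0.14, n_sphere_points = 960,
                            rdf_bin = 0.002, rdf_rmax = NULL,
                            equilibration_cutoff = 30, radii_table = NULL) {
  stopifnot(probe_radius > 0, n_sphere_points >= 12, rdf_bin > 0,
            is.null(rdf_rmax) || rdf_rmax > 0, equilibration_cutoff >= 0)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 rdf_bin = rdf_bin, rdf_rmax = rdf_rmax,
                 equilibration_cutoff = equilibration_cutoff,
                 radii_table = radii_table),
            class = "analysis_config")
}

# vdW radius in Angstrom for elements, honoring a config override (nm)
vdw_radii <- function(elements, config) {
  el <- normalize_element(elements)
  r <- element_property(el, "vdw")
  if (!is.null(config$radii_table)) {
    hit <- el %in% names(config$radii_table)
    r[hit] <- config$radii_table[el[hit]] * 10
  }
  r
}

#' Construct a trajectory
#'
#' @param atoms topology atom table (as in [cluster_model()]).
#' @param frames list of n_atoms x 3 coordinate matrices in Angstrom.
#' @param times frame times in ns (default `0, 1, 2, ...`).
#' @param box box edge lengths in Angstrom (length 3) or `NULL`.
#' @param periodic logical; minimum-image convention is applied in analyses
#'   when `TRUE` (requires `box`).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(atoms, frames, times = NULL, box = NULL,
                       periodic = !is.null(box)) {
  stopifnot(is.list(frames), length(frames) >= 1)
  n <- nrow(atoms)
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3) {
      stop("every frame must be an n_atoms x 3 matrix matching the topology")
    }
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  stopifnot(length(times) == length(frames))
  if (periodic && (is.null(box) || any(box <= 0))) {
    stop("periodic trajectories need positive box lengths")
  }
  structure(list(atoms = atoms, frames = frames, times = as.numeric(times),
                 box = box, periodic = periodic),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %g..%g ns%s\n",
              length(x$frames), nrow(x$atoms), min(x$times), max(x$times),
              if (x$periodic) sprintf(", periodic box %.1f A",
                                      min(x$box)) else ""))
  invisible(x)
}

# single-structure convenience: a one-frame trajectory
as_trajectory <- function(model, time = 0) {
  trajectory(model$atoms, list(model_xyz(model)), times = time,
             box = model$box, periodic = FALSE)
}

#' Read a trajectory file
#'
#' Multi-model PDB (via bio3d) or concatenated XYZ. XYZ frame comments may
#' carry `time=<ns>` and `box=<a>,<b>,<c>` (Angstrom) key=value entries; for
#' PDB, times default to `dt`-spaced values and the box is taken from
#' CRYST1 when present.
#'
#' @param path trajectory file.
#' @param format `"pdb"` or `"xyz"`; default from the extension.
#' @param dt frame spacing in ns used when the file carries no times
#'   (default 1).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = NULL, dt = 1) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("pdb", "xyz"))
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    topo <- read_pdb_model(path)
    nf <- nrow(pdb$xyz)
    frames <- lapply(seq_len(nf), function(i) {
      matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    })
    box <- NULL
    cry <- grep("^CRYST1", readLines(path, n = 500), value = TRUE)
    if (length(cry) >= 1) {
      bx <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                         substr(cry[1], 25, 33)))
      if (!anyNA(bx) && all(bx > 0)) box <- bx
    }
    trajectory(topo$atoms, frames, times = (seq_len(nf) - 1) * dt,
               box = box, periodic = !is.null(box))
  } else {
    lines <- readLines(path)
    frames <- list(); times <- numeric(0); box <- NULL; atoms <- NULL
    i <- 1
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
      n <- as.integer(trimws(lines[i]))
      tmp <- tempfile(fileext = ".xyz")
      writeLines(lines[i:(i + n + 1)], tmp)
      m <- read_xyz(tmp)
      unlink(tmp)
      if (is.null(atoms)) atoms <- m$atoms
      frames[[length(frames) + 1]] <- model_xyz(m)
      kv <- regmatches(lines[i + 1],
                       regexpr("time=[-0-9.eE+]+", lines[i + 1]))
      times <- c(times, if (length(kv) == 1)
        as.numeric(sub("time=", "", kv)) else (length(frames) - 1) * dt)
      if (!is.null(m$box)) box <- m$box
      i <- i + n + 2
    }
    trajectory(atoms, frames, times = times, box = box,
               periodic = !is.null(box))
  }
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$atoms
  resid <- .comp_to_resid[a$component]
  name <- make_atom_names(a)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$box)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
      traj$box[1], traj$box[2], traj$box[3]), con)
  }
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$frames[[f]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)) %% 100000L, substr(name, 1, 4), substr(resid, 1, 3),
      a$molecule_id %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3],
      toupper(a$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# resolve a selection (component tag(s), integer indices, or NULL = all)
resolve_selection <- function(atoms, selection) {
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  if (is.character(selection)) {
    idx <- which(atoms$component %in% selection)
  } else {
    idx <- as.integer(selection)
  }
  if (length(idx) == 0) stop("empty atom selection")
  idx
}

#' Radius of gyration
#'
#' Rg = sqrt( sum w_i |r_i - r_bar|^2 / sum w_i ) with r_bar the w-weighted
#' centroid. The conventional estimator weights by atomic mass
#' (`weights = "mass"`); `weights = "uniform"` gives the unit-weight
#' (geometric) convention used by common visualization-toolkit scripts,
#' which is the convention the reference shell values of this package's
#' validation suite follow.
#'
#' @param x a [cluster_model()] or [trajectory()].
#' @param selection component tag(s), atom indices, or `NULL` for all atoms.
#' @param weights `"mass"`, `"uniform"`, or a numeric vector matching the
#'   selection.
#' @return Rg in nm; for a trajectory, one value per frame.
#' @export
radius_of_gyration <- function(x, selection = NULL, weights = "mass") {
  traj <- if (inherits(x, "cluster_model")) as_trajectory(x) else x
  stopifnot(inherits(traj, "trajectory"))
  idx <- resolve_selection(traj$atoms, selection)
  w <- if (is.numeric(weights)) {
    stopifnot(length(weights) == length(idx))
    weights
  } else if (identical(weights, "uniform")) {
    rep(1, length(idx))
  } else {
    element_property(traj$atoms$element[idx], "mass")
  }
  vapply(traj$frames, function(xyz) {
    p <- xyz[idx, , drop = FALSE]
    com <- colSums(p * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(p, 2, com)^2)) / sum(w)) / 10
  }, numeric(1))
}

#' Solvent-accessible surface area by shell component
#'
#' Shrake-Rupley SASA: each atom carries a quasi-uniform shell of test
#' points at radius (vdW + probe); a point is exposed when it lies outside
#' every other atom's inflated sphere, and the atom's accessible area is
#' the exposed fraction of 4 pi (vdW + probe)^2. Atom areas are summed per
#' component tag; the total is the exact sum of the component areas.
#'
#' @param x a [cluster_model()] or single-frame [trajectory()].
#' @param selection atoms to include (default: all atoms except SOLVENT and
#'   ION).
#' @param config an [analysis_config()] (probe radius, point count, radii).
#' @return a list with `components` (named vector, nm^2), `total` (nm^2) and
#'   `per_atom` (nm^2 per selected atom).
#' @export
sasa_by_component <- function(x, selection = NULL,
                              config = analysis_config()) {
  model_atoms <- if (inherits(x, "cluster_model")) x$atoms else x$atoms
  xyz_all <- if (inherits(x, "cluster_model")) model_xyz(x) else x$frames[[1]]
  if (is.null(selection)) {
    idx <- which(!(model_atoms$component %in% c("SOLVENT", "ION")))
  } else {
    idx <- resolve_selection(model_atoms, selection)
  }
  atoms <- model_atoms[idx, , drop = FALSE]
  xyz <- xyz_all[idx, , drop = FALSE]
  probe <- config$probe_radius * 10
  radii <- vdw_radii(atoms$element, config) + probe
  n <- nrow(xyz)
  pts <- sphere_points(config$n_sphere_points)
  # neighbor candidates within the largest possible occlusion distance
  nb_pairs <- pairs_within(xyz, 2 * max(radii))
  nb <- vector("list", n)
  if (nrow(nb_pairs) > 0) {
    d <- sqrt(rowSums((xyz[nb_pairs[, 1], , drop = FALSE] -
                       xyz[nb_pairs[, 2], , drop = FALSE])^2))
    occl <- d < radii[nb_pairs[, 1]] + radii[nb_pairs[, 2]]
    nb_pairs <- nb_pairs[occl, , drop = FALSE]
    for (k in seq_len(nrow(nb_pairs))) {
      i <- nb_pairs[k, 1]; j <- nb_pairs[k, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  area <- numeric(n)
  for (i in seq_len(n)) {
    shell <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(shell))
    for (j in nb[[i]]) {
      d2 <- rowSums(sweep(shell, 2, xyz[j, ])^2)
      exposed <- exposed & d2 >= radii[j]^2
      if (!any(exposed)) break
    }
    area[i] <- mean(exposed) * 4 * pi * radii[i]^2
  }
  area_nm2 <- area / 100
  comp <- tapply(area_nm2, atoms$component, sum)
  list(components = comp[order(names(comp))],
       total = sum(area_nm2), per_atom = area_nm2)
}

#' Component-to-core distance time series
#'
#' For each frame, the distance between the center of mass of each ligand
#' copy carrying the selected component and the center of mass of the gold
#' core, averaged over copies; summarized as mean and sd over frames at or
#' after the equilibration cutoff.
#'
#' @param traj a [trajectory()].
#' @param component component tag(s) or atom indices selecting the shell
#'   component; copies are its distinct molecules.
#' @param core core selection (default component `"GOLD_CORE"`).
#' @param config an [analysis_config()] (equilibration cutoff, ns).
#' @return a list with `times` (ns), `values` (nm per frame), `mean`, `sd`
#'   and `frames_used`.
#' @export
component_core_distance <- function(traj, component, core = "GOLD_CORE",
                                    config = analysis_config()) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- resolve_selection(traj$atoms, component)
  core_idx <- resolve_selection(traj$atoms, core)
  w_sel <- element_property(traj$atoms$element[sel], "mass")
  w_core <- element_property(traj$atoms$element[core_idx], "mass")
  copies <- split(seq_along(sel), traj$atoms$molecule_id[sel])
  vals <- vapply(traj$frames, function(xyz) {
    com_core <- colSums(xyz[core_idx, , drop = FALSE] * w_core) / sum(w_core)
    d <- vapply(copies, function(rows) {
      ii <- sel[rows]
      com <- colSums(xyz[ii, , drop = FALSE] * w_sel[rows]) / sum(w_sel[rows])
      vec_norm(com - com_core)
    }, numeric(1))
    mean(d) / 10
  }, numeric(1))
  s <- time_series_summary(vals, traj$times, config$equilibration_cutoff)
  list(times = traj$times, values = vals, mean = s$mean, sd = s$sd,
       frames_used = s$n)
}

#' Summarize a time series after an equilibration cutoff
#'
#' @param values numeric samples.
#' @param times sample times in ns (same length).
#' @param cutoff keep samples with `time >= cutoff` (ns).
#' @return list with `mean`, `sd` (sample sd; 0 for a single sample) and
#'   `n`.
#' @export
time_series_summary <- function(values, times, cutoff = 30) {
  stopifnot(length(values) == length(times))
  keep <- times >= cutoff
  if (!any(keep)) {
    stop("no samples at or after the equilibration cutoff (", cutoff, " ns)")
  }
  v <- values[keep]
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       n = length(v))
}

#' Radial distribution function between two atom groups
#'
#' Pair distances are histogrammed in `rdf_bin`-wide shells (minimum-image
#' convention when the trajectory is periodic) and normalized by shell
#' volume and the average pair density, so an ideal gas gives g(r) = 1.
#' Frames before the equilibration cutoff are discarded.
#'
#' @param traj a [trajectory()] with a box.
#' @param group_a,group_b disjoint, non-empty atom selections (component
#'   tags or indices).
#' @param config an [analysis_config()] (`rdf_bin`, `rdf_rmax`,
#'   equilibration cutoff).
#' @return a list of class `rdf_result`: `bin_centers` (nm), `g`
#'   (dimensionless), `n_pairs` (count within rmax over used frames) and
#'   `frames_used`.
#' @export
rdf <- function(traj, group_a, group_b, config = analysis_config()) {
  stopifnot(inherits(traj, "trajectory"))
  ia <- resolve_selection(traj$atoms, group_a)
  ib <- resolve_selection(traj$atoms, group_b)
  if (length(intersect(ia, ib)) > 0) stop("group_a and group_b must be disjoint")
  if (is.null(traj$box)) stop("rdf needs a box to normalize the pair density")
  box <- traj$box
  rmax <- if (!is.null(config$rdf_rmax)) config$rdf_rmax * 10 else
    min(box) / 2
  if (traj$periodic && rmax > min(box) / 2 + 1e-9) {
    stop("rdf_rmax (", rmax / 10, " nm) exceeds half the smallest box edge (",
         min(box) / 20, " nm) under periodic boundaries")
  }
  dr <- config$rdf_bin * 10
  edges <- seq(0, rmax, by = dr)
  if (edges[length(edges)] < rmax - 1e-9) edges <- c(edges, rmax)
  nb <- length(edges) - 1
  use <- which(traj$times >= config$equilibration_cutoff)
  if (length(use) == 0) {
    stop("no frames at or after the equilibration cutoff (",
         config$equilibration_cutoff, " ns)")
  }
  counts <- numeric(nb)
  for (f in use) {
    xyz <- traj$frames[[f]]
    dx <- outer(xyz[ia, 1], xyz[ib, 1], "-")
    dy <- outer(xyz[ia, 2], xyz[ib, 2], "-")
    dz <- outer(xyz[ia, 3], xyz[ib, 3], "-")
    if (traj$periodic) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
    }
    d <- sqrt(dx^2 + dy^2 + dz^2)
    d <- d[d < rmax]
    if (length(d) > 0) {
      h <- tabulate(pmin(floor(d / dr) + 1L, nb), nbins = nb)
      counts <- counts + h
    }
  }
  vol <- prod(box)
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  pair_density <- length(ia) * length(ib) / vol
  g <- counts / (length(use) * pair_density * shell_vol)
  structure(list(bin_centers = (edges[-1] + edges[-(nb + 1)]) / 2 / 10,
                 g = g, n_pairs = sum(counts), frames_used = length(use)),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("rdf_result: %d bins to %.3f nm, %d pairs over %d frames\n",
              length(x$g), max(x$bin_centers), x$n_pairs, x$frames_used))
  if (any(x$g > 0)) {
    cat(sprintf("  mode bin at %.3f nm (g = %.2f)\n",
                x$bin_centers[which.max(x$g)], max(x$g)))
  }
  invisible(x)
}
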