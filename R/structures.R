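# Structure data model and file I/O.
#
# A cluster_model holds an ordered atom table (element, x, y, z in Angstrom,
# molecule_id, component), an optional bond list, detected protective units
# (staples) and free-text provenance. Component tags follow the shell
# nomenclature: GOLD_CORE (all metal atoms), OL (original p-MBA thiolates),
# PL (PEG-peptide conjugates), DL (PEG-drug conjugates), ION, SOLVENT.

#' Construct a cluster model
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (Angstrom),
#'   `molecule_id` (integer) and `component` (see [element_property()] for
#'   recognized elements). Extra columns (e.g. `resid`) are preserved.
#' @param bonds optional 2-column integer matrix of bonded atom indices.
#' @param staples optional list of staple units as returned by
#'   [detect_protective_units()].
#' @param provenance free-text metadata string.
#' @return an object of class `cluster_model`.
#' @export
cluster_model <- function(atoms, bonds = NULL, staples = NULL,
                          provenance = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("element", "x", "y", "z", "molecule_id", "component")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atoms is missing column(s): ",
                             paste(miss, collapse = ", "))
  atoms$element <- normalize_element(atoms$element)
  if (!all(is_known_element(atoms$element))) {
    stop("unknown element(s): ",
         paste(unique(atoms$element[!is_known_element(atoms$element)]),
               collapse = ", "))
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite atom coordinates")
  }
  check_component(atoms$component)
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds, staples = staples,
                 provenance = provenance),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  a <- x$atoms
  cat("cluster_model:", nrow(a), "atoms,",
      length(unique(a$molecule_id)), "molecules\n")
  cat("  components:",
      paste(sprintf("%s=%d", names(table(a$component)), table(a$component)),
            collapse = " "), "\n")
  if (!is.null(x$staples)) cat("  protective units:", length(x$staples), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# n x 3 coordinate matrix of a model (or of selected atom indices)
model_xyz <- function(model, idx = NULL) {
  a <- model$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  cbind(a$x, a$y, a$z)
}

#' Detect covalent bonds by distance
#'
#' Bonds are assigned where the interatomic distance is below a cutoff:
#' 1.2 times the covalent-radius sum for organic pairs, and a fixed
#' `au_s_cutoff` for Au-S contacts. Au-Au metallic contacts are not listed
#' as bonds.
#'
#' @param model a [cluster_model()].
#' @param au_s_cutoff Au-S bond cutoff in Angstrom (default 2.6).
#' @param scale multiplier on the covalent-radius sum (default 1.2).
#' @return 2-column integer matrix of bonded atom index pairs (i < j).
#' @export
detect_bonds <- function(model, au_s_cutoff = 2.6, scale = 1.2) {
  a <- model$atoms
  n <- nrow(a)
  if (n < 2) return(matrix(integer(0), 0, 2))
  rc <- element_property(a$element, "covalent")
  maxcut <- max(au_s_cutoff, scale * 2 * max(rc))
  cand <- pairs_within(model_xyz(model), maxcut)
  if (nrow(cand) == 0) return(cand)
  xyz <- model_xyz(model)
  d <- sqrt(rowSums((xyz[cand[, 1], , drop = FALSE] -
                     xyz[cand[, 2], , drop = FALSE])^2))
  el_i <- a$element[cand[, 1]]; el_j <- a$element[cand[, 2]]
  aus <- (el_i == "Au" & el_j == "S") | (el_i == "S" & el_j == "Au")
  auau <- el_i == "Au" & el_j == "Au"
  cut <- ifelse(aus, au_s_cutoff, scale * (rc[cand[, 1]] + rc[cand[, 2]]))
  keep <- !auau & d <= cut
  cand[keep, , drop = FALSE]
}

# connected components of the bond graph -> molecule ids (in first-atom order)
molecules_from_bonds <- function(n_atoms, bonds) {
  parent <- seq_len(n_atoms)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      ri <- find(bonds[k, 1]); rj <- find(bonds[k, 2])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n_atoms), find, integer(1))
  match(roots, unique(roots))
}

# default component heuristics when a file carries no tags: metals are core,
# counterions ION, water-like molecules SOLVENT, other organics OL
guess_components <- function(atoms) {
  comp <- rep("OL", nrow(atoms))
  comp[atoms$element == "Au"] <- "GOLD_CORE"
  comp[atoms$element %in% c("Na", "Cl") &
         !ave(rep(TRUE, nrow(atoms)), atoms$molecule_id,
              FUN = function(z) length(z) > 1)] <- "ION"
  for (m in unique(atoms$molecule_id)) {
    sel <- atoms$molecule_id == m
    el <- atoms$element[sel]
    if (all(el %in% c("O", "H")) && sum(sel) <= 3) comp[sel] <- "SOLVENT"
  }
  comp
}

# component <-> PDB residue-name dialect
.comp_to_resid <- c(GOLD_CORE = "AUC", OL = "MBA", PL = "PEP", DL = "DRG",
                    ION = "ION", SOLVENT = "HOH")
.resid_to_comp <- stats::setNames(names(.comp_to_resid), .comp_to_resid)

# run-length key=value helpers for the extended XYZ comment line
rle_encode <- function(v) {
  r <- rle(as.character(v))
  paste(sprintf("%d:%s", r$lengths, r$values), collapse = ",")
}

rle_decode <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  unlist(lapply(parts, function(p) rep(p[2], as.integer(p[1]))))
}

#' Read a structure file
#'
#' Supports XYZ (with the package's extended comment line carrying molecule
#' and component tags as key=value pairs), PDB (via bio3d; the molecule
#' partition comes from chain+residue records and component tags from the
#' residue-name dialect AUC/MBA/PEP/DRG/ION/HOH), GRO (nm converted to
#' Angstrom) and SDF (via ChemmineR, payload/ligand templates). When the
#' format carries no molecule records, the partition is inferred from
#' connectivity using covalent-radius bond detection, and component tags
#' from element/molecule heuristics.
#'
#' @param path file path.
#' @param format one of `"xyz"`, `"pdb"`, `"gro"`, `"sdf"`; default guesses
#'   from the file extension.
#' @param component optional component tag overriding the heuristics for all
#'   non-metal, non-ion atoms.
#' @return a [cluster_model()].
#' @export
read_structure <- function(path, format = NULL, component = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("xyz", "pdb", "gro", "sdf"))
  model <- switch(format,
    xyz = read_xyz(path),
    pdb = read_pdb_model(path),
    gro = read_gro(path),
    sdf = read_sdf_model(path))
  if (!is.null(component)) {
    sel <- !(model$atoms$component %in% c("GOLD_CORE", "ION", "SOLVENT"))
    model$atoms$component[sel] <- check_component(component)
  }
  model
}

read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("parse error in ", path, ": empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("parse error in ", path, " at line 1: expected atom count")
  if (length(lines) < n + 2) stop("parse error in ", path,
                                  ": fewer atom lines than declared")
  comment <- if (length(lines) >= 2) lines[2] else ""
  atoms <- if (n > 0) {
    toks <- strsplit(trimws(lines[3:(n + 2)]), "[[:space:]]+")
    bad <- which(vapply(toks, length, integer(1)) < 4)
    if (length(bad) > 0) stop("parse error in ", path, " at line ",
                              bad[1] + 2, ": expected 'El x y z'")
    data.frame(
      element = vapply(toks, `[`, "", 1),
      x = as.numeric(vapply(toks, `[`, "", 2)),
      y = as.numeric(vapply(toks, `[`, "", 3)),
      z = as.numeric(vapply(toks, `[`, "", 4)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(element = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), stringsAsFactors = FALSE)
  }
  # extended comment: key=value tokens (mol=, comp=, box=)
  kv <- list()
  for (tok in strsplit(trimws(comment), "[[:space:]]+")[[1]]) {
    if (grepl("=", tok, fixed = TRUE)) {
      p <- strsplit(tok, "=", fixed = TRUE)[[1]]
      kv[[p[1]]] <- p[2]
    }
  }
  if (!is.null(kv$mol) && n > 0) {
    atoms$molecule_id <- as.integer(rle_decode(kv$mol))
    atoms$component <- if (!is.null(kv$comp)) rle_decode(kv$comp) else NA
  } else if (n > 0) {
    tmp <- data.frame(atoms, molecule_id = 1L, component = "OL")
    m0 <- cluster_model(tmp)
    b <- detect_bonds(m0)
    atoms$molecule_id <- molecules_from_bonds(n, b)
  }
  if (n > 0 && (is.null(atoms$component) || anyNA(atoms$component))) {
    atoms$component <- guess_components(atoms)
  }
  if (n == 0) {
    atoms$molecule_id <- integer(0)
    atoms$component <- character(0)
  }
  box <- if (!is.null(kv$box)) as.numeric(strsplit(kv$box, ",")[[1]]) else NULL
  m <- cluster_model(atoms, provenance = paste("read from", basename(path)))
  m$box <- box
  m
}

read_pdb_model <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  el <- a$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el)))) {
    el <- gsub("[0-9'\"]", "", trimws(a$elety))
    el <- substr(el, 1, 2)
    el[!is_known_element_safe(el)] <- substr(el[!is_known_element_safe(el)], 1, 1)
  }
  key <- paste(a$chain, a$resno, sep = "|")
  atoms <- data.frame(
    element = trimws(el),
    x = a$x, y = a$y, z = a$z,
    molecule_id = match(key, unique(key)),
    component = NA_character_,
    resid = a$resid,
    stringsAsFactors = FALSE)
  comp <- .resid_to_comp[a$resid]
  atoms$component <- ifelse(is.na(comp), NA, comp)
  if (anyNA(atoms$component)) {
    guessed <- guess_components(atoms)
    atoms$component[is.na(atoms$component)] <- guessed[is.na(atoms$component)]
  }
  cluster_model(atoms, provenance = paste("read from", basename(path)))
}

is_known_element_safe <- function(el) {
  ok <- logical(length(el))
  for (i in seq_along(el)) {
    ok[i] <- nzchar(trimws(el[i])) &&
      normalize_element(el[i]) %in% .element_table$symbol
  }
  ok
}

read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("parse error in ", path, ": truncated GRO file")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("parse error in ", path, " at line 2: expected atom count")
  if (length(lines) < n + 3) stop("parse error in ", path,
                                  ": fewer atom lines than declared")
  at <- lines[seq_len(n) + 2]
  resno <- as.integer(substr(at, 1, 5))
  resnm <- trimws(substr(at, 6, 10))
  atnm <- trimws(substr(at, 11, 15))
  x <- as.numeric(substr(at, 21, 28)) * 10  # nm -> Angstrom
  y <- as.numeric(substr(at, 29, 36)) * 10
  z <- as.numeric(substr(at, 37, 44)) * 10
  el <- gsub("[0-9]", "", atnm)
  el <- ifelse(is_known_element_safe(substr(el, 1, 2)), substr(el, 1, 2),
               substr(el, 1, 1))
  comp <- .resid_to_comp[resnm]
  atoms <- data.frame(element = el, x = x, y = y, z = z,
                      molecule_id = match(resno, unique(resno)),
                      component = ifelse(is.na(comp), NA, comp),
                      resid = resnm, stringsAsFactors = FALSE)
  if (anyNA(atoms$component)) {
    guessed <- guess_components(atoms)
    atoms$component[is.na(atoms$component)] <- guessed[is.na(atoms$component)]
  }
  m <- cluster_model(atoms, provenance = paste("read from", basename(path)))
  bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]),
                                             "[[:space:]]+")[[1]]))
  if (length(bx) >= 3 && !anyNA(bx[1:3])) m$box <- bx[1:3] * 10
  m
}

read_sdf_model <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  ab <- ChemmineR::atomblock(sdf[[1]])
  el <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      molecule_id = 1L, component = "OL",
                      stringsAsFactors = FALSE)
  bb <- ChemmineR::bondblock(sdf[[1]])
  bonds <- if (nrow(bb) > 0) cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
           else matrix(integer(0), 0, 2)
  atoms$component <- guess_components(atoms)
  cluster_model(atoms, bonds = bonds,
                provenance = paste("read from", basename(path)))
}

#' Write a structure file
#'
#' Inverse of [read_structure()] for XYZ, PDB and GRO. XYZ output carries the
#' molecule partition, component tags and any box vector on the extended
#' comment line; PDB encodes components through the residue-name dialect and
#' writes Angstrom; GRO converts to nm.
#'
#' @param model a [cluster_model()].
#' @param path output file path.
#' @param format one of `"xyz"`, `"pdb"`, `"gro"`; default guesses from the
#'   extension.
#' @return invisibly, `path`.
#' @export
write_structure <- function(model, path, format = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("xyz", "pdb", "gro"))
  a <- model$atoms
  switch(format,
    xyz = {
      kv <- sprintf("mol=%s comp=%s", rle_encode(a$molecule_id),
                    rle_encode(a$component))
      if (!is.null(model$box)) {
        kv <- paste0(kv, sprintf(" box=%g,%g,%g", model$box[1], model$box[2],
                                 model$box[3]))
      }
      lines <- c(sprintf("%d", nrow(a)), paste("aushell", kv))
      if (nrow(a) > 0) {
        lines <- c(lines, sprintf("%-3s %14.6f %14.6f %14.6f",
                                  a$element, a$x, a$y, a$z))
      }
      writeLines(lines, path)
    },
    pdb = {
      if (nrow(a) > 99999) stop("PDB format cannot hold ", nrow(a),
                                " atoms (max 99999)")
      if (nrow(a) == 0) {
        writeLines("END", path)
      } else {
        resid <- .comp_to_resid[a$component]
        name <- make_atom_names(a)
        n <- nrow(a)
        suppressWarnings(bio3d::write.pdb(
          file = path,
          xyz = as.numeric(t(model_xyz(model))),
          resno = a$molecule_id, resid = resid, chain = rep("A", n),
          elety = name, elesy = a$element, o = rep(1, n), b = rep(0, n)))
      }
    },
    gro = {
      if (nrow(a) > 99999) stop("GRO format cannot hold ", nrow(a),
                                " atoms (max 99999)")
      resid <- .comp_to_resid[a$component]
      name <- make_atom_names(a)
      lines <- c("aushell model", sprintf("%5d", nrow(a)))
      if (nrow(a) > 0) {
        lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                                  a$molecule_id %% 100000L, resid,
                                  substr(name, 1, 5),
                                  seq_len(nrow(a)) %% 100000L,
                                  a$x / 10, a$y / 10, a$z / 10))
      }
      bx <- if (!is.null(model$box)) model$box / 10 else c(0, 0, 0)
      lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", bx[1], bx[2], bx[3]))
      writeLines(lines, path)
    })
  invisible(path)
}

# per-molecule element counters -> unique short atom names (e.g. C1, C2)
make_atom_names <- function(a) {
  nm <- character(nrow(a))
  for (m in unique(a$molecule_id)) {
    sel <- which(a$molecule_id == m)
    el <- a$element[sel]
    cnt <- stats::ave(seq_along(el), el, FUN = seq_along)
    nm[sel] <- paste0(toupper(el), cnt)
  }
  substr(nm, 1, 4)
}

#' Detect RS-Au-SR protective units (staples)
#'
#' A protective unit is a gold adatom bridging exactly two thiolate sulfurs.
#' Detection is geometric: a gold atom is an apex candidate when exactly two
#' sulfur atoms lie within `au_s_cutoff`, each sulfur belonging to a
#' thiolate ligand molecule (a molecule that is not the metal itself). Each
#' sulfur may belong to at most one unit; a sulfur claimed by two apex
#' candidates indicates malformed geometry and raises an error listing the
#' conflict. Units are returned ordered by apex gold index.
#'
#' @param model a [cluster_model()].
#' @param au_s_cutoff Au-S bond cutoff in Angstrom (default 2.6).
#' @return a list of staple units, each a list with `apex_gold` (atom index),
#'   `sulfurs` (two atom indices), `ligands` (two molecule ids) and
#'   `replaced` (two logicals, initially FALSE).
#' @export
detect_protective_units <- function(model, au_s_cutoff = 2.6) {
  a <- model$atoms
  au <- which(a$element == "Au")
  s <- which(a$element == "S")
  if (length(s) == 0 || length(au) == 0) return(list())
  xyz_au <- model_xyz(model, au)
  xyz_s <- model_xyz(model, s)
  # sulfur neighbors within cutoff for every gold atom
  d2 <- outer(rowSums(xyz_au^2), rowSums(xyz_s^2), "+") -
    2 * xyz_au %*% t(xyz_s)
  nb <- d2 <= au_s_cutoff^2 + 1e-9
  # thiolate sulfurs: molecule contains no gold atoms
  metal_mols <- unique(a$molecule_id[au])
  is_thiolate <- !(a$molecule_id[s] %in% metal_mols)
  cand <- which(rowSums(nb[, is_thiolate, drop = FALSE]) == 2 &
                rowSums(nb) == 2)
  units <- list()
  claimed <- integer(0)
  for (i in cand) {
    s_idx <- s[which(nb[i, ])]
    m <- a$molecule_id[s_idx]
    if (m[1] == m[2]) next  # both sulfurs on one molecule: not a staple
    clash <- intersect(s_idx, claimed)
    if (length(clash) > 0) {
      stop("malformed geometry: sulfur atom(s) ",
           paste(clash, collapse = ", "),
           " shared by two candidate apex gold atoms (including atom ",
           au[i], ")")
    }
    claimed <- c(claimed, s_idx)
    units[[length(units) + 1]] <- list(
      apex_gold = au[i],
      sulfurs = sort(s_idx),
      ligands = a$molecule_id[sort(s_idx)],
      replaced = c(FALSE, FALSE))
  }
  units[order(vapply(units, `[[`, integer(1), "apex_gold"))]
}

# icosahedron vertex directions (unit vectors), deterministic orientation
icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(1 + phi^2)
}

icosahedron_edges <- function(v) {
  # edges connect vertices at the minimal pairwise distance
  d <- as.matrix(stats::dist(v))
  mind <- min(d[d > 1e-9])
  which(d <= mind + 1e-6 & upper.tri(d), arr.ind = TRUE)
}

icosahedron_faces <- function(v, edges) {
  adj <- matrix(FALSE, nrow(v), nrow(v))
  adj[edges] <- TRUE
  adj <- adj | t(adj)
  faces <- NULL
  for (i in seq_len(nrow(v))) {
    for (j in which(adj[i, ] & seq_len(nrow(v)) > i)) {
      for (k in which(adj[j, ] & adj[i, ] & seq_len(nrow(v)) > j)) {
        faces <- rbind(faces, c(i, j, k))
      }
    }
  }
  faces
}

# 114-atom icosahedral core: 12 @ r1, 42 @ r2 (vertices + edge midpoints),
# 60 @ r3 (face orbit), radii from typical Au144(SR)60 geometries
icosahedral_core_114 <- function(r1 = 2.80, r2 = 5.40, r3 = 6.90,
                                 face_lambda = 0.22) {
  v <- icosahedron_vertices()
  edges <- icosahedron_edges(v)
  mids <- t(apply(edges, 1, function(e) unit(v[e[1], ] + v[e[2], ])))
  faces <- icosahedron_faces(v, edges)
  fo <- NULL
  for (f in seq_len(nrow(faces))) {
    tri <- faces[f, ]
    for (corner in tri) {
      others <- setdiff(tri, corner)
      p <- (1 - 2 * face_lambda) * v[corner, ] +
        face_lambda * (v[others[1], ] + v[others[2], ])
      fo <- rbind(fo, unit(p))
    }
  }
  rbind(r1 * v, r2 * v, r2 * mids, r3 * fo)
}

# generic quasi-uniform shells for non-default gold counts
fibonacci_core <- function(n_core, spacing = 2.85) {
  if (n_core == 0) return(matrix(numeric(0), 0, 3))
  pts <- matrix(numeric(0), 0, 3)
  if (n_core %% 2 == 1 || n_core < 12) {
    pts <- rbind(pts, c(0, 0, 0))
  }
  k <- 1
  while (nrow(pts) < n_core) {
    r <- k * spacing
    cap <- max(12, round(4 * pi * r^2 / (spacing^2 * 0.95)))
    take <- min(cap, n_core - nrow(pts))
    pts <- rbind(pts, r * sphere_points(take))
    k <- k + 1
  }
  pts
}

#' Generate the idealized reference cluster
#'
#' Builds an idealized, icosahedrally symmetric model of a thiolate-protected
#' gold cluster: a layered metal core decorated with RS-Au-SR protective
#' units whose two thiolate ligands point radially outward. The default
#' yields the Au144(p-MBA)60 reference composition: a 114-atom three-shell
#' icosahedral core plus 30 staple gold adatoms (144 gold total) carrying 60
#' p-MBA ligands in 30 two-ligand units. This is a geometric idealization
#' with literature-typical shell radii, not a DFT-optimized structure.
#'
#' @param n_gold total gold atoms including staple adatoms (default 144).
#' @param n_ligands number of thiolate ligands, two per unit (default 60;
#'   must be even, with `n_gold >= n_ligands / 2`).
#' @param ligand a [ligand_template()] for the thiolates (default
#'   [pmba_template()]).
#' @param d_min minimum allowed inter-molecular distance in Angstrom used in
#'   the construction's own clash scan (default 1.75).
#' @return a [cluster_model()] with staples attached and component tags
#'   GOLD_CORE / OL.
#' @export
generate_reference_cluster <- function(n_gold = 144, n_ligands = 60,
                                       ligand = pmba_template(),
                                       d_min = 1.75) {
  if (n_ligands %% 2 != 0) stop("n_ligands must be even (two per unit)")
  n_units <- n_ligands / 2
  if (n_gold < n_units) stop("n_gold (", n_gold,
                             ") must be at least n_ligands/2 (", n_units, ")")
  n_core <- n_gold - n_units
  icosa <- n_core == 114 && n_units == 30
  core <- if (icosa) icosahedral_core_114() else fibonacci_core(n_core)
  atoms <- data.frame(element = rep("Au", nrow(core)),
                      x = core[, 1], y = core[, 2], z = core[, 3],
                      molecule_id = 1L, component = "GOLD_CORE",
                      stringsAsFactors = FALSE)
  if (n_units > 0) {
    if (icosa) {
      atoms <- decorate_icosahedral(atoms, ligand, d_min = d_min)
    } else {
      r_out <- if (nrow(core) > 0) max(sqrt(rowSums(core^2))) else 0
      apex_dir <- sphere_points(n_units)
      apex_tan <- t(apply(apex_dir, 1, function(u) {
        ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        unit(cross3(u, ref))
      }))
      atoms <- decorate_with_staples(atoms, apex_dir, apex_tan,
                                     r_out + 2.4, ligand)
    }
  }
  model <- cluster_model(atoms, provenance = sprintf(
    "idealized reference cluster: %d Au, %d thiolates, %d units",
    n_gold, n_ligands, n_units))
  if (n_units > 0) {
    gap <- reference_min_intermolecular(model)
    if (gap < d_min) {
      stop("infeasible decoration: clash-free placement failed ",
           sprintf("(min inter-molecular non-bonded distance %.2f < %.2f)",
                   gap, d_min))
    }
    model$staples <- detect_protective_units(model)
  } else {
    model$staples <- list()
  }
  model
}

# The 60 proper rotations of the icosahedron defined by
# icosahedron_vertices(), generated by closure from a C5 vertex axis and a
# C2 edge axis. Keys are rounded integer matrices so -0/in-tolerance
# duplicates collapse.
ico_rotation_group <- function() {
  v <- icosahedron_vertices()
  edges <- icosahedron_edges(v)
  g1 <- rotation_matrix(v[1, ], 72)
  g2 <- rotation_matrix(unit(v[edges[1, 1], ] + v[edges[1, 2], ]), 180)
  key <- function(R) paste(as.integer(round(R * 1e4)), collapse = ",")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  els <- list(diag(3))
  assign(key(diag(3)), TRUE, envir = seen)
  queue <- els
  while (length(queue) > 0) {
    R <- queue[[1]]
    queue <- queue[-1]
    for (g in list(g1, g2)) {
      Rn <- g %*% R
      k <- key(Rn)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        els[[length(els) + 1]] <- Rn
        queue[[length(queue) + 1]] <- Rn
      }
    }
  }
  els
}

# Symmetric decoration of the 114-atom icosahedral core: one generating
# RS-Au-SR unit is made C2-symmetric about its apex axis and replicated over
# the 30 staple sites by the icosahedral rotation group, so every ligand has
# a congruent environment and the whole-shell clearance equals the
# generating ligand's clearance. The generator orientation (staple tangent
# angle psi, ligand cone tilt/azimuth, ring spin) is found by the same rule
# the ligand-exchange placement uses: scan orientations from the natural
# radial direction outward and accept the first whose clearance satisfies
# d_min. `params`, when given, short-circuits the scan with a known-good
# orientation (it is still verified before use).
decorate_icosahedral <- function(atoms, ligand, r_apex = 8.30, b_sau = 2.33,
                                 tilt_deg = 7.5, d_min = 1.75,
                                 params = c(psi = 165, ta = 10, az = 300,
                                            spin = 60)) {
  v <- icosahedron_vertices()
  edges <- icosahedron_edges(v)
  u0 <- unit(v[edges[1, 1], ] + v[edges[1, 2], ])
  t0 <- unit(v[edges[1, 2], ] - v[edges[1, 1], ])
  G <- ico_rotation_group()
  reps <- list()
  apexes <- NULL
  for (R in G) {
    a <- as.numeric(R %*% u0)
    if (is.null(apexes) || min(colSums((t(apexes) - a)^2)) > 1e-6) {
      apexes <- rbind(apexes, a)
      reps[[length(reps) + 1]] <- R
    }
  }
  core_xyz <- cbind(atoms$x, atoms$y, atoms$z)
  lig_el <- ligand$atoms$element
  tilt <- tilt_deg * pi / 180
  C2 <- rotation_matrix(u0, 180)
  build <- function(psi, ta, az, spin) {
    w <- unit(cross3(u0, t0))
    tv <- cos(psi * pi / 180) * t0 + sin(psi * pi / 180) * w
    apex <- r_apex * u0
    s1 <- apex + b_sau * (cos(tilt) * tv - sin(tilt) * u0)
    radial <- unit(s1)
    dd <- if (ta == 0) radial else as.numeric(rotate_about(
      matrix(radial, 1), c(0, 0, 0),
      cos(az * pi / 180) * tv + sin(az * pi / 180) * unit(cross3(radial, tv)),
      ta))
    at <- instantiate_ligand(ligand, s1, dd, ref_tangent = tv)
    l1 <- rotate_about(cbind(at$x, at$y, at$z), s1, dd, spin)
    list(l1 = l1, pair = rbind(l1, l1 %*% t(C2)))
  }
  clearance <- function(sh) {
    all_lig <- do.call(rbind, lapply(reps, function(R) sh$pair %*% t(R)))
    n1 <- nrow(sh$l1)
    other <- rbind(core_xyz, apexes * r_apex,
                   all_lig[-seq_len(n1), , drop = FALSE])
    s_rows <- which(lig_el == "S")
    # Gold contacts of the anchor sulfur, mirroring the real staple motif:
    # the bonded apex (row nrow(core_xyz) + 1 of `other`) is exempt; the
    # sulfur may additionally bridge its nearest core gold at >= d_min (the
    # staple's surface anchoring bond), but every further gold atom must
    # stay beyond the Au-S detection cutoff, and the bridged core gold may
    # carry no other sulfur -- otherwise unit detection is ambiguous.
    n_au <- nrow(core_xyz) + nrow(apexes)
    cutoff_au <- 2.6 + 0.05
    s_xyz <- sh$l1[s_rows[1], ]
    d_core <- sqrt(colSums((t(core_xyz) - s_xyz)^2))
    d_apex <- sqrt(colSums((t(apexes * r_apex) - s_xyz)^2))[-1]
    nearest <- which.min(d_core)
    ok_au <- min(d_apex) >= cutoff_au &&
      sort(d_core)[2] >= cutoff_au && d_core[nearest] >= d_min
    if (ok_au && d_core[nearest] < cutoff_au) {
      # injectivity: no other sulfur within the cutoff of the bridged gold
      other_s <- all_lig[-seq_len(n1), , drop = FALSE][
        rep(lig_el, 2 * length(reps))[-seq_len(n1)] == "S", , drop = FALSE]
      ok_au <- min_cross_distance(matrix(core_xyz[nearest, ], 1),
                                  other_s) >= cutoff_au
    }
    other_nonau <- other[-seq_len(n_au), , drop = FALSE]
    min(min_cross_distance(sh$l1[-s_rows, , drop = FALSE], other),
        min_cross_distance(sh$l1[s_rows, , drop = FALSE], other_nonau),
        if (ok_au) Inf else -Inf)
  }
  sh <- NULL
  if (!is.null(params)) {
    cand <- build(params["psi"], params["ta"], params["az"], params["spin"])
    if (clearance(cand) >= d_min) sh <- cand
  }
  if (is.null(sh)) {
    # radial-first scan: the smallest cone tilt admitting a clash-free
    # shell wins (maximal outreach from the surface); among orientations at
    # that tilt, the most open packing (maximal clearance) is taken
    best_sc <- -Inf
    for (ta in c(0, 10, 20, 30)) {
      ta_best <- NULL
      for (psi in seq(0, 165, by = 15)) {
        for (az in if (ta == 0) 0 else seq(0, 330, by = 30)) {
          for (spin in seq(0, 345, by = 15)) {
            cand <- build(psi, ta, az, spin)
            sc <- clearance(cand)
            if (sc > best_sc) best_sc <- sc
            if (is.null(ta_best) || sc > ta_best$sc) {
              ta_best <- list(sc = sc, sh = cand)
            }
          }
        }
      }
      if (ta_best$sc >= d_min) {
        sh <- ta_best$sh
        break
      }
    }
    if (is.null(sh)) {
      stop("infeasible decoration: no clash-free symmetric shell ",
           sprintf("orientation found (best clearance %.2f < %.2f)",
                   best_sc, d_min))
    }
  }
  next_mol <- max(atoms$molecule_id) + 1L
  for (k in seq_along(reps)) {
    R <- reps[[k]]
    apex <- as.numeric(R %*% (r_apex * u0))
    atoms <- rbind(atoms, data.frame(
      element = "Au", x = apex[1], y = apex[2], z = apex[3],
      molecule_id = atoms$molecule_id[1], component = "GOLD_CORE",
      stringsAsFactors = FALSE))
    pair <- sh$pair %*% t(R)
    n1 <- nrow(sh$l1)
    for (side in 1:2) {
      rows <- if (side == 1) seq_len(n1) else n1 + seq_len(n1)
      atoms <- rbind(atoms, data.frame(
        element = lig_el, x = pair[rows, 1], y = pair[rows, 2],
        z = pair[rows, 3], molecule_id = next_mol,
        component = ligand$component, stringsAsFactors = FALSE))
      next_mol <- next_mol + 1L
    }
  }
  atoms
}

# Decorate a gold core with RS-Au-SR units. The apex positions are fixed by
# the (Fibonacci) frame; the remaining orientational freedoms (the staple
# tangent within its tangent plane, each ligand's outward direction within a
# small cone around the radial, and each ligand's spin about its axis) are
# chosen by a deterministic greedy grid search that maximizes the clearance
# to everything already placed -- the same first-spatially-open-orientation
# philosophy the ligand-exchange builder uses. Au-S contacts are exempt from
# the clearance score (thiolate sulfurs anchor to gold by construction).
decorate_with_staples <- function(atoms, apex_dir, apex_tan, r_apex, ligand,
                                  b_sau = 2.33, tilt_deg = 7.5) {
  tilt <- tilt_deg * pi / 180
  next_mol <- max(atoms$molecule_id) + 1L
  env_xyz <- cbind(atoms$x, atoms$y, atoms$z)
  env_el <- atoms$element
  reach <- template_outreach(ligand) + 4
  # clearance of candidate atoms against the local environment, Au-S exempt
  clearance <- function(cand_xyz, cand_el, center, cap = Inf) {
    near <- rowSums(sweep(env_xyz, 2, center)^2) <= reach^2
    exyz <- env_xyz[near, , drop = FALSE]
    eel <- env_el[near]
    d <- min_cross_distance(cand_xyz[cand_el != "S", , drop = FALSE], exyz)
    d_s <- min_cross_distance(cand_xyz[cand_el == "S", , drop = FALSE],
                              exyz[eel != "Au", , drop = FALSE])
    min(d, d_s, cap)
  }
  psi_grid <- seq(0, 150, by = 30)
  az_grid <- seq(0, 330, by = 30)
  spin_grid <- seq(0, 330, by = 30)
  lig_el <- ligand$atoms$element
  # greedily orient one ligand anchored at s_pos: outward direction within a
  # cone around the radial, then spin about the chosen axis
  orient_ligand <- function(s_pos, tv, extra_xyz) {
    radial <- unit(s_pos)
    perp <- unit(cross3(radial, tv))
    dirs <- list(radial)
    for (ta in c(10, 20)) {
      for (az in az_grid) {
        d0 <- rotate_about(matrix(radial, 1), c(0, 0, 0),
                           cos(az * pi / 180) * tv +
                             sin(az * pi / 180) * perp, ta)
        dirs[[length(dirs) + 1]] <- as.numeric(d0)
      }
    }
    best_dir <- NULL; best_d <- -Inf
    for (dd in dirs) {
      at <- instantiate_ligand(ligand, s_pos, dd, ref_tangent = tv)
      lx <- cbind(at$x, at$y, at$z)
      d <- min(clearance(lx, lig_el, s_pos),
               min_cross_distance(lx, extra_xyz))
      if (d > best_d) {
        best_d <- d
        best_dir <- dd
      }
    }
    at <- instantiate_ligand(ligand, s_pos, best_dir, ref_tangent = tv)
    base <- cbind(at$x, at$y, at$z)
    best_xyz <- base; best_d <- -Inf
    for (sp in spin_grid) {
      lx <- rotate_about(base, s_pos, best_dir, sp)
      d <- min(clearance(lx, lig_el, s_pos),
               min_cross_distance(lx, extra_xyz))
      if (d > best_d) {
        best_d <- d
        best_xyz <- lx
      }
    }
    list(xyz = best_xyz, score = best_d)
  }
  for (k in seq_len(nrow(apex_dir))) {
    u <- apex_dir[k, ]
    t0 <- apex_tan[k, ]
    w <- unit(cross3(u, t0))
    apex <- r_apex * u
    best <- NULL
    for (psi in psi_grid) {
      tv <- cos(psi * pi / 180) * t0 + sin(psi * pi / 180) * w
      s_pair <- lapply(c(-1, 1), function(sgn) {
        apex + b_sau * (sgn * cos(tilt) * tv - sin(tilt) * u)
      })
      l1 <- orient_ligand(s_pair[[1]], tv,
                          rbind(matrix(apex, 1), matrix(s_pair[[2]], 1)))
      l2 <- orient_ligand(s_pair[[2]], tv, rbind(matrix(apex, 1), l1$xyz))
      score <- min(l1$score, l2$score)
      if (is.null(best) || score > best$score) {
        best <- list(score = score, xyz = list(l1$xyz, l2$xyz))
      }
    }
    atoms <- rbind(atoms, data.frame(
      element = "Au", x = apex[1], y = apex[2], z = apex[3],
      molecule_id = atoms$molecule_id[1], component = "GOLD_CORE",
      stringsAsFactors = FALSE))
    env_xyz <- rbind(env_xyz, matrix(apex, 1))
    env_el <- c(env_el, "Au")
    for (side in 1:2) {
      lx <- best$xyz[[side]]
      atoms <- rbind(atoms, data.frame(
        element = lig_el, x = lx[, 1], y = lx[, 2], z = lx[, 3],
        molecule_id = next_mol, component = ligand$component,
        stringsAsFactors = FALSE))
      env_xyz <- rbind(env_xyz, lx)
      env_el <- c(env_el, lig_el)
      next_mol <- next_mol + 1L
    }
  }
  atoms
}

# minimum inter-molecular distance over the whole model, exempting the
# bonded S-Au anchor contacts (which are inter-molecular by construction)
reference_min_intermolecular <- function(model, exempt_au_s = TRUE) {
  a <- model$atoms
  xyz <- model_xyz(model)
  p <- pairs_within(xyz, 4.0)
  if (nrow(p) == 0) return(Inf)
  inter <- a$molecule_id[p[, 1]] != a$molecule_id[p[, 2]]
  p <- p[inter, , drop = FALSE]
  if (exempt_au_s) {
    aus <- (a$element[p[, 1]] == "Au" & a$element[p[, 2]] == "S") |
      (a$element[p[, 1]] == "S" & a$element[p[, 2]] == "Au")
    p <- p[!aus, , drop = FALSE]
  }
  if (nrow(p) == 0) return(Inf)
  min(sqrt(rowSums((xyz[p[, 1], , drop = FALSE] -
                    xyz[p[, 2], , drop = FALSE])^2)))
}

# place a ligand template: anchor sulfur at s_pos, S->C axis along axis_dir,
# remaining orientation fixed by ref_tangent for determinism
instantiate_ligand <- function(template, s_pos, axis_dir,
                               ref_tangent = NULL) {
  xyz <- cbind(template$atoms$x, template$atoms$y, template$atoms$z)
  anchor <- xyz[template$anchor_sulfur, ]
  xyz <- sweep(xyz, 2, anchor)
  local_axis <- unit(xyz[template$axis_carbon, ])
  R <- align_rotation(local_axis, axis_dir)
  xyz <- xyz %*% t(R)
  if (!is.null(ref_tangent)) {
    # spin about the new axis so the template's local +x maps toward the
    # reference tangent (deterministic ring orientation)
    perp <- ref_tangent - sum(ref_tangent * axis_dir) * axis_dir
    if (vec_norm(perp) > 1e-8) {
      cur <- as.numeric(R %*% c(1, 0, 0))
      cur <- cur - sum(cur * axis_dir) * axis_dir
      if (vec_norm(cur) > 1e-8) {
        ang <- atan2(sum(cross3(unit(cur), unit(perp)) * axis_dir),
                     sum(unit(cur) * unit(perp))) * 180 / pi
        xyz <- xyz %*% t(rotation_matrix(axis_dir, ang))
      }
    }
  }
  xyz <- sweep(xyz, 2, s_pos, "+")
  data.frame(element = template$atoms$element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             molecule_id = NA_integer_, component = template$component,
             stringsAsFactors = FALSE)
}

#' Metal-core diameter
#'
#' Maximum pairwise Au-Au distance, reported in nm.
#'
#' @param model a [cluster_model()] with at least two gold atoms.
#' @return diameter in nm.
#' @export
core_diameter <- function(model) {
  au <- which(model$atoms$element == "Au")
  if (length(au) < 2) stop("core_diameter needs at least 2 gold atoms, found ",
                           length(au))
  xyz <- model_xyz(model, au)
  max(stats::dist(xyz)) / 10
}
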