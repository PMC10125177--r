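# Incoming-ligand construction: PEG thiol linkers, amide conjugation of
# peptide/drug payloads (EDC/NHS-style coupling as a pure bond-topology
# operation), and elongated conformer generation.
#
# Templates live in a local frame: anchor sulfur at the origin, the first
# carbon (the S-C sampling axis used by the builder) along +z.

# idealized geometry constants, Angstrom / degrees
.geom <- list(
  b_SC = 1.82, b_SC_ar = 1.78, b_SH = 1.34, b_CC = 1.54, b_CC_ar = 1.39,
  b_CO = 1.43, b_C_dblO = 1.23, b_CO_acid = 1.36, b_CN_amide = 1.33,
  b_CN = 1.47, b_CH = 1.09, b_NH = 1.01, b_OH = 0.96,
  ang_tet = 109.47, ang_trig = 120, ang_HCH = 107.8)

#' Construct a ligand template
#'
#' @param atoms data.frame with `element`, `x`, `y`, `z` (Angstrom, local
#'   frame).
#' @param bonds 2-column integer matrix of bonded atom indices.
#' @param anchor_sulfur index of the anchoring thiolate sulfur.
#' @param axis_carbon index of the first carbon bonded to the anchor sulfur
#'   (defines the S-C rotational sampling axis).
#' @param rotatable_bonds ordered 2-column matrix of bonds whose dihedrals
#'   [elongate_conformer()] may adjust; must be acyclic in the bond graph.
#' @param component one of `"OL"`, `"PL"`, `"DL"`.
#' @param name label.
#' @return an object of class `ligand_template`.
#' @export
ligand_template <- function(atoms, bonds, anchor_sulfur, axis_carbon,
                            rotatable_bonds = matrix(integer(0), 0, 2),
                            component = "OL", name = "ligand") {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in%
                                        names(atoms)))
  atoms$element <- normalize_element(atoms$element)
  if (atoms$element[anchor_sulfur] != "S") {
    stop("anchor_sulfur (atom ", anchor_sulfur, ") is ",
         atoms$element[anchor_sulfur], ", not S")
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  if (!(paste(min(anchor_sulfur, axis_carbon),
              max(anchor_sulfur, axis_carbon)) %in% key)) {
    stop("axis_carbon must be bonded to anchor_sulfur")
  }
  rotatable_bonds <- matrix(as.integer(rotatable_bonds), ncol = 2)
  if (!(component %in% c("OL", "PL", "DL"))) {
    stop("component must be OL, PL or DL")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms[c("element", "x", "y", "z")], bonds = bonds,
                 anchor_sulfur = as.integer(anchor_sulfur),
                 axis_carbon = as.integer(axis_carbon),
                 rotatable_bonds = rotatable_bonds,
                 component = component, name = name),
            class = "ligand_template")
}

#' @export
print.ligand_template <- function(x, ...) {
  cat(sprintf("ligand_template '%s' (%s): %d atoms (%d heavy), %d rotatable bonds\n",
              x$name, x$component, nrow(x$atoms),
              sum(x$atoms$element != "H"), nrow(x$rotatable_bonds)))
  cat(sprintf("  anchor S = atom %d, axis C = atom %d, outreach %.2f A\n",
              x$anchor_sulfur, x$axis_carbon, template_outreach(x)))
  invisible(x)
}

template_xyz <- function(t) cbind(t$atoms$x, t$atoms$y, t$atoms$z)

# anchor-sulfur-to-farthest-atom distance, Angstrom
template_outreach <- function(t) {
  xyz <- template_xyz(t)
  max(sqrt(rowSums(sweep(xyz, 2, xyz[t$anchor_sulfur, ])^2)))
}

# adjacency list from a bond matrix
bond_neighbors <- function(bonds, n) {
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(v) sort(unique(v)))
}

# atoms on the far side of bond i-j (connected to j with the bond removed)
distal_atoms <- function(bonds, n, i, j) {
  nb <- bond_neighbors(bonds, n)
  seen <- rep(FALSE, n)
  seen[i] <- TRUE
  queue <- j
  seen[j] <- TRUE
  while (length(queue) > 0) {
    a <- queue[1]; queue <- queue[-1]
    for (b in nb[[a]]) {
      if (!seen[b]) {
        seen[b] <- TRUE
        queue <- c(queue, b)
      }
    }
  }
  out <- which(seen)
  setdiff(out, i)
}

# --- internal chain builder -------------------------------------------------

# Grows a molecule atom-by-atom with NeRF placement. `ref` indices pick the
# three reference atoms (a = bonded neighbor, then b, then c).
new_molbuild <- function() {
  env <- new.env(parent = emptyenv())
  env$el <- character(0)
  env$xyz <- matrix(numeric(0), 0, 3)
  env$bonds <- matrix(integer(0), 0, 2)
  env
}

mb_add <- function(mb, element, pos, bond_to = NULL) {
  mb$el <- c(mb$el, element)
  mb$xyz <- rbind(mb$xyz, pos)
  i <- length(mb$el)
  if (!is.null(bond_to)) mb$bonds <- rbind(mb$bonds, c(bond_to, i))
  i
}

mb_place <- function(mb, element, a, b, c, bond, angle, dihedral) {
  pos <- place_atom(mb$xyz[a, ], mb$xyz[b, ], mb$xyz[c, ], bond, angle,
                    dihedral)
  mb_add(mb, element, pos, bond_to = a)
}

mb_atoms <- function(mb) {
  data.frame(element = mb$el, x = mb$xyz[, 1], y = mb$xyz[, 2],
             z = mb$xyz[, 3], stringsAsFactors = FALSE)
}

# two hydrogens on a tetrahedral atom with two heavy neighbors
mb_add_h2 <- function(mb, i, nb1, nb2, b_XH = .geom$b_CH) {
  p <- mb$xyz[i, ]
  u1 <- unit(mb$xyz[nb1, ] - p)
  u2 <- unit(mb$xyz[nb2, ] - p)
  bis <- -unit(u1 + u2)
  w <- unit(cross3(u1, u2))
  half <- .geom$ang_HCH / 2 * pi / 180
  for (s in c(1, -1)) {
    mb_add(mb, "H", p + b_XH * (cos(half) * bis + s * sin(half) * w),
           bond_to = i)
  }
}

#' Build a PEG thiol linker template
#'
#' Constructs the thiol linker HS-(CH2)`alkyl_len`-(O-CH2-CH2)`n_eg`-O-CH2-
#' COOH with idealized bond lengths and angles and an all-anti backbone,
#' terminal carboxyl intact (protonated, ready for amide coupling). The
#' defaults of the study design are the long peptide linker
#' (`n_eg = 6, alkyl_len = 11`) and the short drug linker (`n_eg = 3`).
#' Backbone bonds are enumerated as rotatable.
#'
#' @param n_eg number of ethylene-glycol units (>= 0).
#' @param alkyl_len number of CH2 groups in the alkyl segment (>= 1).
#' @return a [ligand_template()] with component `"OL"` (unassigned until
#'   conjugation) whose heavy-atom count is `alkyl_len + 3 n_eg + 6`.
#' @export
make_peg_linker <- function(n_eg, alkyl_len = 11) {
  stopifnot(n_eg >= 0, alkyl_len >= 1)
  mb <- new_molbuild()
  s <- mb_add(mb, "S", c(0, 0, 0))
  c1 <- mb_add(mb, "C", c(0, 0, .geom$b_SC), bond_to = s)
  # virtual reference for the first placements
  backbone <- c(s, c1)
  seq_el <- c(rep("C", alkyl_len - 1),
              rep(c("O", "C", "C"), n_eg),
              "O", "C", "C")  # trailing C is the carboxyl carbon
  for (k in seq_along(seq_el)) {
    n <- length(backbone)
    a <- backbone[n]; b <- backbone[n - 1]
    prev_el <- mb$el[a]
    el <- seq_el[k]
    bond <- if (el == "O" || prev_el == "O") .geom$b_CO else .geom$b_CC
    if (n == 2) {
      # third backbone atom: fix the zigzag plane with a virtual reference
      cref <- mb$xyz[b, ] + c(1, 0, 0)
      pos <- place_atom(mb$xyz[a, ], mb$xyz[b, ], cref, bond, .geom$ang_tet,
                        180)
      i <- mb_add(mb, el, pos, bond_to = a)
    } else {
      i <- mb_place(mb, el, a, b, backbone[n - 2], bond, .geom$ang_tet, 180)
    }
    backbone <- c(backbone, i)
  }
  nb <- length(backbone)
  c_cx <- backbone[nb]
  # carboxyl: =O and -OH (trigonal), plus the acidic hydrogen
  o_dbl <- mb_place(mb, "O", c_cx, backbone[nb - 1], backbone[nb - 2],
                    .geom$b_C_dblO, .geom$ang_trig, 90)
  o_oh <- mb_place(mb, "O", c_cx, backbone[nb - 1], backbone[nb - 2],
                   .geom$b_CO_acid, .geom$ang_trig, 270)
  mb_place(mb, "H", o_oh, c_cx, o_dbl, .geom$b_OH, 105, 180)
  # thiol hydrogen
  mb_place(mb, "H", s, c1, backbone[3], .geom$b_SH, 96, 180)
  # methylene hydrogens on every backbone carbon except the carboxyl
  for (k in 2:(nb - 1)) {
    i <- backbone[k]
    if (mb$el[i] != "C") next
    mb_add_h2(mb, i, backbone[k - 1], backbone[k + 1])
  }
  rot <- cbind(backbone[-nb], backbone[-1])
  ligand_template(mb_atoms(mb), mb$bonds, anchor_sulfur = s,
                  axis_carbon = c1, rotatable_bonds = rot,
                  component = "OL",
                  name = sprintf("HS-C%d-(EG)%d-OCH2-COOH", alkyl_len, n_eg))
}

#' The p-MBA ligand template
#'
#' Idealized para-mercaptobenzoic acid thiolate (deprotonated carboxylate,
#' matching the fully deprotonated shell modelled in solution): S-C6H4-COO-,
#' 14 atoms, built radially along the local +z axis.
#'
#' @return a [ligand_template()] with component `"OL"`.
#' @export
pmba_template <- function() {
  b <- .geom$b_CC_ar
  zc <- .geom$b_SC_ar + b  # ring center height
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- cbind(b * sin(ang), 0, zc - b * cos(ang))
  el <- c("S", rep("C", 6), "C", "O", "O", rep("H", 4))
  s <- c(0, 0, 0)
  c7 <- ring[4, ] + c(0, 0, 1.50)
  o1 <- c7 + 1.26 * c(sin(pi / 3), 0, cos(pi / 3))
  o2 <- c7 + 1.26 * c(-sin(pi / 3), 0, cos(pi / 3))
  hpos <- NULL
  for (i in c(2, 3, 5, 6)) {
    dir <- unit(ring[i, ] - c(0, 0, zc))
    hpos <- rbind(hpos, ring[i, ] + 1.08 * dir)
  }
  xyz <- rbind(s, ring, c7, o1, o2, hpos)
  atoms <- data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  bonds <- rbind(
    c(1, 2),                                   # S-C1
    cbind(2:7, c(3:7, 2)),                     # ring
    c(5, 8), c(8, 9), c(8, 10),                # C4-C7, C7-O
    cbind(c(3, 4, 6, 7), 11:14))               # ring H
  ligand_template(atoms, bonds, anchor_sulfur = 1, axis_carbon = 2,
                  rotatable_bonds = rbind(c(1, 2), c(5, 8)),
                  component = "OL", name = "pMBA")
}

#' Construct a payload specification
#'
#' A payload (drug or targeting peptide) is a rigid molecule geometry with a
#' designated primary-amine nitrogen used for amide coupling. The attach
#' atom must be a nitrogen bearing at least one hydrogen.
#'
#' @param atoms data.frame with `element`, `x`, `y`, `z` (Angstrom).
#' @param bonds 2-column bond index matrix; if `NULL`, detected from
#'   covalent radii.
#' @param attach_atom index of the coupling amine nitrogen.
#' @param class `"peptide"` or `"drug"`.
#' @param name payload label (e.g. `"QS13"`, `"TOR"`, or a user label).
#' @return an object of class `payload_spec`.
#' @export
payload_spec <- function(atoms, attach_atom, class = c("drug", "peptide"),
                         name = "payload", bonds = NULL) {
  class <- match.arg(class)
  atoms$element <- normalize_element(atoms$element)
  if (is.null(bonds)) {
    tmp <- cluster_model(data.frame(atoms[c("element", "x", "y", "z")],
                                    molecule_id = 1L, component = "OL"))
    bonds <- detect_bonds(tmp)
  }
  if (atoms$element[attach_atom] != "N") {
    stop("attach_atom (atom ", attach_atom, ") is ",
         atoms$element[attach_atom], ", not a nitrogen")
  }
  nb <- bond_neighbors(bonds, nrow(atoms))
  h_on_n <- nb[[attach_atom]][atoms$element[nb[[attach_atom]]] == "H"]
  if (length(h_on_n) < 1) {
    stop("attach_atom must be an amine nitrogen bearing at least one ",
         "hydrogen")
  }
  structure(list(atoms = atoms[c("element", "x", "y", "z")],
                 bonds = matrix(as.integer(bonds), ncol = 2),
                 attach_atom = as.integer(attach_atom),
                 class = class, name = name),
            class = "payload_spec")
}

#' Read a payload from an SDF or PDB file
#'
#' @param path structure file (SDF or PDB).
#' @param attach_atom index of the coupling amine nitrogen.
#' @inheritParams payload_spec
#' @return a [payload_spec()].
#' @export
read_payload <- function(path, attach_atom, class = c("drug", "peptide"),
                         name = NULL) {
  class <- match.arg(class)
  model <- read_structure(path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  payload_spec(model$atoms, attach_atom = attach_atom, class = class,
               name = name, bonds = model$bonds)
}

#' Synthetic rigid-ring drug payload
#'
#' A small aniline-like stand-in for a drug molecule (benzene ring with a
#' primary amine), used to exercise conjugation and placement without
#' bundling real drug geometries. Synthetic: it represents no real compound.
#'
#' @param name label (default `"toy-drug"`).
#' @return a [payload_spec()] with class `"drug"`.
#' @export
synthetic_drug_payload <- function(name = "toy-drug") {
  b <- .geom$b_CC_ar
  # amine N at origin, ring extending along +z
  n <- c(0, 0, 0)
  c1 <- c(0, 0, .geom$b_CN)
  zc <- .geom$b_CN + b
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- cbind(b * sin(ang), 0, zc - b * cos(ang))
  hn <- rbind(n + .geom$b_NH * c(sin(1.95), 0, -cos(1.95) * 0.45),
              n + .geom$b_NH * c(-sin(1.95), 0, -cos(1.95) * 0.45))
  hr <- NULL
  for (i in 2:6) {
    dir <- unit(ring[i, ] - c(0, 0, zc))
    hr <- rbind(hr, ring[i, ] + 1.08 * dir)
  }
  xyz <- rbind(n, ring, hn, hr)
  atoms <- data.frame(element = c("N", rep("C", 6), "H", "H", rep("H", 5)),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  bonds <- rbind(c(1, 2), cbind(2:7, c(3:7, 2)), c(1, 8), c(1, 9),
                 cbind(3:7, 10:14))
  payload_spec(atoms, attach_atom = 1, class = "drug", name = name,
               bonds = bonds)
}

#' Synthetic oligoglycine peptide payload
#'
#' An extended polyglycine chain used as a stand-in targeting peptide
#' (synthetic: it is not QS13 or RGD4C). The N-terminal amine is the
#' coupling site.
#'
#' @param n_res number of glycine residues (default 5).
#' @param name label (default `"toy-peptide"`).
#' @return a [payload_spec()] with class `"peptide"`.
#' @export
synthetic_peptide_payload <- function(n_res = 5, name = "toy-peptide") {
  stopifnot(n_res >= 1)
  mb <- new_molbuild()
  n1 <- mb_add(mb, "N", c(0, 0, 0))
  ca1 <- mb_add(mb, "C", c(0, 0, .geom$b_CN), bond_to = n1)
  cref <- c(1, 0, 0)
  c1 <- mb_add(mb, "C", place_atom(mb$xyz[ca1, ], mb$xyz[n1, ], cref,
                                   1.52, .geom$ang_tet, 180), bond_to = ca1)
  backbone <- c(n1, ca1, c1)
  res_n <- list(n1); res_ca <- list(ca1); res_c <- list(c1)
  for (r in seq_len(n_res - 1)) {
    nb <- length(backbone)
    ni <- mb_place(mb, "N", backbone[nb], backbone[nb - 1], backbone[nb - 2],
                   .geom$b_CN_amide, .geom$ang_trig, 180)
    cai <- mb_place(mb, "C", ni, backbone[nb], backbone[nb - 1],
                    .geom$b_CN, .geom$ang_trig, 180)
    ci <- mb_place(mb, "C", cai, ni, backbone[nb], 1.52, .geom$ang_tet, 180)
    backbone <- c(backbone, ni, cai, ci)
    res_n <- c(res_n, ni); res_ca <- c(res_ca, cai); res_c <- c(res_c, ci)
  }
  # carbonyl oxygens on every backbone C', terminal carboxylate O on last
  for (r in seq_len(n_res)) {
    ci <- res_c[[r]]
    cai <- res_ca[[r]]
    ni <- res_n[[r]]
    mb_place(mb, "O", ci, cai, ni, .geom$b_C_dblO, .geom$ang_trig, 90)
    if (r == n_res) {
      mb_place(mb, "O", ci, cai, ni, .geom$b_CO_acid, .geom$ang_trig, 270)
    }
  }
  # amide hydrogens on internal N, two hydrogens on the terminal amine
  mb_place(mb, "H", n1, ca1, res_c[[1]], .geom$b_NH, .geom$ang_tet, 60)
  mb_place(mb, "H", n1, ca1, res_c[[1]], .geom$b_NH, .geom$ang_tet, 300)
  if (n_res > 1) {
    for (r in 2:n_res) {
      mb_place(mb, "H", res_n[[r]], res_ca[[r]], res_c[[r]], .geom$b_NH,
               .geom$ang_trig, 90)
    }
  }
  # CA hydrogens
  for (r in seq_len(n_res)) {
    mb_add_h2(mb, res_ca[[r]], res_n[[r]], res_c[[r]])
  }
  payload_spec(mb_atoms(mb), attach_atom = n1, class = "peptide",
               name = name, bonds = mb$bonds)
}

#' Conjugate a payload onto a PEG linker by amide coupling
#'
#' Models carbodiimide (EDC/NHS-style) coupling as a bond-topology
#' operation: the linker's carboxyl -OH and one hydrogen of the payload's
#' amine are removed (net loss of one water equivalent) and an amide C-N
#' bond of ideal length is formed. The payload geometry is rigid-translated
#' onto the new bond position. The resulting template's component class
#' follows the payload class (peptide -> PL, drug -> DL).
#'
#' @param linker a [ligand_template()] terminating in -COOH (e.g. from
#'   [make_peg_linker()]).
#' @param payload a [payload_spec()].
#' @param clash_tol intra-template clash tolerance in Angstrom between
#'   non-bonded linker/payload atom pairs (default 1.0).
#' @return a [ligand_template()] with `linker + payload - 3` atoms.
#' @export
conjugate_payload <- function(linker, payload, clash_tol = 1.0) {
  stopifnot(inherits(linker, "ligand_template"),
            inherits(payload, "payload_spec"))
  la <- linker$atoms; lb <- linker$bonds
  nb <- bond_neighbors(lb, nrow(la))
  # locate the carboxyl: C bonded to =O and -O(H)
  c_cx <- NA; o_oh <- NA; h_oh <- NA
  for (i in which(la$element == "C")) {
    os <- nb[[i]][la$element[nb[[i]]] == "O"]
    if (length(os) != 2) next
    for (o in os) {
      hs <- nb[[o]][la$element[nb[[o]]] == "H"]
      if (length(hs) == 1) {
        c_cx <- i; o_oh <- o; h_oh <- hs
      }
    }
  }
  if (is.na(c_cx)) stop("linker does not terminate in a -COOH group")
  pa <- payload$atoms; pb <- payload$bonds
  pnb <- bond_neighbors(pb, nrow(pa))
  n_at <- payload$attach_atom
  h_n <- pnb[[n_at]][pa$element[pnb[[n_at]]] == "H"]
  if (length(h_n) < 1) stop("attach_atom is not an amine (no N-H hydrogen)")
  h_n <- h_n[1]
  # target N position: ideal amide bond along the former C-OH direction
  cpos <- as.numeric(la[c_cx, c("x", "y", "z")])
  opos <- as.numeric(la[o_oh, c("x", "y", "z")])
  n_target <- cpos + .geom$b_CN_amide * unit(opos - cpos)
  shift <- n_target - as.numeric(pa[n_at, c("x", "y", "z")])
  pa$x <- pa$x + shift[1]; pa$y <- pa$y + shift[2]; pa$z <- pa$z + shift[3]
  # drop the hydroxyl (O + H) and one amine hydrogen
  drop_l <- c(o_oh, h_oh)
  keep_l <- setdiff(seq_len(nrow(la)), drop_l)
  map_l <- match(seq_len(nrow(la)), keep_l)
  keep_p <- setdiff(seq_len(nrow(pa)), h_n)
  map_p <- match(seq_len(nrow(pa)), keep_p) + length(keep_l)
  atoms <- rbind(la[keep_l, ], pa[keep_p, c("element", "x", "y", "z")])
  lb2 <- lb[!(lb[, 1] %in% drop_l | lb[, 2] %in% drop_l), , drop = FALSE]
  lb2 <- cbind(map_l[lb2[, 1]], map_l[lb2[, 2]])
  pb2 <- pb[!(pb[, 1] == h_n | pb[, 2] == h_n), , drop = FALSE]
  pb2 <- cbind(map_p[pb2[, 1]], map_p[pb2[, 2]])
  bonds <- rbind(lb2, pb2, c(map_l[c_cx], map_p[n_at]))
  # intra-template clash scan over non-bonded linker/payload pairs
  lxyz <- as.matrix(la[keep_l, c("x", "y", "z")])
  pxyz <- as.matrix(pa[keep_p, c("x", "y", "z")])
  d2 <- outer(rowSums(lxyz^2), rowSums(pxyz^2), "+") - 2 * lxyz %*% t(pxyz)
  d2[map_l[c_cx], map_p[n_at] - length(keep_l)] <- Inf  # the new bond
  if (min(d2) < clash_tol^2) {
    stop(sprintf(
      "unavoidable intra-template clash after conjugation (%.2f A); ",
      sqrt(max(min(d2), 0))),
      "consider elongating the linker conformer first")
  }
  rot <- linker$rotatable_bonds
  rot <- rot[!(rot[, 1] %in% drop_l | rot[, 2] %in% drop_l), , drop = FALSE]
  rot <- cbind(map_l[rot[, 1]], map_l[rot[, 2]])
  ligand_template(atoms, bonds, anchor_sulfur = map_l[linker$anchor_sulfur],
                  axis_carbon = map_l[linker$axis_carbon],
                  rotatable_bonds = rot,
                  component = if (payload$class == "peptide") "PL" else "DL",
                  name = paste(linker$name, payload$name, sep = "+"))
}

#' Elongate a ligand conformer
#'
#' Sets every rotatable-bond dihedral to the anti (180 degree) conformation,
#' maximizing the outreach of a chain from its anchor sulfur. Only dihedrals
#' change; bond lengths and angles are untouched. If the anti conformer does
#' not extend farther than the input (possible for branched templates), the
#' input is returned unchanged, so the anchor-to-farthest-atom distance
#' never decreases. Deterministic.
#'
#' @param template a [ligand_template()].
#' @return a [ligand_template()] with outreach >= that of `template`.
#' @export
elongate_conformer <- function(template) {
  if (nrow(template$rotatable_bonds) == 0) return(template)
  out <- template
  n <- nrow(out$atoms)
  nb <- bond_neighbors(out$bonds, n)
  xyz <- template_xyz(out)
  for (k in seq_len(nrow(out$rotatable_bonds))) {
    i <- out$rotatable_bonds[k, 1]; j <- out$rotatable_bonds[k, 2]
    a <- setdiff(nb[[i]], j)
    d <- setdiff(nb[[j]], i)
    if (length(a) == 0 || length(d) == 0) next
    a <- min(a); d <- min(d)
    cur <- measure_dihedral(xyz[a, ], xyz[i, ], xyz[j, ], xyz[d, ])
    # a positive rotation about i->j decreases the (a,i,j,d) torsion
    delta <- cur - 180
    if (abs(delta) < 1e-9) next
    dist_set <- distal_atoms(out$bonds, n, i, j)
    xyz[dist_set, ] <- rotate_about(xyz[dist_set, , drop = FALSE],
                                    xyz[i, ], xyz[j, ] - xyz[i, ], delta)
  }
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  if (template_outreach(out) >= template_outreach(template)) out else template
}

#' Write a ligand template to SDF
#'
#' Serializes the template geometry and bond list as a V2000 SDF record via
#' ChemmineR, with the anchor sulfur, axis carbon, component and rotatable
#' bonds recorded as data fields.
#'
#' @param template a [ligand_template()].
#' @param path output file.
#' @return invisibly, `path`.
#' @importClassesFrom ChemmineR SDF
#' @export
write_ligand_template <- function(template, path) {
  a <- template$atoms
  ab <- as.matrix(a[c("x", "y", "z")])
  ab <- cbind(ab, matrix(0, nrow(ab), 13))
  rownames(ab) <- paste(a$element, seq_len(nrow(a)), sep = "_")
  colnames(ab) <- c("C1", "C2", "C3", paste0("V", 4:16))
  b <- template$bonds
  bb <- cbind(b, rep(1L, nrow(b)), matrix(0L, nrow(b), 4))
  rownames(bb) <- paste0("b", seq_len(nrow(b)))
  colnames(bb) <- c("C1", "C2", "C3", paste0("V", 4:7))
  sdf <- methods::new("SDF",
    header = c(Molecule_Name = template$name, Source = "aushell",
               Comment = "", Counts_Line = sprintf(
                 "%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                 nrow(a), nrow(b))),
    atomblock = ab, bondblock = bb,
    datablock = c(
      anchor_sulfur = as.character(template$anchor_sulfur),
      axis_carbon = as.character(template$axis_carbon),
      component = template$component,
      rotatable_bonds = paste(apply(template$rotatable_bonds, 1, paste,
                                    collapse = "-"), collapse = ",")))
  ChemmineR::write.SDF(sdf, file = path)
  invisible(path)
}

#' Read a ligand template from SDF
#'
#' @param path an SDF written by [write_ligand_template()].
#' @return a [ligand_template()].
#' @export
read_ligand_template <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  db <- ChemmineR::datablock(sdf)
  atoms <- data.frame(element = sub("_.*$", "", rownames(ab)),
                      x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      stringsAsFactors = FALSE)
  rot <- db[["rotatable_bonds"]]
  rot <- if (!is.null(rot) && nzchar(rot)) {
    do.call(rbind, lapply(strsplit(strsplit(rot, ",")[[1]], "-"),
                          as.integer))
  } else {
    matrix(integer(0), 0, 2)
  }
  ligand_template(atoms, cbind(as.integer(bb[, 1]), as.integer(bb[, 2])),
                  anchor_sulfur = as.integer(db[["anchor_sulfur"]]),
                  axis_carbon = as.integer(db[["axis_carbon"]]),
                  rotatable_bonds = rot,
                  component = db[["component"]],
                  name = ChemmineR::header(sdf)[["Molecule_Name"]])
}
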