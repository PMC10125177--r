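# PEG linkers, amide conjugation stoichiometry, conformer elongation.

test_that("PEG linker heavy-atom count follows the closed form", {
  # heavy atoms: S + alkyl C's + 3 per EG unit + terminal O-CH2-COOH (5)
  for (n_eg in c(0, 1, 3, 6)) {
    for (alkyl in c(1, 4, 11)) {
      t <- make_peg_linker(n_eg, alkyl)
      expect_equal(sum(t$atoms$element != "H"), alkyl + 3 * n_eg + 6,
                   info = sprintf("n_eg=%d alkyl=%d", n_eg, alkyl))
      # backbone chemistry: one S, correct O count (EG + ether + carboxyl)
      expect_equal(sum(t$atoms$element == "S"), 1)
      expect_equal(sum(t$atoms$element == "O"), n_eg + 3)
    }
  }
})

test_that("study linkers have the published heavy-atom formulas", {
  long <- make_peg_linker(6, 11)   # HS-C11-(EG)6-OCH2-COOH
  short <- make_peg_linker(3, 11)  # HS-C11-(EG)3-OCH2-COOH
  expect_equal(sum(long$atoms$element == "C"), 11 + 12 + 2)
  expect_equal(sum(long$atoms$element == "O"), 9)
  expect_equal(sum(short$atoms$element == "C"), 11 + 6 + 2)
  expect_equal(sum(short$atoms$element == "O"), 6)
  expect_identical(long$atoms$element[long$anchor_sulfur], "S")
})

test_that("conjugation loses exactly one water equivalent", {
  linker <- make_peg_linker(3, 11)
  for (payload in list(synthetic_drug_payload(),
                       synthetic_peptide_payload(3))) {
    conj <- conjugate_payload(linker, payload)
    expect_equal(nrow(conj$atoms),
                 nrow(linker$atoms) + nrow(payload$atoms) - 3)
    # element book-keeping: one O and two H fewer than the parts
    count <- function(a, el) sum(a$element == el)
    expect_equal(count(conj$atoms, "O"),
                 count(linker$atoms, "O") + count(payload$atoms, "O") - 1)
    expect_equal(count(conj$atoms, "H"),
                 count(linker$atoms, "H") + count(payload$atoms, "H") - 2)
    expect_equal(count(conj$atoms, "N"),
                 count(linker$atoms, "N") + count(payload$atoms, "N"))
  }
})

test_that("component class follows the payload class", {
  expect_identical(conjugate_payload(make_peg_linker(6, 11),
                                     synthetic_peptide_payload())$component,
                   "PL")
  expect_identical(conjugate_payload(make_peg_linker(3, 11),
                                     synthetic_drug_payload())$component,
                   "DL")
})

test_that("conjugation rejects a non-amine attach atom", {
  p <- synthetic_drug_payload()
  expect_error(payload_spec(p$atoms, attach_atom = 2, class = "drug",
                            bonds = p$bonds), "not a nitrogen")
})

test_that("elongation is a no-op without rotatable bonds", {
  t <- methylthiolate_template()
  expect_identical(elongate_conformer(t), t)
})

test_that("elongated chain reaches the grid-scan maximum end-to-end span", {
  # butane-like C4 backbone: one free dihedral plus two terminal ones
  mkchain <- function(d1, d2, d3) {
    xyz <- matrix(0, 6, 3)
    xyz[1, ] <- c(0, 0, 0)
    xyz[2, ] <- c(0, 0, 1.82)
    xyz[3, ] <- place_atom(xyz[2, ], xyz[1, ], c(1, 0, 0), 1.54, 109.47, 180)
    xyz[4, ] <- place_atom(xyz[3, ], xyz[2, ], xyz[1, ], 1.54, 109.47, d1)
    xyz[5, ] <- place_atom(xyz[4, ], xyz[3, ], xyz[2, ], 1.54, 109.47, d2)
    xyz[6, ] <- place_atom(xyz[5, ], xyz[4, ], xyz[3, ], 1.54, 109.47, d3)
    xyz
  }
  # independent oracle: exhaustive 36^3 grid over the three dihedrals
  grid <- seq(0, 350, by = 10)
  best <- 0
  for (d1 in grid) for (d2 in grid) for (d3 in grid) {
    xyz <- mkchain(d1, d2, d3)
    span <- sqrt(sum((xyz[6, ] - xyz[1, ])^2))
    if (span > best) best <- span
  }
  start <- mkchain(60, 300, 60)  # gauche-kinked input
  atoms <- data.frame(element = c("S", "C", "C", "C", "C", "C"),
                      x = start[, 1], y = start[, 2], z = start[, 3])
  bonds <- cbind(1:5, 2:6)
  t <- ligand_template(atoms, bonds, anchor_sulfur = 1, axis_carbon = 2,
                       rotatable_bonds = cbind(2:4, 3:5), name = "chain")
  e <- elongate_conformer(t)
  span_e <- sqrt(sum((as.numeric(e$atoms[6, c("x", "y", "z")]) -
                      as.numeric(e$atoms[1, c("x", "y", "z")]))^2))
  expect_equal(span_e, best, tolerance = 1e-6)
})

test_that("elongation only changes dihedrals, never bonds or angles", {
  t <- conjugate_payload(make_peg_linker(4, 6), synthetic_drug_payload())
  e <- elongate_conformer(t)
  lens <- function(tm) {
    xyz <- cbind(tm$atoms$x, tm$atoms$y, tm$atoms$z)
    sqrt(rowSums((xyz[tm$bonds[, 1], ] - xyz[tm$bonds[, 2], ])^2))
  }
  expect_equal(lens(e), lens(t), tolerance = 1e-6)
  expect_gte(aushell:::template_outreach(e),
             aushell:::template_outreach(t) - 1e-9)
})

test_that("elongated linker out-reaches a gauche-perturbed copy", {
  t <- make_peg_linker(6, 11)
  e <- elongate_conformer(t)
  # perturb one mid-backbone dihedral to gauche
  g <- e
  k <- 8
  i <- g$rotatable_bonds[k, 1]; j <- g$rotatable_bonds[k, 2]
  dist_set <- aushell:::distal_atoms(g$bonds, nrow(g$atoms), i, j)
  xyz <- cbind(g$atoms$x, g$atoms$y, g$atoms$z)
  xyz[dist_set, ] <- aushell:::rotate_about(
    xyz[dist_set, , drop = FALSE], xyz[i, ], xyz[j, ] - xyz[i, ], 120)
  g$atoms$x <- xyz[, 1]; g$atoms$y <- xyz[, 2]; g$atoms$z <- xyz[, 3]
  expect_gt(aushell:::template_outreach(e), aushell:::template_outreach(g))
})

test_that("ligand templates survive an SDF round trip with properties", {
  t <- conjugate_payload(make_peg_linker(3, 4), synthetic_drug_payload())
  path <- tempfile(fileext = ".sdf")
  write_ligand_template(t, path)
  back <- read_ligand_template(path)
  expect_identical(back$atoms$element, t$atoms$element)
  expect_equal(back$atoms$x, t$atoms$x, tolerance = 1e-4)
  expect_identical(back$anchor_sulfur, t$anchor_sulfur)
  expect_identical(back$axis_carbon, t$axis_carbon)
  expect_identical(back$component, t$component)
  expect_identical(back$rotatable_bonds, t$rotatable_bonds)
})
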