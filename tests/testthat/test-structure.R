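test_that("PDB fixtures parse with correct coordinates and altloc rules", {
  path <- write_pdb_lines(c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 1.0, 2.0, 3.0, element = "N"),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 2.5, 2.0, 3.0, element = "C"),
    pdb_atom_line(3, "C", "GLY", "A", 1, 3.0, 3.5, 3.0, element = "C")))
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x[m$atoms$elety == "CA"], 2.5)
  expect_equal(m$atoms$element, c("N", "C", "C"))

  # altloc: keep the highest-occupancy conformer
  path2 <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.6, altloc = "B")))
  m2 <- read_structure(path2)
  expect_equal(nrow(m2$atoms), 1)
  expect_equal(m2$atoms$x, 5)
  expect_equal(m2$atoms$altloc, "B")

  # tied occupancies resolve to altloc A
  path3 <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.5, altloc = "B"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.5, altloc = "A")))
  expect_equal(read_structure(path3)$atoms$altloc, "A")

  # waters are skipped; a water-only file has no usable atoms
  path4 <- write_pdb_lines(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0,
                                         element = "O"))
  expect_error(read_structure(path4), "no usable ATOM")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("SASA of isolated and paired spheres matches analytic areas", {
  one <- structure_model(data.frame(
    chain = "A", resno = 1L, insert = "", resid = "SPH", elety = "X",
    element = "C", x = 0, y = 0, z = 0, occupancy = 1, altloc = "",
    stringsAsFactors = FALSE))
  s1 <- sasa(one)
  expect_equal(s1$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)

  # two atoms far apart: exact additivity
  two_far <- structure_model(rbind(one$atoms,
                                   within(one$atoms, { x <- 100; chain <- "B" })))
  expect_equal(sasa(two_far)$total, 2 * s1$total, tolerance = 1e-9)

  # two identical fully overlapping atoms count once
  two_same <- one$atoms
  two_same <- rbind(two_same, within(two_same, chain <- "B"))
  expect_equal(sasa(structure_model(two_same))$total, s1$total,
               tolerance = 1e-9)
})

test_that("SASA is invariant under rigid-body motion", {
  td <- gen_toy_dimer("symmetric", n_atoms = 5)
  ref <- sasa(td, n_points = 12000L, radii_override = c(X = 3))$total
  set.seed(42)
  for (i in 1:3) {
    R <- rotation_matrix(stats::runif(3, 0, 2 * pi))
    m <- td
    xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% R
    m$atoms$x <- xyz[, 1] + 5; m$atoms$y <- xyz[, 2] - 3
    m$atoms$z <- xyz[, 3] + 1
    moved <- sasa(m, n_points = 12000L, radii_override = c(X = 3))$total
    expect_lt(abs(moved - ref) / ref, 0.001)
  }
})

test_that("unknown elements fall back with a warning or error on request", {
  odd <- structure_model(data.frame(
    chain = "A", resno = 1L, insert = "", resid = "UNK", elety = "Q",
    element = "Q", x = 0, y = 0, z = 0, occupancy = 1, altloc = "",
    stringsAsFactors = FALSE))
  expect_warning(s <- sasa(odd), "no radius")
  expect_equal(s$total, 4 * pi * (1.8 + 1.4)^2, tolerance = 0.01)
  expect_error(suppressWarnings(sasa(odd, unknown_radius = NA)), "radius")
})

test_that("toy sphere dimers reproduce the spherical-cap buried area", {
  td <- gen_toy_dimer("spheres", sphere_radius = 10, buried_area = 500)
  ia <- interface_area(td, "A", "B", radii_override = c(X = 10))
  expect_equal(ia$buried_per_monomer, attr(td, "expected_buried"),
               tolerance = 0.02)
  # separated spheres bury nothing
  far <- gen_toy_dimer("spheres", sphere_radius = 10, distance = 100)
  ia_far <- interface_area(far, "A", "B", radii_override = c(X = 10))
  expect_equal(ia_far$buried_per_monomer, 0)
  expect_true(all(ia_far$residue_classes == "none"))
  expect_error(interface_area(td, "A", "Z", radii_override = c(X = 10)),
               "not present")
})

test_that("buried area decreases monotonically as the chains separate", {
  areas <- vapply(c(15, 18, 21, 25), function(d) {
    td <- gen_toy_dimer("spheres", sphere_radius = 10, distance = d)
    interface_area(td, "A", "B", radii_override = c(X = 10))$buried_per_monomer
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("interface residues classify into core, rim and none", {
  m <- burial_fixture()
  ia <- interface_area(m, "A", "B", radii_override = c(X = 6))
  cls <- ia$residue_classes
  expect_equal(unname(cls["A:1"]), "core")   # fully caged residue
  expect_equal(unname(cls["A:2"]), "rim")    # partially occluded at the mouth
  expect_equal(unname(cls["A:3"]), "none")   # far from the interface
  # every classified residue lost accessible area
  touched <- names(cls)[cls != "none"]
  expect_true(all(ia$delta_sasa[touched] > 0))
})

test_that("contact searches respect the inclusive cutoff boundary", {
  # carbon heavy atoms exactly 4.5 A apart across chains
  atoms <- data.frame(
    chain = c("A", "B", "B"), resno = c(1L, 1L, 2L), insert = "",
    resid = "ALA", elety = "CB", element = "C",
    x = c(0, 4.5, 20), y = 0, z = 0, occupancy = 1, altloc = "",
    stringsAsFactors = FALSE)
  m <- structure_model(atoms)
  hits <- contact_residues(m, "A", 1, cutoff = 4.5)
  expect_equal(hits$resno, 1L)           # at the boundary: included
  expect_equal(hits$min_dist, 4.5)
  # isolated chain finds nothing
  lone <- structure_model(atoms[1, , drop = FALSE])
  expect_equal(nrow(contact_residues(lone, "A", 1)), 0)
  expect_error(contact_residues(m, "A", 99), "not found")
})

test_that("linker feasibility is exact arithmetic on anchors", {
  z <- linker_feasible(c(0, 0, 0), c(0, 0, 0), 0)
  expect_true(z$feasible)
  expect_equal(z$margin, 0)
  far <- linker_feasible(c(0, 0, 0), c(40, 0, 0), 5)
  expect_false(far$feasible)          # max reach 19 A < 40 A
  expect_equal(far$max_reach, 19)
  expect_equal(far$margin, -21)
  edge <- linker_feasible(c(0, 0, 0), c(19, 0, 0), 5)
  expect_true(edge$feasible)          # boundary counts as feasible
  expect_equal(edge$margin, 0, tolerance = 1e-12)
  expect_error(linker_feasible(c(0, 0, 0), c(1, 0, 0), -1), ">= 0")
})

test_that("constraint audits report pass, fail and unevaluable independently", {
  m <- gen_toy_dimer("symmetric", n_atoms = 5)
  # empty set: empty report, overall pass
  empty <- audit_constraints(m, constraint_set())
  expect_equal(nrow(empty), 0)
  expect_true(attr(empty, "overall_pass"))

  cs <- constraint_set(
    constraint("symmetric", chainA = "A", chainB = "B", max_rmsd = 0.01),
    constraint("contact", resA = "A:1", resB = "B:1", cutoff = 2.0),
    constraint("contact", resA = "A:1", resB = "B:99", cutoff = 5),
    constraint("disjoint_interfaces", set1 = c("A:1", "A:2"),
               set2 = c("A:4", "A:5")))
  rep_ <- audit_constraints(m, cs)
  expect_equal(rep_$status[1], "pass")   # exact two-fold construction
  expect_lt(rep_$value[1], 0.01)
  expect_equal(rep_$status[2], "fail")   # A:1-B:1 farther than 2 A
  expect_equal(rep_$value[2],
               assocfit:::min_residue_distance(m, "A:1", "B:1"))
  expect_equal(rep_$margin[2], 2.0 - rep_$value[2])
  expect_equal(rep_$status[3], "unevaluable")
  expect_equal(rep_$status[4], "pass")
  expect_false(attr(rep_, "overall_pass"))

  # order independence: permuting constraints permutes the rows unchanged
  rep_perm <- audit_constraints(m, structure(unclass(cs)[c(3, 1, 4, 2)],
                                             class = "constraint_set"))
  expect_equal(rep_perm$status, rep_$status[c(3, 1, 4, 2)])
  expect_equal(rep_perm$value, rep_$value[c(3, 1, 4, 2)])
})

test_that("a constructed violation fails with the correct distance margin", {
  atoms <- data.frame(
    chain = c("A", "B"), resno = 1L, insert = "", resid = "ALA",
    elety = "CB", element = "C", x = c(0, 10), y = 0, z = 0,
    occupancy = 1, altloc = "", stringsAsFactors = FALSE)
  m <- structure_model(atoms)
  rep_ <- audit_constraints(m, constraint_set(
    constraint("contact", resA = "A:1", resB = "B:1", cutoff = 6)))
  expect_equal(rep_$status, "fail")
  expect_equal(rep_$value, 10)
  expect_equal(rep_$margin, -4)
})

test_that("constraint files round-trip through the parser", {
  path <- tempfile(fileext = ".txt")
  writeLines(c(
    "# a comment line",
    "contact A:176 B:164 5.5   # pocket contact",
    "interface_contains A B A:127,A:133",
    "buried P:13 0.15",
    "accessible A:1 0.2",
    "disjoint_interfaces A:1,A:2 A:4",
    "symmetric A B 1.0"), path)
  cs <- read_constraints(path)
  expect_length(cs, 6)
  expect_equal(cs[[1]]$type, "contact")
  expect_equal(cs[[1]]$cutoff, 5.5)
  expect_equal(cs[[1]]$label, "pocket contact")
  expect_equal(cs[[2]]$residues, c("A:127", "A:133"))
  expect_equal(cs[[6]]$max_rmsd, 1.0)
  expect_error(read_constraints(tempfile()), "not found")
})

test_that("the shipped default constraint file parses and audits cleanly", {
  path <- system.file("extdata", "p85a_pten_constraints.txt",
                      package = "assocfit")
  cs <- read_constraints(path)
  expect_gte(length(cs), 8)
  # against a toy dimer lacking those residues every constraint must be
  # reported unevaluable, never silently failed
  m <- gen_toy_dimer("symmetric", n_atoms = 3)
  rep_ <- suppressWarnings(audit_constraints(m, cs))
  expect_true(all(rep_$status %in% c("pass", "unevaluable")))
})
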