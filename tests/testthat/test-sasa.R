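test_that("Shrake-Rupley matches the analytic sphere-cap area on atom toys", {
  # two carbon atoms 3 A apart: symmetric partial occlusion
  at2 <- data.frame(elety = "CA", resid = "ALA", chain = "A",
                    resno = 1:2, x = c(0, 3), y = 0, z = 0, element = "C")
  s2 <- vhh_structure(at2)
  per_atom <- vhhumanize:::shrake_rupley_atoms(
    as.matrix(at2[, c("x", "y", "z")]), rep(1.7 + 1.4, 2) - 1.4,
    probe = 1.4, n_points = 960)
  r_ext <- 1.7 + 1.4
  analytic <- sphere_cap_exposed_area(r_ext, r_ext, 3)
  expect_lt(abs(per_atom[1] - analytic) / analytic, 0.02)

  # three collinear atoms: the central one loses two opposite caps
  at3 <- data.frame(elety = "CA", resid = "ALA", chain = "A",
                    resno = 1:3, x = c(-3, 0, 3), y = 0, z = 0,
                    element = "C")
  per3 <- vhhumanize:::shrake_rupley_atoms(
    as.matrix(at3[, c("x", "y", "z")]), rep(1.7, 3),
    probe = 1.4, n_points = 960)
  analytic3 <- sphere_cap_exposed_area(r_ext, r_ext, c(3, 3))
  expect_lt(abs(per3[2] - analytic3) / analytic3, 0.02)
})

test_that("an isolated residue has relative SASA ~ 1 against its own reference", {
  at <- data.frame(elety = c("CA", "CB"), resid = "VAL", chain = "A",
                   resno = 1, x = c(0, 1.5), y = 0, z = 0, element = "C")
  sa <- compute_sasa(vhh_structure(at), reference = "isolated")
  expect_equal(sa$rel_sasa, 1, tolerance = 1e-9)
})

test_that("a fully enclosed atom has zero SASA", {
  # central atom caged by 14 atoms (octahedron + cube corners) at 2.0 A
  dirs <- rbind(diag(3), -diag(3),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) /
                  sqrt(3))
  shell <- 2.0 * dirs
  at <- data.frame(elety = "CA", resid = "ALA", chain = "A",
                   resno = 1, x = 0, y = 0, z = 0, element = "C")
  occ <- data.frame(elety = "C", resid = "OCC", chain = "X",
                    resno = 9001, x = shell[, 1], y = shell[, 2],
                    z = shell[, 3], element = "C")
  sa <- compute_sasa(vhh_structure(rbind(at, occ)), reference = "isolated")
  expect_equal(sa$sasa, 0)
})

test_that("SASA is invariant under rigid motion", {
  s <- make_ring_structure(rep("L", 15), id = "rot")
  base <- compute_sasa(s, reference = "isolated")
  # translation leaves the sampled geometry exactly unchanged
  st <- s; st$atoms$x <- st$atoms$x + 11.3
  st$atoms$y <- st$atoms$y - 4.2; st$atoms$z <- st$atoms$z + 0.7
  expect_equal(compute_sasa(st, reference = "isolated")$sasa, base$sasa,
               tolerance = 1e-9)
  # rotation re-samples the spheres: agreement to sampling accuracy
  q <- random_rotation(8)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(q)
  sr <- s; sr$atoms$x <- xyz[, 1]; sr$atoms$y <- xyz[, 2]
  sr$atoms$z <- xyz[, 3]
  rot <- compute_sasa(sr, reference = "isolated")
  expect_lt(max(abs(rot$sasa - base$sasa) / base$sasa), 0.03)
})

test_that("hydrophobic_exposed applies both the residue and exposure filter", {
  # all-glycine ring: nothing hydrophobic
  g <- make_ring_structure(rep("G", 12))
  expect_equal(nrow(hydrophobic_exposed(g)), 0)
  # planted: valine ring with three caged residues
  s <- make_ring_structure(rep("V", 20), buried = c(4, 9, 15))
  he <- hydrophobic_exposed(s)
  expect_setequal(he$resno, setdiff(1:20, c(4, 9, 15)))
  # threshold 0 keeps every hydrophobic residue
  expect_equal(nrow(hydrophobic_exposed(s, rel_threshold = 0)), 20)
})

test_that("unknown elements fall back to the generic radius with a warning", {
  at <- data.frame(elety = "Q1", resid = "ALA", chain = "A",
                   resno = 1, x = 0, y = 0, z = 0, element = "Q")
  expect_warning(compute_sasa(vhh_structure(at), reference = "isolated"),
                 "unknown element")
})
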