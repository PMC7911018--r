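two_residue_structure <- function(d, sep = 5) {
  # two CA/CB residues with heavy-atom minimum distance d; resno sep apart
  atoms <- data.frame(
    elety = rep(c("CA", "CB"), 2), resid = "LEU", chain = "A",
    resno = rep(c(1, 1 + sep), each = 2),
    x = c(0, 1.5, d + 1.5 + 1.5, d + 1.5), y = 0, z = 0, element = "C")
  vhh_structure(atoms)
}

test_that("single-conformation contacts follow the distance rule", {
  near <- contact_map(two_residue_structure(3), cutoff = 4.5)
  expect_equal(near[1, 2], 1)
  far <- contact_map(two_residue_structure(10), cutoff = 4.5)
  expect_equal(far[1, 2], 0)
})

test_that("the near-diagonal band is excluded whatever the geometry", {
  s <- two_residue_structure(3, sep = 2)  # |i-j| = 2 <= min_sep
  cm <- contact_map(s, cutoff = 4.5, min_sep = 2)
  expect_equal(sum(cm), 0)
})

test_that("ensemble contact fractions average over conformations", {
  a <- two_residue_structure(3)
  b <- two_residue_structure(10)
  e <- as_ensemble(list(a, b))
  cm <- contact_map(e, cutoff = 4.5)
  expect_equal(cm[1, 2], 0.5)
  expect_equal(attr(cm, "n_frames"), 2)
})

test_that("contact maps are symmetric with entries in [0, 1]", {
  bx <- make_basin_ensemble(n = 20, n_frames = 12,
                            proportions = c(0.5, 0.5), loop = 14:18,
                            seed = 3)
  cm <- contact_map(bx$ensemble)
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_true(all(cm >= 0 & cm <= 1))
  expect_true(all(diag(cm) == 0))
})

test_that("identical maps give an all-zero projection and empty mask", {
  s <- random_structure(12, seed = 1)
  cm <- contact_map(s)
  dp <- contact_diff_projection(cm, cm)
  expect_true(all(dp$d == 0))
  expect_false(any(dp$selected))
})

test_that("a single flipped contact projects to d_i = d_j = 1", {
  rf <- make_rewiring_fixture(targets = c(5, 9, 13, 17, 21))
  # restrict to one flip by building maps by hand from the package output
  wt <- contact_map(rf$wt)
  mut <- contact_map(rf$mut)
  flip <- wt
  flip[, ] <- unclass(mut)
  flip["A:27", "A:5"] <- flip["A:5", "A:27"] <- 1  # re-flip one pair
  dp <- contact_diff_projection(flip, mut)
  expect_equal(dp$d[dp$key == "A:27"], 1)
  expect_equal(dp$d[dp$key == "A:5"], 1)
  expect_equal(sum(dp$d), 2)
})

test_that("projection obeys the triangle bound d(A,C) <= d(A,B) + d(B,C)", {
  maps <- lapply(1:3, function(i) contact_map(random_structure(15, seed = i)))
  dab <- contact_diff_projection(maps[[1]], maps[[2]])$d
  dbc <- contact_diff_projection(maps[[2]], maps[[3]])$d
  dac <- contact_diff_projection(maps[[1]], maps[[3]])$d
  expect_true(all(dac <= dab + dbc + 1e-12))
})

test_that("mismatched maps are rejected", {
  a <- contact_map(random_structure(10, seed = 4))
  b <- contact_map(random_structure(12, seed = 5))
  expect_error(contact_diff_projection(a, b), "dimensions")
  c2 <- contact_map(random_structure(10, seed = 4), cutoff = 6)
  expect_error(contact_diff_projection(a, c2), "contact rules")
})

test_that("planted rewiring puts the mutated residue first in the projection", {
  rf <- make_rewiring_fixture()
  dp <- contact_diff_projection(contact_map(rf$wt), contact_map(rf$mut))
  expect_equal(dp$key[which.max(dp$d)], paste0("A:", rf$truth$mover))
  expect_equal(max(dp$d), rf$truth$n_flipped)
  expect_true(dp$selected[which.max(dp$d)])
})

test_that("active-residue nomination keeps spatially clustered candidates", {
  rf <- make_rewiring_fixture()
  s <- get_conformation(rf$wt, 1)
  # empty inputs -> empty nomination
  empty <- nominate_active_residues(character(0), character(0), s)
  expect_equal(nrow(empty), 0)
  # the clustered targets + mover survive; their provenance is recorded
  dp <- contact_diff_projection(contact_map(rf$wt), contact_map(rf$mut))
  exposed <- hydrophobic_exposed(s)
  nom <- nominate_active_residues(exposed, dp, s, distance = 6)
  expect_true(paste0("A:", rf$truth$mover) %in% nom$key)
  expect_true(all(nom$provenance %in% c("exposure", "diff", "both")))
  # two isolated singletons far from any candidate are dropped
  ring <- make_ring_structure(rep("V", 40))
  lone <- nominate_active_residues(c("A:1", "A:20"), character(0), ring,
                                   distance = 6)
  expect_equal(nrow(lone), 0)
  # strict intersection mode
  nomi <- nominate_active_residues(c("A:1", "A:2"), c("A:2", "A:3"),
                                   ring, distance = 6,
                                   mode = "intersection")
  expect_true(nrow(nomi) == 0)  # A:2 alone has no candidate neighbor
})
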