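test_that("hydrophobic stretches score lower than polar stretches", {
  p <- intrinsic_profile(paste0(strrep("S", 30), strrep("V", 30)))
  s_ser <- mean(p$intrinsic[1:25])   # away from the junction
  s_val <- mean(p$intrinsic[36:60])
  expect_gt(s_ser, s_val)
})

test_that("a homopolymer has a flat intrinsic profile", {
  p <- intrinsic_profile(strrep("A", 40))
  expect_true(all(abs(p$intrinsic) < 1e-12))
})

test_that("the surrogate tracks an inverted hydropathy window score", {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  window_mean <- function(x, w = 7) {
    h <- w %/% 2
    vapply(seq_along(x), function(i)
      mean(x[max(1, i - h):min(length(x), i + h)]), 0)
  }
  set.seed(31)
  for (rep in 1:5) {
    seqv <- sample(names(kd), 80, replace = TRUE)
    p <- intrinsic_profile(paste(seqv, collapse = ""))
    oracle <- window_mean(-kd[seqv])
    expect_gte(stats::cor(p$intrinsic, oracle, method = "spearman"), 0.6)
  }
})

test_that("profiles are labeled as surrogate scores", {
  p <- intrinsic_profile("ACDEFGHIKLMNPQRSTVWYACDEFGHIKL")
  expect_equal(attr(p, "scorer"), "surrogate-intrinsic")
})

test_that("a uniform intrinsic profile is unchanged by structural correction", {
  s <- make_ring_structure(rep("V", 25), buried = c(3, 12))
  prof <- intrinsic_profile(strrep("A", 25))
  prof$intrinsic <- rep(0.7, 25)
  out <- structural_correction(s, prof)
  expect_equal(out$corrected, rep(0.7, 25), tolerance = 1e-12)
})

test_that("residues beyond the patch radius keep their intrinsic score", {
  atoms <- data.frame(elety = rep(c("CA", "CB"), 2), resid = "ALA",
                      chain = "A", resno = rep(1:2, each = 2),
                      x = c(0, 1.5, 30, 31.5), y = 0, z = 0, element = "C")
  s <- vhh_structure(atoms)
  prof <- data.frame(scheme_pos = c("1", "2"), residue = "A",
                     intrinsic = c(-2, 1), stringsAsFactors = FALSE)
  class(prof) <- c("solubility_profile", "data.frame")
  out <- structural_correction(s, prof, patch_radius = 10)
  expect_equal(out$corrected, out$intrinsic)
})

test_that("a planted poor patch drags down its spatial neighborhood", {
  fix <- make_shielding_fixture()
  out <- structural_correction(fix$exposed, fix$profile)
  patch <- unlist(fix$truth$patches)
  expect_lt(mean(out$corrected[patch]), mean(out$intrinsic[-patch]))
  # interior patch residues are corrected below their flat neighbors
  expect_true(all(out$corrected[c(6, 7, 26, 27)] < -1))
  expect_true(all(out$corrected[-patch] > -1))
})

test_that("hotspot scores equal the sum of member corrected scores exactly", {
  fix <- make_shielding_fixture()
  prof <- structural_correction(fix$exposed, fix$profile)
  hs <- detect_hotspots(fix$exposed, prof)
  for (h in hs) {
    i <- match(h$members, prof$key)
    expect_equal(h$score, sum(prof$corrected[i]), tolerance = 1e-12)
  }
})

test_that("hotspot membership is monotone in the membership distance", {
  fix <- make_shielding_fixture()
  prof <- structural_correction(fix$exposed, fix$profile)
  cuts <- c(3, 4.5, 6, 8, 12)
  members <- lapply(cuts, function(cc) {
    hs <- detect_hotspots(fix$exposed, prof, hotspot_distance = cc)
    sort(unique(unlist(lapply(hs, `[[`, "members"))))
  })
  for (i in seq_along(cuts)[-1])
    expect_true(all(members[[i - 1]] %in% members[[i]]))
})

test_that("membership matches the exhaustive all-pairs oracle on small toys", {
  for (seed_n in list(c(1, 18), c(2, 24), c(3, 30))) {
    n <- seed_n[2]
    set.seed(seed_n[1])
    buried <- sample(n, 3)
    s <- make_ring_structure(rep("I", n), buried = buried)
    prof <- data.frame(scheme_pos = as.character(1:n), residue = "I",
                       intrinsic = stats::runif(n, -2.5, 1.5),
                       stringsAsFactors = FALSE)
    class(prof) <- c("solubility_profile", "data.frame")
    prof <- structural_correction(s, prof)
    hs <- detect_hotspots(s, prof, hotspot_distance = 6)
    got <- unique(unlist(lapply(hs, `[[`, "members")))
    seeds <- which(prof$corrected < -1)
    oracle <- brute_force_members(s, seeds, prof$exposed, 6)
    expect_setequal(got, paste0("A:", oracle))
  }
})

test_that("two well-separated planted patches give exactly two hotspots", {
  fix <- make_shielding_fixture()
  prof <- structural_correction(fix$exposed, fix$profile)
  hs <- detect_hotspots(fix$exposed, prof)
  expect_length(hs, 2)
  got <- lapply(hs, function(h) sort(match(h$members, prof$key)))
  truth <- fix$truth$members
  matched <- vapply(got, function(g)
    any(vapply(truth, function(tr) identical(g, as.integer(tr)), TRUE)),
    TRUE)
  expect_true(all(matched))
})

test_that("two adjacent seeds sharing members merge into one hotspot", {
  fix <- make_shielding_fixture(patches = list(10:13))
  prof <- structural_correction(fix$exposed, fix$profile)
  hs <- detect_hotspots(fix$exposed, prof)
  expect_length(hs, 1)
  expect_length(hs[[1]]$seeds, 2)
})

test_that("an isolated seed forms a hotspot of itself", {
  atoms <- data.frame(elety = rep(c("CA", "CB"), 2), resid = "VAL",
                      chain = "A", resno = rep(c(1, 10), each = 2),
                      x = c(0, 1.5, 40, 41.5), y = 0, z = 0, element = "C")
  s <- vhh_structure(atoms)
  prof <- data.frame(scheme_pos = c("1", "10"), residue = "V",
                     intrinsic = c(-2, 0.5), stringsAsFactors = FALSE)
  class(prof) <- c("solubility_profile", "data.frame")
  prof <- structural_correction(s, prof)
  hs <- detect_hotspots(s, prof)
  expect_length(hs, 1)
  expect_identical(hs[[1]]$members, "A:1")
  expect_equal(hs[[1]]$score, prof$corrected[1], tolerance = 1e-12)
})

test_that("no seed passing the rule gives an empty, valid result", {
  fix <- make_shielding_fixture(patch_value = 0.2)
  prof <- structural_correction(fix$exposed, fix$profile)
  hs <- detect_hotspots(fix$exposed, prof)
  expect_length(hs, 0)
  expect_equal(nrow(hotspot_report(prof, hs, "x")), 0)
})

test_that("hotspot reports support side-by-side construct comparison", {
  fix <- make_shielding_fixture()
  pe <- structural_correction(fix$exposed, fix$profile)
  ps <- structural_correction(fix$shielded, fix$profile)
  he <- detect_hotspots(fix$exposed, pe)
  hs <- detect_hotspots(fix$shielded, ps)
  rep_df <- rbind(hotspot_report(pe, he, "exposed"),
                  hotspot_report(ps, hs, "shielded"))
  expect_equal(sum(rep_df$construct == "exposed"), 2)
  expect_true(all(rep_df$scorer == "surrogate-intrinsic"))
  # shielding strictly reduces total membership (here to zero)
  expect_lt(sum(rep_df$n_members[rep_df$construct == "shielded"]),
            sum(rep_df$n_members[rep_df$construct == "exposed"]))
})

test_that("external profiles bypass the surrogate and keep their label", {
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(scheme_pos = as.character(1:5), residue = "A",
               intrinsic = c(-1.5, 0, 0.5, 1, -0.2)),
    tf, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- read_profile_tsv(tf)
  expect_equal(attr(p, "scorer"), "external")
  expect_equal(p$intrinsic[1], -1.5)
})
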