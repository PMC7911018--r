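# Synthetic toy structures and conformational ensembles with planted
# ground truth.
#
# Structures are deliberately non-physical: residues are CA/CB pseudo-atom
# pairs laid out on a circular backbone, burial and loop shielding are
# realized by occluder pseudo-atoms (residue name "OCC"), and ensemble
# basins are rigid displacements of a loop segment.  Every downstream
# operator depends only on distances, exposure and labels, so idealized
# geometry is sufficient - and the generator can emit the exact ground
# truth (exposed sets, contacts, basin labels) alongside each fixture.

# occluder cage: atoms at `dist` along the given unit directions
cage_atoms <- function(center, directions, dist = 2.1) {
  t(apply(directions, 1, function(u) center + dist * u))
}

#' Circular toy structure with planted exposure
#'
#' Residues are placed on a circle (CA on the backbone ring, CB pointing
#' outward).  Residues listed in `buried` or `shielded` are wrapped in an
#' occluder cage that removes their solvent accessibility: `buried` models
#' intrinsically buried side chains, `shielded` models a loop conformation
#' sitting over a surface patch; both are geometrically identical and the
#' distinction is bookkeeping for the caller.
#'
#' @param aa character vector of one-letter residue codes (or a single
#'   string).
#' @param spacing backbone arc spacing between consecutive CA atoms, in
#'   Angstrom.
#' @param buried,shielded residue indices to occlude.
#' @param id structure identifier.
#' @return a `vhh_structure` with ground truth in the `truth` attribute
#'   (`exposed`: logical per residue).
#' @export
make_ring_structure <- function(aa, spacing = 4.5, buried = integer(0),
                                shielded = integer(0), id = "ring") {
  if (length(aa) == 1 && nchar(aa) > 1) aa <- strsplit(aa, "")[[1]]
  n <- length(aa)
  stopifnot(n >= 3)
  R <- spacing * n / (2 * pi)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  ca <- cbind(R * cos(theta), R * sin(theta), 0)
  cb <- cbind((R + 1.8) * cos(theta), (R + 1.8) * sin(theta), 0)
  rows <- list()
  occl <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <- data.frame(
      elety = c("CA", "CB"), resid = aa_three(aa[i]), chain = "A",
      resno = i, x = c(ca[i, 1], cb[i, 1]), y = c(ca[i, 2], cb[i, 2]),
      z = c(ca[i, 3], cb[i, 3]), element = "C", stringsAsFactors = FALSE)
    if (i %in% c(buried, shielded)) {
      u_r <- c(cos(theta[i]), sin(theta[i]), 0)   # outward
      u_t <- c(-sin(theta[i]), cos(theta[i]), 0)  # tangent
      u_z <- c(0, 0, 1)
      pts <- rbind(
        cage_atoms(cb[i, ], rbind(u_r, u_t, -u_t, u_z, -u_z)),
        cage_atoms(ca[i, ], rbind(-u_r, u_z, -u_z)))
      occl[[length(occl) + 1]] <- data.frame(
        elety = "C", resid = OCCLUDER_RESID, chain = "X",
        resno = 9000 + i, x = pts[, 1], y = pts[, 2], z = pts[, 3],
        element = "C", stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, c(rows, occl))
  s <- vhh_structure(atoms, id = id)
  truth <- list(exposed = !(seq_len(n) %in% c(buried, shielded)),
                buried = buried, shielded = shielded, spacing = spacing)
  attr(s, "truth") <- truth
  s
}

#' Shielded/exposed conformation pair of one sequence
#'
#' Two conformations of the same toy chain: one with a planted
#' poor-solubility surface patch fully exposed, one with the patch hidden
#' under an occluding loop.  The planted per-residue profile is returned
#' alongside, with the expected hotspot seeds and members for the exposed
#' conformation.
#'
#' @param n chain length.
#' @param patches list of integer vectors: planted poor-solubility patches.
#' @param patch_value,background intrinsic scores planted inside/outside
#'   the patches (z scale).
#' @param aa residue code used for all positions (default `"V"`).
#' @param spacing backbone spacing in Angstrom.
#' @return list with `exposed` and `shielded` structures, the planted
#'   `profile` (a `solubility_profile`), and `truth` (patches, expected
#'   seeds and members per patch under the default 10 A patch radius,
#'   6 A hotspot distance and -1 seed threshold).
#' @export
make_shielding_fixture <- function(n = 40, patches = list(5:8, 25:28),
                                   patch_value = -1.8, background = 0.3,
                                   aa = "V", spacing = 4.5) {
  seqv <- rep(aa, n)
  exposed <- make_ring_structure(seqv, spacing = spacing, id = "exposed")
  shielded <- make_ring_structure(seqv, spacing = spacing,
                                  shielded = unlist(patches),
                                  id = "shielded")
  intr <- rep(background, n)
  for (p in patches) intr[p] <- patch_value
  profile <- data.frame(scheme_pos = as.character(seq_len(n)),
                        residue = seqv, intrinsic = intr,
                        stringsAsFactors = FALSE)
  attr(profile, "scorer") <- "surrogate-intrinsic"
  class(profile) <- c("solubility_profile", "data.frame")
  truth <- list(patches = patches,
                seeds = lapply(patches, function(p) p[-c(1, length(p))]),
                members = patches)
  list(exposed = exposed, shielded = shielded, profile = profile,
       truth = truth)
}

#' Toy ensemble with planted cluster basins
#'
#' Builds `n_frames` conformations of a circular chain in which a loop
#' segment occupies one of several rigidly displaced basins; within-basin
#' variation is isotropic Gaussian jitter on every atom.  With displacement
#' much larger than jitter the planted basin labels are recoverable by
#' RMSD clustering.
#'
#' @param n chain length.
#' @param n_frames number of conformations.
#' @param proportions basin occupancies (summing to 1).
#' @param loop residue indices of the mobile loop segment.
#' @param displacement rigid basin displacement in Angstrom.
#' @param jitter per-coordinate Gaussian noise sd in Angstrom.
#' @param seed RNG seed (fixed seed + spec gives identical output).
#' @param aa residue code for all positions.
#' @return list with `ensemble` (a `conformation_ensemble`) and `truth`
#'   (`labels`: planted basin per frame, basin 1 = most populated).
#' @export
make_basin_ensemble <- function(n = 60, n_frames = 200,
                                proportions = c(0.85, 0.10, 0.05),
                                loop = 45:54, displacement = 8,
                                jitter = 0.15, seed = 1, aa = "A") {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, all(loop <= n))
  base <- make_ring_structure(rep(aa, n), id = "basins")
  xyz0 <- atom_coords(base)
  loop_atoms <- which(base$atoms$resno %in% loop &
                        base$atoms$chain == "A")
  k <- length(proportions)
  dirs <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, -1),
                c(1, 0, 0), c(-1, 0, 0))[seq_len(k), , drop = FALSE]
  counts <- floor(proportions * n_frames)
  counts[1] <- counts[1] + (n_frames - sum(counts))
  labels0 <- rep(seq_len(k), counts)
  with_seed(seed, {
    labels <- sample(labels0)
    structures <- lapply(seq_len(n_frames), function(f) {
      xyz <- xyz0
      b <- labels[f]
      xyz[loop_atoms, ] <- sweep(xyz[loop_atoms, , drop = FALSE], 2,
                                 displacement * dirs[b, ], "+")
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter),
                          ncol = 3)
      a <- base$atoms
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      vhh_structure(a, id = sprintf("frame%d", f))
    })
    ens <- as_ensemble(structures, id = "basin_ensemble")
    list(ensemble = ens, truth = list(labels = labels, loop = loop,
                                      displacement = displacement,
                                      jitter = jitter))
  })
}

#' Wild-type/mutant pair with planted contact rewiring
#'
#' A toy chain in which a set of target residues forms a tight spatial
#' cluster at the ring center.  In the "wild-type" conformation one
#' additional residue (the mover) sits inside that cluster and contacts
#' every target; in the "mutant" conformation it sits at its backbone ring
#' position and contacts nothing.  The contact-map difference between the
#' two therefore flips exactly the mover-target contacts, and the mover
#' carries the maximal per-residue projection.
#'
#' @param n chain length.
#' @param mover residue index that changes position.
#' @param targets residue indices forming the static cluster (pairwise and
#'   mover sequence separations all exceed the default contact exclusion).
#' @param aa residue code for all positions.
#' @return list with `wt` and `mut` single-conformation ensembles and
#'   `truth` (`mover`, `targets`, `n_flipped`).
#' @export
make_rewiring_fixture <- function(n = 30, mover = 27,
                                  targets = c(5, 9, 13, 17, 21),
                                  aa = "L") {
  stopifnot(all(abs(outer(c(mover, targets), c(mover, targets), "-"))
                [upper.tri(diag(length(targets) + 1))] > 2))
  base <- make_ring_structure(rep(aa, n), id = "rewire")
  cluster_xy <- function(i) {
    ang <- 2 * pi * (i - 1) / length(targets)
    c(3 * cos(ang), 3 * sin(ang), 0)
  }
  place <- function(s, resno, ca_pos) {
    at <- which(s$atoms$resno == resno & s$atoms$chain == "A")
    s$atoms$x[at] <- ca_pos[1] + c(0, 1.8)
    s$atoms$y[at] <- ca_pos[2]
    s$atoms$z[at] <- ca_pos[3]
    s
  }
  wt <- base; mut <- base
  for (i in seq_along(targets)) {
    p <- cluster_xy(i)
    wt <- place(wt, targets[i], p)
    mut <- place(mut, targets[i], p)
  }
  wt <- place(wt, mover, c(0, 0, 0))   # inside the cluster
  wt$id <- "rewire_wt"; mut$id <- "rewire_mut"
  list(wt = as_ensemble(list(wt), id = "wt"),
       mut = as_ensemble(list(mut), id = "mut"),
       truth = list(mover = mover, targets = targets,
                    n_flipped = length(targets)))
}
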