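# Solvent-accessible surface area: Shrake-Rupley with a deterministic
# golden-spiral point set.
#
# Defaults: probe 1.4 A, 960 sphere points per atom, element-based van der
# Waals radii.  Relative SASA divides the absolute per-residue area by a
# reference: the tabulated theoretical maximum for all-atom structures, or
# the residue's own isolated area ("isolated") for the package's
# pseudo-atom synthetic structures, clipped to [0, 1.5].

golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(s) {
  r <- VDW_RADII[s$atoms$element]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(unique(s$atoms$element[unknown]), collapse = ", "),
            "; using generic radius ", VDW_DEFAULT)
    r[unknown] <- VDW_DEFAULT
  }
  unname(r)
}

# per-atom accessible area, all atoms (occluders included) occlude
shrake_rupley_atoms <- function(xyz, radii, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)
  r_ext <- radii + probe
  area <- numeric(n)
  r2 <- rowSums(xyz^2)
  for (i in seq_len(n)) {
    ri <- r_ext[i]
    d2 <- r2 + r2[i] - 2 * drop(xyz %*% xyz[i, ])
    nb <- which(d2 < (ri + r_ext)^2 & seq_len(n) != i)
    if (!length(nb)) { area[i] <- 4 * pi * ri^2; next }
    p <- pts * ri
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb[order(d2[nb])]) {
      if (!any(free)) break
      dd <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- dd >= r_ext[j]^2
    }
    area[i] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  area
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley numerical SASA.  All atoms in the structure occlude
#' (including synthetic occluder pseudo-atoms); areas are reported per
#' protein residue.
#'
#' @param s a `vhh_structure`.
#' @param probe probe radius in Angstrom.
#' @param n_points sphere test points per atom.
#' @param reference `"tabulated"` (theoretical per-residue maxima; suitable
#'   for all-atom structures) or `"isolated"` (each residue's own area
#'   computed in isolation; suitable for pseudo-atom structures).
#' @return data frame with columns `chain`, `resno`, `resid`, `aa`, `key`,
#'   `sasa` (absolute, A^2), `rel_sasa` (clipped to [0, 1.5]).
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960,
                         reference = c("tabulated", "isolated")) {
  stopifnot(inherits(s, "vhh_structure"))
  reference <- match.arg(reference)
  xyz <- atom_coords(s)
  radii <- atom_radii(s)
  per_atom <- shrake_rupley_atoms(xyz, radii, probe, n_points)
  rt <- residue_table(s)
  idx <- residue_atom_indices(s)
  rt$sasa <- vapply(idx, function(i) sum(per_atom[i]), 0)
  ref_area <- if (reference == "tabulated") {
    known <- rt$aa %in% names(MAX_SASA)
    if (!all(known))
      warning("residue type(s) without tabulated maximum: ",
              paste(unique(rt$resid[!known]), collapse = ", "),
              "; using generic 200 A^2")
    out <- rep(200, nrow(rt))
    out[known] <- MAX_SASA[rt$aa[known]]
    out
  } else {
    vapply(idx, function(i)
      sum(shrake_rupley_atoms(xyz[i, , drop = FALSE], radii[i],
                              probe, n_points)), 0)
  }
  rt$rel_sasa <- pmin(pmax(rt$sasa / ref_area, 0), 1.5)
  attr(rt, "parameters") <- list(probe = probe, n_points = n_points,
                                 reference = reference)
  rt
}

#' Exposed hydrophobic residues
#'
#' Residues whose one-letter code is in the hydrophobic set and whose
#' relative SASA reaches the exposure threshold.
#'
#' @param s a `vhh_structure`.
#' @param sasa optional precomputed table from [compute_sasa()]; computed
#'   with `reference = "isolated"` when missing.
#' @param rel_threshold relative-SASA exposure threshold (default 0.25).
#' @param hydrophobic hydrophobic one-letter codes.
#' @return subset of the SASA table (exposed hydrophobic residues).
#' @export
hydrophobic_exposed <- function(s, sasa = NULL, rel_threshold = 0.25,
                                hydrophobic = HYDROPHOBIC_SET) {
  if (is.null(sasa)) sasa <- compute_sasa(s, reference = "isolated")
  out <- sasa[sasa$aa %in% hydrophobic & sasa$rel_sasa >= rel_threshold, ]
  rownames(out) <- NULL
  out
}
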