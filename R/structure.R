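# Structure and ensemble containers (PDB I/O via bio3d).
#
# A `vhh_structure` is one conformation: an atom table with residue
# bookkeeping.  A `conformation_ensemble` is N conformations sharing one
# topology, stored bio3d-style as an (N x 3*natoms) coordinate matrix.
# Atoms with residue name "OCC" are synthetic occluders: they take part in
# every geometric computation (SASA occlusion, shielding) but are not
# protein residues and never appear in residue-level reports.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
OCCLUDER_RESID <- "OCC"

#' Construct a structure from an atom table
#'
#' @param atoms data frame with columns `elety` (atom name), `resid`
#'   (3-letter residue name), `chain`, `resno`, `x`, `y`, `z`; optional
#'   `eleno` and `element` (derived from the first letter of `elety` when
#'   absent).
#' @param id structure identifier.
#' @return object of class `vhh_structure`.
#' @export
vhh_structure <- function(atoms, id = "structure") {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$element))
    atoms$element <- substr(atoms$elety, 1, 1)
  structure(list(id = id, atoms = atoms), class = "vhh_structure")
}

#' @export
print.vhh_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("vhh_structure '%s': %d residues, %d atoms (%d occluder)\n",
              x$id, nrow(rt), nrow(x$atoms),
              sum(x$atoms$resid == OCCLUDER_RESID)))
  invisible(x)
}

#' Residue table of a structure
#'
#' Protein residues (occluder pseudo-atoms excluded) in chain/residue-number
#' order, one row per residue.
#'
#' @param s a `vhh_structure`.
#' @return data frame with columns `chain`, `resno`, `resid`, `aa`
#'   (one-letter code) and `key` (`chain:resno`).
#' @export
residue_table <- function(s) {
  a <- s$atoms[s$atoms$resid != OCCLUDER_RESID, ]
  key <- paste(a$chain, a$resno, sep = ":")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    resid = a$resid[first], stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno), ]
  out$aa <- aa_one(out$resid)
  out$key <- paste(out$chain, out$resno, sep = ":")
  rownames(out) <- NULL
  out
}

# per-residue atom index list, aligned with residue_table order
residue_atom_indices <- function(s) {
  rt <- residue_table(s)
  akey <- paste(s$atoms$chain, s$atoms$resno, sep = ":")
  lapply(rt$key, function(k) which(akey == k & s$atoms$resid != OCCLUDER_RESID))
}

# side-chain atom indices per residue (non-backbone heavy atoms; CA
# fallback for Gly and other side-chain-less residues)
sidechain_atom_indices <- function(s) {
  idx <- residue_atom_indices(s)
  lapply(idx, function(i) {
    sc <- i[!(s$atoms$elety[i] %in% BACKBONE_ATOMS) &
              s$atoms$element[i] != "H"]
    if (length(sc)) sc else i[s$atoms$elety[i] == "CA"]
  })
}

atom_coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

# minimum inter-residue distance matrix over the given per-residue atom
# index lists (exhaustive; intended for modest structure sizes)
min_distance_matrix <- function(s, index_list) {
  xyz <- atom_coords(s)
  n <- length(index_list)
  d <- matrix(0, n, n)
  cents <- t(vapply(index_list, function(i)
    colMeans(xyz[i, , drop = FALSE]), numeric(3)))
  for (i in seq_len(n - 1)) {
    xi <- xyz[index_list[[i]], , drop = FALSE]
    for (j in (i + 1):n) {
      xj <- xyz[index_list[[j]], , drop = FALSE]
      dm <- sqrt(outer(rowSums(xi^2), rowSums(xj^2), "+") -
                   2 * xi %*% t(xj))
      d[i, j] <- d[j, i] <- min(dm)
    }
  }
  d
}

#' Construct an ensemble from conformations
#'
#' @param structures list of `vhh_structure` objects sharing atom ordering
#'   and counts (checked).
#' @param id ensemble identifier.
#' @return object of class `conformation_ensemble`.
#' @export
as_ensemble <- function(structures, id = "ensemble") {
  stopifnot(length(structures) >= 1,
            all(vapply(structures, inherits, TRUE, "vhh_structure")))
  ref <- structures[[1]]$atoms
  for (s in structures[-1]) {
    same <- nrow(s$atoms) == nrow(ref) &&
      identical(s$atoms$elety, ref$elety) &&
      identical(s$atoms$resno, ref$resno) &&
      identical(s$atoms$resid, ref$resid)
    if (!same)
      stop(structure(class = c("vhh_ensemble_error", "error", "condition"),
                     list(message = "topology mismatch across conformations",
                          call = sys.call(-1))))
  }
  xyz <- t(vapply(structures, function(s) as.vector(t(atom_coords(s))),
                  numeric(3 * nrow(ref))))
  structure(list(id = id, atoms = ref[, setdiff(names(ref),
                                                c("x", "y", "z"))],
                 xyz = xyz),
            class = "conformation_ensemble")
}

#' Number of conformations in an ensemble
#' @param e a `conformation_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(e) nrow(e$xyz)

#' Extract one conformation from an ensemble
#'
#' @param e a `conformation_ensemble`.
#' @param i frame index.
#' @return a `vhh_structure`.
#' @export
get_conformation <- function(e, i) {
  stopifnot(inherits(e, "conformation_ensemble"), i >= 1, i <= n_frames(e))
  m <- matrix(e$xyz[i, ], ncol = 3, byrow = TRUE)
  atoms <- e$atoms
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  vhh_structure(atoms, id = sprintf("%s_frame%d", e$id, i))
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("conformation_ensemble '%s': %d frames, %d atoms\n",
              x$id, n_frames(x), nrow(x$atoms)))
  invisible(x)
}

#' Read a (multi-model) PDB file
#'
#' Single-model files give a `vhh_structure`; multi-model files a
#' `conformation_ensemble`.
#'
#' @param path PDB file.
#' @return `vhh_structure` or `conformation_ensemble`.
#' @export
read_structure_pdb <- function(path) {
  if (!file.exists(path))
    stop(structure(class = c("vhh_input_error", "error", "condition"),
                   list(message = paste0("input file not found: ", path),
                        call = sys.call(-1))))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom[, c("eleno", "elety", "resid", "chain", "resno",
                        "x", "y", "z")]
  atoms$chain[is.na(atoms$chain)] <- "A"
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || nmod <= 1)
    return(vhh_structure(atoms, id = basename(path)))
  top <- vhh_structure(atoms, id = basename(path))
  structures <- lapply(seq_len(nmod), function(i) {
    m <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    a <- top$atoms
    a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
    vhh_structure(a, id = sprintf("%s_%d", basename(path), i))
  })
  as_ensemble(structures, id = basename(path))
}

bio3d_from_atoms <- function(atoms) {
  n <- nrow(atoms)
  atom <- data.frame(
    type = "ATOM", eleno = atoms$eleno, elety = atoms$elety, alt = "",
    resid = atoms$resid, chain = atoms$chain, resno = atoms$resno,
    insert = "", x = atoms$x, y = atoms$y, z = atoms$z,
    o = 1, b = 0, segid = "", elesy = atoms$element, charge = "",
    stringsAsFactors = FALSE)
  atom
}

#' Write a structure or ensemble as PDB
#'
#' Ensembles are written as multi-model PDB (one MODEL record per frame).
#'
#' @param x a `vhh_structure` or `conformation_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(x, path) {
  if (inherits(x, "vhh_structure")) {
    a <- bio3d_from_atoms(x$atoms)
    bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(
      a[, c("x", "y", "z")]))), type = a$type, resno = a$resno,
      resid = a$resid, eleno = a$eleno, elety = a$elety, chain = a$chain,
      elesy = a$elesy)
  } else if (inherits(x, "conformation_ensemble")) {
    a <- x$atoms
    bio3d::write.pdb(file = path, xyz = x$xyz, type = rep("ATOM", nrow(a)),
                     resno = a$resno, resid = a$resid, eleno = a$eleno,
                     elety = a$elety, chain = a$chain, elesy = a$element)
  } else stop("x must be a vhh_structure or conformation_ensemble")
  invisible(path)
}
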