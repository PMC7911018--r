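# Residue contact maps, contact-map difference projection, and
# active-residue nomination.
#
# Contact rule (config, not code): two residues are in contact in one
# conformation when any heavy-atom pair lies closer than the cutoff
# (default 4.5 A), excluding the near-diagonal band |i-j| <= 2.  Over an
# ensemble the map entry is the fraction of conformations in contact.

#' Ensemble residue contact map
#'
#' @param e a `conformation_ensemble` (or a single `vhh_structure`, treated
#'   as a one-frame ensemble).
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @param min_sep sequence-separation exclusion: pairs with
#'   `|i - j| <= min_sep` are fixed at zero.
#' @return matrix of class `contact_map` with entries in [0, 1]; residue
#'   keys as dimnames; contact-rule parameters as attributes.
#' @export
contact_map <- function(e, cutoff = 4.5, min_sep = 2) {
  if (inherits(e, "vhh_structure")) e <- as_ensemble(list(e), id = e$id)
  stopifnot(inherits(e, "conformation_ensemble"))
  s0 <- get_conformation(e, 1)
  rt <- residue_table(s0)
  n <- nrow(rt)
  acc <- matrix(0, n, n)
  for (f in seq_len(n_frames(e))) {
    s <- get_conformation(e, f)
    idx <- residue_atom_indices(s)
    d <- min_distance_matrix(s, idx)
    acc <- acc + (d < cutoff)
  }
  cm <- acc / n_frames(e)
  band <- abs(outer(rt$resno, rt$resno, "-")) <= min_sep
  cm[band] <- 0
  dimnames(cm) <- list(rt$key, rt$key)
  structure(cm, class = c("contact_map", "matrix"),
            cutoff = cutoff, min_sep = min_sep, n_frames = n_frames(e),
            residues = rt)
}

#' Per-residue projection of a contact-map difference
#'
#' Projects the absolute difference between two contact maps onto residues:
#' with the default L1 norm, `d_i = sum_j |wt_ij - mut_ij|`.  Residues with
#' `d_i > mean(d) + k * sd(d)` form the "most affected" mask.
#'
#' @param wt,mut `contact_map` objects with identical dimensions and
#'   contact-rule parameters.
#' @param norm `"l1"` (row sum, default) or `"l2"` (row Euclidean norm).
#' @param k selection stringency in standard deviations (default 1).
#' @return data frame of class `diff_profile`: `key`, `d`, `selected`.
#' @export
contact_diff_projection <- function(wt, mut, norm = c("l1", "l2"), k = 1) {
  norm <- match.arg(norm)
  stopifnot(inherits(wt, "contact_map"), inherits(mut, "contact_map"))
  if (!all(dim(wt) == dim(mut)))
    stop("contact maps have different dimensions")
  if (!isTRUE(all.equal(attr(wt, "cutoff"), attr(mut, "cutoff"))) ||
      !identical(attr(wt, "min_sep"), attr(mut, "min_sep")))
    stop("contact maps computed under different contact rules")
  dm <- abs(unclass(wt) - unclass(mut))
  d <- if (norm == "l1") rowSums(dm) else sqrt(rowSums(dm^2))
  thr <- mean(d) + k * stats::sd(d)
  sel <- if (is.na(thr)) rep(FALSE, length(d)) else d > thr
  out <- data.frame(key = rownames(wt), d = unname(d), selected = sel,
                    stringsAsFactors = FALSE)
  attr(out, "norm") <- norm
  attr(out, "k") <- k
  class(out) <- c("diff_profile", "data.frame")
  out
}

#' Nominate active residues for docking restraints
#'
#' Combines the exposed-hydrophobic residue set with the most-affected
#' residues of a contact-map difference, then keeps the spatially clustered
#' candidates: a residue survives when at least one other candidate's side
#' chain lies within the hotspot distance.  Provenance (exposure, diff, or
#' both) is reported per residue.
#'
#' @param exposed residue keys (`chain:resno`) from [hydrophobic_exposed()],
#'   or its data frame.
#' @param diff_mask residue keys from a [contact_diff_projection()] mask,
#'   or the `diff_profile` itself (selected rows are used).
#' @param s the `vhh_structure` both sets were computed on.
#' @param distance spatial-cluster distance in Angstrom (default 6).
#' @param mode `"union"` (default) or `"intersection"` of the two sets
#'   before spatial clustering.
#' @return data frame: `key`, `provenance`, `n_neighbors`.
#' @export
nominate_active_residues <- function(exposed, diff_mask, s, distance = 6,
                                     mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (is.data.frame(exposed)) exposed <- exposed$key
  if (inherits(diff_mask, "diff_profile"))
    diff_mask <- diff_mask$key[diff_mask$selected]
  rt <- residue_table(s)
  stopifnot(all(exposed %in% rt$key), all(diff_mask %in% rt$key))
  cand <- if (mode == "union") union(exposed, diff_mask)
          else intersect(exposed, diff_mask)
  if (!length(cand))
    return(data.frame(key = character(0), provenance = character(0),
                      n_neighbors = integer(0)))
  sc <- sidechain_atom_indices(s)
  d <- min_distance_matrix(s, sc)
  ci <- match(cand, rt$key)
  dm <- d[ci, ci, drop = FALSE]
  diag(dm) <- Inf
  n_nb <- rowSums(dm <= distance)
  keep <- n_nb >= 1
  prov <- ifelse(cand %in% exposed & cand %in% diff_mask, "both",
                 ifelse(cand %in% exposed, "exposure", "diff"))
  out <- data.frame(key = cand[keep], provenance = prov[keep],
                    n_neighbors = as.integer(n_nb[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$key, rt$key)), ]
  rownames(out) <- NULL
  out
}
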