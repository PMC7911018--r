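# RMSD matrices and gromos clustering of conformational ensembles.
#
# Pairwise RMSD is computed after optimal least-squares superposition
# (closed-form Kabsch rotation; the reflection branch is handled by a
# determinant sign correction).  The clustering cutoff defaults to the mean
# of all unordered pairwise RMSDs, and clusters are extracted greedily:
# the conformation with the most neighbors within the cutoff becomes a
# cluster center, it and its neighbors are removed, and the rule repeats
# until no conformation remains.  Ties break to the lowest frame index.

#' Optimal-superposition RMSD of two coordinate sets
#'
#' @param x,y n x 3 coordinate matrices (same atom order).
#' @return least-squares-fit RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)),
            ncol(x) == 3)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  sv <- svd(crossprod(xc, yc))
  sgn <- sign(det(sv$v %*% t(sv$u)))
  sig <- sv$d
  sig[3] <- sig[3] * sgn
  msd <- (sum(xc^2) + sum(yc^2) - 2 * sum(sig)) / nrow(x)
  sqrt(max(msd, 0))
}

#' Pairwise RMSD matrix of an ensemble
#'
#' @param e a `conformation_ensemble`.
#' @param atoms atom selection: `"calpha"` (default, CA atoms only) or
#'   `"heavy"` (all non-hydrogen protein atoms).
#' @return symmetric matrix of class `rmsd_matrix` with zero diagonal.
#' @export
rmsd_matrix <- function(e, atoms = c("calpha", "heavy")) {
  atoms <- match.arg(atoms)
  stopifnot(inherits(e, "conformation_ensemble"))
  N <- n_frames(e)
  if (N < 2) stop("at least 2 conformations required")
  keep <- if (atoms == "calpha")
    which(e$atoms$elety == "CA" & e$atoms$resid != OCCLUDER_RESID)
  else
    which(e$atoms$resid != OCCLUDER_RESID &
            substr(e$atoms$elety, 1, 1) != "H")
  if (!length(keep)) stop("atom selection is empty")
  coord_idx <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
  frames <- lapply(seq_len(N), function(i)
    matrix(e$xyz[i, coord_idx], ncol = 3, byrow = TRUE))
  centered <- lapply(frames, function(m) sweep(m, 2, colMeans(m)))
  norms <- vapply(centered, function(m) sum(m^2), 0)
  n_at <- length(keep)
  m <- matrix(0, N, N)
  for (i in seq_len(N - 1)) {
    xi <- centered[[i]]
    for (j in (i + 1):N) {
      sv <- svd(crossprod(xi, centered[[j]]))
      sig <- sv$d
      sig[3] <- sig[3] * sign(det(sv$v %*% t(sv$u)))
      msd <- (norms[i] + norms[j] - 2 * sum(sig)) / n_at
      m[i, j] <- m[j, i] <- sqrt(max(msd, 0))
    }
  }
  structure(m, class = c("rmsd_matrix", "matrix"),
            atoms = atoms, n_atoms = n_at)
}

#' Automatic clustering cutoff from an RMSD matrix
#'
#' The mean of the strictly off-diagonal upper-triangle entries, i.e. the
#' average RMSD over all unordered conformation pairs.
#'
#' @param m a symmetric RMSD matrix.
#' @return cutoff in Angstrom.
#' @export
auto_cutoff <- function(m) {
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (nrow(m) < 2) stop("at least 2 conformations required")
  mean(m[upper.tri(m)])
}

#' Greedy neighbor-count (gromos) clustering
#'
#' @param m RMSD matrix.
#' @param cutoff neighbor cutoff in Angstrom (> 0); conformations within
#'   `cutoff` (inclusive) are neighbors.
#' @return list of class `cluster_result`: `labels` (cluster id per frame,
#'   1 = first-extracted = largest), `sizes`, `centers` (frame index of
#'   each cluster's center), `cutoff`.
#' @export
gromos_cluster <- function(m, cutoff) {
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), cutoff > 0)
  N <- nrow(m)
  adj <- m <= cutoff
  diag(adj) <- TRUE
  remaining <- seq_len(N)
  labels <- integer(N)
  centers <- integer(0)
  k <- 0
  while (length(remaining)) {
    counts <- rowSums(adj[remaining, remaining, drop = FALSE])
    center <- remaining[which.max(counts)]   # ties -> lowest index
    members <- remaining[adj[center, remaining]]
    k <- k + 1
    labels[members] <- k
    centers[k] <- center
    remaining <- setdiff(remaining, members)
  }
  sizes <- as.integer(table(factor(labels, levels = seq_len(k))))
  structure(list(labels = labels, sizes = sizes, centers = centers,
                 cutoff = cutoff, n = N),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d frames, %d clusters (cutoff %.3f A)\n",
              x$n, length(x$sizes), x$cutoff))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Representative conformations of a clustering
#'
#' Each cluster is represented by its gromos center (the member that had
#' the maximal within-cutoff neighbor count when the cluster was
#' extracted); the overall reference conformation is the center of the
#' largest (first) cluster.
#'
#' @param e the clustered `conformation_ensemble`.
#' @param result a `cluster_result` from [gromos_cluster()].
#' @return list with `frames` (center frame index per cluster),
#'   `reference_frame`, and `reference` (the reference `vhh_structure`).
#' @export
select_representative <- function(e, result) {
  stopifnot(inherits(e, "conformation_ensemble"),
            inherits(result, "cluster_result"),
            n_frames(e) == result$n)
  list(frames = result$centers,
       reference_frame = result$centers[1],
       reference = get_conformation(e, result$centers[1]))
}
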