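# Position-anchored mutation sets and numbering-aligned difference
# accounting.
#
# All comparisons are by scheme position, never by gap-optimizing global
# alignment: the constructs this package manipulates are residue-anchored
# (a substitution at 89 stays at 89 whatever the loop lengths), so the
# position-wise diff reproduces the field's counting deterministically.

empty_subs <- function()
  data.frame(scheme_pos = character(0), from = character(0),
             to = character(0), stringsAsFactors = FALSE)
empty_indel <- function()
  data.frame(scheme_pos = character(0), residue = character(0),
             stringsAsFactors = FALSE)

#' Build a mutation set
#'
#' A mutation set is a position-anchored recipe: substitutions
#' (`scheme_pos`, `from`, `to`), insertions (`scheme_pos`, `residue`) and
#' deletions (`scheme_pos`, `residue`). No two entries may share a scheme
#' position within the same category.  Applying a set and then its
#' [invert_mutations()] restores the original sequence exactly.
#'
#' @param substitutions data frame with columns `scheme_pos`, `from`, `to`,
#'   or `NULL`.
#' @param insertions,deletions data frames with columns `scheme_pos`,
#'   `residue`, or `NULL`.
#' @return object of class `mutation_set`.
#' @export
mutation_set <- function(substitutions = NULL, insertions = NULL,
                         deletions = NULL) {
  sub <- if (is.null(substitutions)) empty_subs() else
    data.frame(scheme_pos = as.character(substitutions$scheme_pos),
               from = substitutions$from, to = substitutions$to,
               stringsAsFactors = FALSE)
  ins <- if (is.null(insertions)) empty_indel() else
    data.frame(scheme_pos = as.character(insertions$scheme_pos),
               residue = insertions$residue, stringsAsFactors = FALSE)
  del <- if (is.null(deletions)) empty_indel() else
    data.frame(scheme_pos = as.character(deletions$scheme_pos),
               residue = deletions$residue, stringsAsFactors = FALSE)
  for (d in list(sub, ins, del))
    if (anyDuplicated(d$scheme_pos))
      stop("duplicated scheme position within one mutation category")
  if (nrow(sub) && any(sub$from == sub$to))
    stop("substitution with identical from/to residue")
  structure(list(substitutions = sub, insertions = ins, deletions = del),
            class = "mutation_set")
}

#' @export
print.mutation_set <- function(x, ...) {
  cat(sprintf("mutation_set: %d substitutions, %d insertions, %d deletions\n",
              nrow(x$substitutions), nrow(x$insertions), nrow(x$deletions)))
  if (nrow(x$substitutions))
    cat("  sub:", paste0(x$substitutions$from, x$substitutions$scheme_pos,
                         x$substitutions$to, collapse = " "), "\n")
  if (nrow(x$insertions))
    cat("  ins:", paste0(x$insertions$scheme_pos, x$insertions$residue,
                         collapse = " "), "\n")
  if (nrow(x$deletions))
    cat("  del:", paste0(x$deletions$scheme_pos, x$deletions$residue,
                         collapse = " "), "\n")
  invisible(x)
}

#' Invert a mutation set
#'
#' Swaps from/to of every substitution and exchanges insertions with
#' deletions, so that `apply_mutations(apply_mutations(v, m),
#' invert_mutations(m))` is byte-identical to `v`.
#'
#' @param m a `mutation_set`.
#' @return the inverse `mutation_set`.
#' @export
invert_mutations <- function(m) {
  stopifnot(inherits(m, "mutation_set"))
  mutation_set(
    substitutions = data.frame(scheme_pos = m$substitutions$scheme_pos,
                               from = m$substitutions$to,
                               to = m$substitutions$from,
                               stringsAsFactors = FALSE),
    insertions = m$deletions,
    deletions = m$insertions)
}

#' Apply a mutation set to a numbered sequence
#'
#' Substitutions require the current residue to match `from` (a stale set
#' fails with an error listing the offending positions, so re-applying a
#' set is impossible). Insertions require the scheme position to be vacant,
#' deletions require the recorded residue.  The result is renumbered
#' bookkeeping-free: residues keep their scheme positions, inserted
#' positions take the region their base number falls in.
#'
#' @param vhh a `vhh_sequence`.
#' @param m a `mutation_set`.
#' @return a new `vhh_sequence` (id suffixed with `_mut` unless `id` given).
#' @param id optional identifier for the mutated sequence.
#' @export
apply_mutations <- function(vhh, m, id = paste0(vhh$id, "_mut")) {
  stopifnot(inherits(vhh, "vhh_sequence"), inherits(m, "mutation_set"))
  res <- vhh_named(vhh)

  if (nrow(m$substitutions)) {
    cur <- unname(res[m$substitutions$scheme_pos])
    stale <- is.na(cur) | cur != m$substitutions$from
    if (any(stale))
      stop(structure(
        class = c("vhh_stale_mutation", "error", "condition"),
        list(message = paste0(
          "stale mutation(s) for ", vhh$id, " at position(s) ",
          paste(m$substitutions$scheme_pos[stale], collapse = ", "),
          ": expected ", paste(m$substitutions$from[stale], collapse = ","),
          ", found ", paste(ifelse(is.na(cur[stale]), "-", cur[stale]),
                            collapse = ",")),
          call = sys.call(-1))))
    res[m$substitutions$scheme_pos] <- m$substitutions$to
  }
  if (nrow(m$deletions)) {
    cur <- unname(res[m$deletions$scheme_pos])
    bad <- is.na(cur) | cur != m$deletions$residue
    if (bad_any <- any(bad))
      stop("deletion mismatch at position(s) ",
           paste(m$deletions$scheme_pos[bad], collapse = ", "))
    res <- res[setdiff(names(res), m$deletions$scheme_pos)]
  }
  if (nrow(m$insertions)) {
    occupied <- m$insertions$scheme_pos %in% names(res)
    if (any(occupied))
      stop("insertion at occupied position(s) ",
           paste(m$insertions$scheme_pos[occupied], collapse = ", "))
    res <- c(res, stats::setNames(m$insertions$residue,
                                  m$insertions$scheme_pos))
  }
  res <- res[order(scheme_key(names(res)))]
  structure(list(id = id, residues = unname(res), positions = names(res),
                 regions = region_of_position(names(res), vhh$scheme),
                 scheme = vhh$scheme),
            class = "vhh_sequence")
}

#' Numbering-aligned difference between two sequences
#'
#' Compares two numbered sequences position by position.  `diff_sequences(a,
#' b)` returns the mutation set that transforms `b` into `a`: substitutions
#' where both carry a residue and the residues differ, insertions at
#' positions present only in `a`, deletions at positions present only in
#' `b`.  Each substitution is additionally labeled with its region and with
#' the species-fingerprint class of the `a`-side residue.
#'
#' @param a,b `vhh_sequence` objects numbered under the same scheme.
#' @param scope optional character vector of region names restricting the
#'   comparison (e.g. `c("FW1","FW2","FW3","FW4")` for a framework-only
#'   diff); default all regions.
#' @param ref fingerprint reference for classification.
#' @return object of class `sequence_diff` (also a `mutation_set`), with
#'   counts `n_sub`, `n_ins`, `n_del` and a labeled substitution table.
#' @examples
#' pan <- vhh_reference_panel()
#' d <- diff_sequences(pan$A10, pan$C8WT, scope = paste0("FW", 1:4))
#' d$n_sub  # 14
#' @export
diff_sequences <- function(a, b, scope = NULL,
                           ref = default_fingerprints()) {
  stopifnot(inherits(a, "vhh_sequence"), inherits(b, "vhh_sequence"))
  ra <- vhh_named(a); rb <- vhh_named(b)
  all_pos <- union(names(ra), names(rb))
  all_pos <- all_pos[order(scheme_key(all_pos))]
  if (!is.null(scope)) {
    stopifnot(all(scope %in% REGION_NAMES))
    all_pos <- all_pos[region_of_position(all_pos, a$scheme) %in% scope]
  }
  in_a <- all_pos %in% names(ra)
  in_b <- all_pos %in% names(rb)

  both <- all_pos[in_a & in_b]
  differs <- both[ra[both] != rb[both]]
  sub <- data.frame(scheme_pos = differs, from = unname(rb[differs]),
                    to = unname(ra[differs]), stringsAsFactors = FALSE)
  ins_pos <- all_pos[in_a & !in_b]
  del_pos <- all_pos[!in_a & in_b]
  m <- mutation_set(
    substitutions = sub,
    insertions = data.frame(scheme_pos = ins_pos,
                            residue = unname(ra[ins_pos]),
                            stringsAsFactors = FALSE),
    deletions = data.frame(scheme_pos = del_pos,
                           residue = unname(rb[del_pos]),
                           stringsAsFactors = FALSE))
  m$substitutions$region <- region_of_position(m$substitutions$scheme_pos,
                                               a$scheme)
  m$substitutions$fingerprint <- classify_residue(m$substitutions$scheme_pos,
                                                  m$substitutions$to, ref)
  m$a_id <- a$id; m$b_id <- b$id
  m$n_sub <- nrow(m$substitutions)
  m$n_ins <- nrow(m$insertions)
  m$n_del <- nrow(m$deletions)
  class(m) <- c("sequence_diff", "mutation_set")
  m
}

#' @export
print.sequence_diff <- function(x, ...) {
  cat(sprintf("sequence_diff %s vs %s: %d substitutions, %d insertions, %d deletions\n",
              x$a_id, x$b_id, x$n_sub, x$n_ins, x$n_del))
  if (x$n_sub) print(x$substitutions, row.names = FALSE)
  invisible(x)
}

#' Write a diff report as TSV
#'
#' One row per substitution (`scheme_pos`, `from`, `to`, `region`,
#' `fingerprint`) followed by insertion/deletion rows marked in the
#' `change` column.
#'
#' @param d a `sequence_diff`.
#' @param path output file.
#' @return the report data frame, invisibly.
#' @export
write_diff_tsv <- function(d, path) {
  stopifnot(inherits(d, "sequence_diff"))
  rows <- list()
  if (d$n_sub)
    rows$sub <- data.frame(change = "substitution", d$substitutions,
                           stringsAsFactors = FALSE)
  if (d$n_ins)
    rows$ins <- data.frame(change = "insertion",
                           scheme_pos = d$insertions$scheme_pos,
                           from = "-", to = d$insertions$residue,
                           region = region_of_position(
                             d$insertions$scheme_pos, default_scheme()),
                           fingerprint = "unclassified",
                           stringsAsFactors = FALSE)
  if (d$n_del)
    rows$del <- data.frame(change = "deletion",
                           scheme_pos = d$deletions$scheme_pos,
                           from = d$deletions$residue, to = "-",
                           region = region_of_position(
                             d$deletions$scheme_pos, default_scheme()),
                           fingerprint = "unclassified",
                           stringsAsFactors = FALSE)
  rep_df <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(change = character(0), scheme_pos = character(0),
               from = character(0), to = character(0),
               region = character(0), fingerprint = character(0))
  utils::write.table(rep_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rep_df)
}
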