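# CDR grafting and variant-panel construction.

#' Graft donor CDRs onto an acceptor scaffold
#'
#' Builds the chimera carrying the acceptor's four framework segments and
#' the donor's three CDR loops verbatim, renumbered from scratch under the
#' acceptor's scheme.  Residue provenance is recorded in the `provenance`
#' attribute (`"donor"`/`"acceptor"` per residue).
#'
#' @param donor,acceptor `vhh_sequence` objects.
#' @param id identifier of the chimera (default `<donor>g<acceptor>`).
#' @return a `vhh_sequence` with a `provenance` attribute.
#' @examples
#' pan <- vhh_reference_panel()
#' a10c <- graft_cdrs(pan$A10, pan$C8WT)
#' detect_hallmarks(a10c)$classification  # "human": the scaffold's tetrad
#' @export
graft_cdrs <- function(donor, acceptor,
                       id = paste0(donor$id, "g", acceptor$id)) {
  stopifnot(inherits(donor, "vhh_sequence"), inherits(acceptor, "vhh_sequence"))
  pieces <- list(FW1 = acceptor, CDR1 = donor, FW2 = acceptor,
                 CDR2 = donor, FW3 = acceptor, CDR3 = donor, FW4 = acceptor)
  seq <- paste(vapply(REGION_NAMES,
                      function(r) vhh_region(pieces[[r]], r), ""),
               collapse = "")
  lens <- vapply(REGION_NAMES,
                 function(r) sum(pieces[[r]]$regions == r), 0L)
  out <- tryCatch(
    number_vhh(seq, id = id, scheme = acceptor$scheme,
               region_lengths = lens),
    vhh_numbering_error = function(e) stop(structure(
      class = c("vhh_graft_failure", "error", "condition"),
      list(message = paste0("graft failure for ", id, ": ",
                            conditionMessage(e)),
           call = sys.call(-1)))))
  attr(out, "provenance") <- ifelse(grepl("^CDR", out$regions),
                                    "donor", "acceptor")
  out
}

#' Build a panel of graft-derived variants
#'
#' Starting from the plain CDR graft of `donor` onto `acceptor`, emits the
#' requested chimeric variants: the hallmark tetrad can be forced to the
#' camelid (FERF) or human (VGLW) state, and the configured fingerprint
#' positions can be forced to their human-type or llama-type residues.
#' Every variant carries the `mutation_set` relating it to the plain graft
#' in its `design` attribute, so the construction is auditable with
#' [diff_sequences()].
#'
#' @param donor,acceptor `vhh_sequence` objects.
#' @param hallmarks target hallmark state: `"none"` (keep the scaffold's),
#'   `"camelid"` or `"human"`.
#' @param fingerprints target fingerprint state for `fingerprint_positions`:
#'   `"none"`, `"human"` or `"llama"` (the first residue of the reference
#'   set is used as the target).
#' @param fingerprint_positions scheme positions mutated when
#'   `fingerprints != "none"`; default the four classic sites 35/50/89/91.
#' @param ref fingerprint reference table.
#' @param id identifier for the variant.
#' @return named list of `vhh_sequence` objects: always `graft`, plus
#'   `variant` when any option is active.
#' @export
build_variant_panel <- function(donor, acceptor,
                                hallmarks = c("none", "camelid", "human"),
                                fingerprints = c("none", "human", "llama"),
                                fingerprint_positions = c("35", "50", "89", "91"),
                                ref = default_fingerprints(),
                                id = NULL) {
  hallmarks <- match.arg(hallmarks)
  fingerprints <- match.arg(fingerprints)
  graft <- graft_cdrs(donor, acceptor)
  if (hallmarks == "none" && fingerprints == "none")
    return(list(graft = graft))

  subs <- empty_subs()
  if (hallmarks != "none") {
    target <- if (hallmarks == "camelid") HALLMARK_CAMELID else HALLMARK_HUMAN
    cur <- residue_at(graft, HALLMARK_POSITIONS)
    change <- cur != target
    subs <- rbind(subs, data.frame(scheme_pos = HALLMARK_POSITIONS[change],
                                   from = cur[change],
                                   to = unname(target[change]),
                                   stringsAsFactors = FALSE))
  }
  if (fingerprints != "none") {
    clash <- intersect(fingerprint_positions, subs$scheme_pos)
    if (length(clash))
      stop(structure(
        class = c("vhh_design_conflict", "error", "condition"),
        list(message = paste0(
          "design conflict: position(s) ", paste(clash, collapse = ", "),
          " targeted by both the hallmark and the fingerprint option"),
          call = sys.call(-1))))
    i <- match(fingerprint_positions, ref$scheme_pos)
    if (anyNA(i))
      stop("fingerprint position(s) absent from reference: ",
           paste(fingerprint_positions[is.na(i)], collapse = ", "))
    target <- vapply(ref[[fingerprints]][i], `[`, "", 1)
    cur <- residue_at(graft, fingerprint_positions)
    change <- !is.na(cur) & cur != target
    subs <- rbind(subs, data.frame(scheme_pos = fingerprint_positions[change],
                                   from = cur[change], to = target[change],
                                   stringsAsFactors = FALSE))
  }
  design <- mutation_set(substitutions = subs)
  variant <- apply_mutations(graft, design,
                             id = if (is.null(id))
                               paste0(graft$id, "_", hallmarks, "_",
                                      fingerprints) else id)
  attr(variant, "design") <- design
  list(graft = graft, variant = variant)
}
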