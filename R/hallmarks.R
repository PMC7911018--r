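# Framework-2 hallmark tetrad detection and species-fingerprint
# classification.
#
# The four FW2 positions 37/44/45/47 carry F,E,R,F in camelid heavy-chain-only
# variable domains and V,G,L,W in conventional human VH domains; anything else
# is a hybrid signature.  Fingerprint positions are framework sites whose
# residue identity is characteristic of the llama or the human germline
# (e.g. llama Tyr35/Ser50/Leu89/Phe91 versus human Gly35/Ala50/Val89/Tyr91);
# the reference sets ship as a versioned TSV and are swappable.

HALLMARK_POSITIONS <- c("37", "44", "45", "47")
HALLMARK_CAMELID <- c(`37` = "F", `44` = "E", `45` = "R", `47` = "F")
HALLMARK_HUMAN   <- c(`37` = "V", `44` = "G", `45` = "L", `47` = "W")

#' Detect the FW2 hallmark tetrad
#'
#' Reads the residues at scheme positions 37, 44, 45 and 47 and classifies
#' the signature as `camelid` (FERF), `human` (VGLW) or `hybrid` (any other
#' combination).  Classification depends only on these four framework
#' positions, never on CDR contents.
#'
#' @param vhh a `vhh_sequence`.
#' @return A list of class `hallmark_state` with elements `tetrad` (named
#'   character vector) and `classification`.
#' @examples
#' pan <- vhh_reference_panel()
#' detect_hallmarks(pan$A10)$classification   # "camelid"
#' detect_hallmarks(pan$C8WT)$classification  # "human"
#' @export
detect_hallmarks <- function(vhh) {
  stopifnot(inherits(vhh, "vhh_sequence"))
  tetrad <- stats::setNames(residue_at(vhh, HALLMARK_POSITIONS),
                            HALLMARK_POSITIONS)
  if (anyNA(tetrad))
    stop(structure(
      class = c("vhh_incomplete_framework", "error", "condition"),
      list(message = paste0(
        "incomplete framework: hallmark position(s) ",
        paste(HALLMARK_POSITIONS[is.na(tetrad)], collapse = ", "),
        " missing from the numbering of ", vhh$id),
        call = sys.call(-1))))
  classification <-
    if (identical(unname(tetrad), unname(HALLMARK_CAMELID))) "camelid"
    else if (identical(unname(tetrad), unname(HALLMARK_HUMAN))) "human"
    else "hybrid"
  structure(list(tetrad = tetrad, classification = classification),
            class = "hallmark_state")
}

#' @export
print.hallmark_state <- function(x, ...) {
  cat(sprintf("hallmark tetrad 37/44/45/47: %s -> %s\n",
              paste(x$tetrad, collapse = ""), x$classification))
  invisible(x)
}

#' Species-fingerprint reference table
#'
#' Per-position sets of residues considered human-type or llama-type.
#' The shipped default covers the framework positions the package's
#' difference accounting classifies; both sets are disjoint at every
#' position.
#'
#' @param path optional path to an alternative TSV with columns
#'   `scheme_pos`, `human`, `llama` (comma-separated residue sets).
#' @return data frame of class `fingerprint_ref` with list-columns `human`
#'   and `llama`.
#' @export
default_fingerprints <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fingerprints_default.tsv",
                        package = "vhhumanize")
  ref <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  ref$human <- strsplit(ref$human, ",", fixed = TRUE)
  ref$llama <- strsplit(ref$llama, ",", fixed = TRUE)
  overlap <- mapply(function(h, l) length(intersect(h, l)) > 0,
                    ref$human, ref$llama)
  if (any(overlap))
    stop("fingerprint reference has overlapping human/llama sets at ",
         paste(ref$scheme_pos[overlap], collapse = ", "))
  class(ref) <- c("fingerprint_ref", "data.frame")
  ref
}

#' Classify a residue against the species fingerprints
#'
#' @param scheme_pos scheme position string(s).
#' @param residue one-letter code(s), recycled against `scheme_pos`.
#' @param ref reference table from [default_fingerprints()].
#' @return character vector: `"human-type"`, `"llama-type"` or
#'   `"unclassified"` (position absent from the reference, residue in
#'   neither set, or residue `X`).
#' @examples
#' classify_residue("35", "Y")  # llama-type
#' classify_residue("50", "A")  # human-type
#' @export
classify_residue <- function(scheme_pos, residue,
                             ref = default_fingerprints()) {
  n <- max(length(scheme_pos), length(residue))
  scheme_pos <- rep_len(as.character(scheme_pos), n)
  residue <- rep_len(residue, n)
  i <- match(scheme_pos, ref$scheme_pos)
  out <- rep("unclassified", n)
  known <- which(!is.na(i) & residue != "X")
  is_human <- vapply(known, function(ix)
    residue[ix] %in% ref$human[[i[ix]]], TRUE)
  is_llama <- vapply(known, function(ix)
    residue[ix] %in% ref$llama[[i[ix]]], TRUE)
  out[known[is_human]] <- "human-type"
  out[known[is_llama]] <- "llama-type"
  out
}
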