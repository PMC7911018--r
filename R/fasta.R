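# FASTA plumbing (Biostrings-backed).

#' Read amino-acid sequences from FASTA
#'
#' @param path FASTA file (one or more records; ids preserved verbatim).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop(structure(class = c("vhh_input_error", "error", "condition"),
                   list(message = paste0("input file not found: ", path),
                        call = sys.call(-1))))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0)
    stop(structure(class = c("vhh_input_error", "error", "condition"),
                   list(message = paste0("empty FASTA input: ", path),
                        call = sys.call(-1))))
  stats::setNames(as.character(set), names(set))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or a list of `vhh_sequence` objects
#'   (ids become record names).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs) && all(vapply(seqs, inherits, TRUE, "vhh_sequence")))
    seqs <- stats::setNames(vapply(seqs, as.character, ""),
                            vapply(seqs, function(s) s$id, ""))
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
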