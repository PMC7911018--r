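# Synthetic VHH sequence generation with planted ground truth.
#
# The generator is first-class, tested code: every sequence it emits comes
# with the hallmark state, fingerprint assignments and region lengths it was
# built from, so downstream stages can be verified closed-loop.

# run expr under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Scaffold framework residues shared by the synthetic constructs: a
# human-like VHH framework written position -> residue.  FW2 reads like a
# genuine human VH3 framework-2 (…WVRQAPGKGLEWVA…) so hallmark/fingerprint
# positions carry realistic context.
scaffold_framework <- function() {
  fw <- character(0)
  put <- function(fw, lo, letters) {
    stats::setNames(c(fw, strsplit(letters, "")[[1]]),
                    c(names(fw), seq(lo, lo + nchar(letters) - 1)))
  }
  fw <- put(fw, 1,  "QVQLQESGGGLVQPGGSLRLSCAAS")   # FW1 1-25
  fw <- put(fw, 33, "AMYWVRQAPGKGLEWVASI")          # FW2 33-51
  fw <- put(fw, 57, "STYYADSVKGRFTISRDANSKLTVYLKMNSLKLPFDTA") # FW3 57-94
  fw <- put(fw, 104, "GQGTQVTVSS")                  # FW4 104-113 (no 103)
  fw
}

# A10-side framework overrides: the 14 positions where the camelid-library
# donor differs from the scaffold, 7 human-type + 7 llama-type, plus the
# FW4-start Trp insertion at 103.
DONOR_FW_OVERRIDES <- c(`1` = "E", `5` = "V", `11` = "V", `35` = "G",
                        `37` = "F", `44` = "E", `45` = "R", `47` = "F",
                        `50` = "A", `74` = "K", `78` = "V", `83` = "R",
                        `89` = "T", `91` = "Y")

assemble_vhh <- function(fw_named, cdr1, cdr2, cdr3, fw4_trp, id,
                         scheme = default_scheme()) {
  fw <- fw_named
  if (fw4_trp) fw <- c(fw, `103` = "W")
  fw <- fw[order(scheme_key(names(fw)))]
  reg <- region_of_position(names(fw), scheme)
  seq <- paste0(paste(fw[reg == "FW1"], collapse = ""), cdr1,
                paste(fw[reg == "FW2"], collapse = ""), cdr2,
                paste(fw[reg == "FW3"], collapse = ""), cdr3,
                paste(fw[reg == "FW4"], collapse = ""))
  number_vhh(seq, id = id, scheme = scheme,
             region_lengths = c(CDR1 = nchar(cdr1), CDR2 = nchar(cdr2),
                                CDR3 = nchar(cdr3),
                                FW4 = sum(reg == "FW4")))
}

#' Synthetic humanization reference panel
#'
#' Deterministically builds the seven-construct panel the package's examples
#' and tests revolve around: a camelid-hallmark donor (`A10`), a
#' human-hallmark acceptor scaffold (`C8WT`), its fully humanized (`C8H`)
#' and hallmark-camelized (`C8VI`) mutants, the plain CDR graft (`A10C`),
#' and the two intermediate chimeras (`A10VI`, `A10-HLL`).  All sequences
#' are synthetic stand-ins constructed so that the panel's difference
#' accounting has known ground truth:
#'
#' * `diff(A10, C8WT)` restricted to the frameworks: 14 substitutions
#'   (7 human-type, 7 llama-type fingerprints) plus the Trp insertion at
#'   the start of FW4 (position 103);
#' * `diff(A10VI, A10)`: 4 substitutions (positions 11, 35, 78, 89) and
#'   the deletion of Tyr102;
#' * `diff(A10-HLL, A10C)`: 8 substitutions; `diff(A10-HLL, A10VI)`: 4.
#'
#' @return named list of `vhh_sequence` objects with a `ground_truth`
#'   attribute recording the planted counts.
#' @examples
#' pan <- vhh_reference_panel()
#' diff_sequences(pan$A10VI, pan$A10)$n_sub  # 4
#' @export
vhh_reference_panel <- function() {
  scheme <- default_scheme()
  fw_acceptor <- scaffold_framework()
  fw_donor <- fw_acceptor
  fw_donor[names(DONOR_FW_OVERRIDES)] <- DONOR_FW_OVERRIDES

  donor_cdr1 <- "GRTFSSY"; donor_cdr2 <- "INSGG"; donor_cdr3 <- "ARDSRGYY"
  acc_cdr1 <- "GSIFSIN";   acc_cdr2 <- "TYSGG";   acc_cdr3 <- "GLPWNRF"

  A10 <- assemble_vhh(fw_donor, donor_cdr1, donor_cdr2, donor_cdr3,
                      fw4_trp = TRUE, id = "A10", scheme = scheme)
  C8WT <- assemble_vhh(fw_acceptor, acc_cdr1, acc_cdr2, acc_cdr3,
                       fw4_trp = FALSE, id = "C8WT", scheme = scheme)

  # full humanization of the acceptor's llama-type framework residues
  ref <- default_fingerprints()
  llama_pos <- c("1", "5", "35", "50", "74", "83", "89", "91")
  h_target <- c(`1` = "E", `5` = "V", `35` = "S", `50` = "A",
                `74` = "K", `83` = "R", `89` = "V", `91` = "Y")
  C8H <- apply_mutations(C8WT, mutation_set(substitutions = data.frame(
    scheme_pos = llama_pos,
    from = residue_at(C8WT, llama_pos),
    to = unname(h_target[llama_pos]))), id = "C8H")

  hallmark_swap <- mutation_set(substitutions = data.frame(
    scheme_pos = HALLMARK_POSITIONS,
    from = unname(HALLMARK_HUMAN), to = unname(HALLMARK_CAMELID)))
  C8VI <- apply_mutations(C8H, hallmark_swap, id = "C8VI")

  A10C <- graft_cdrs(A10, C8WT, id = "A10C")

  A10VI <- apply_mutations(A10, mutation_set(
    substitutions = data.frame(scheme_pos = c("11", "35", "78", "89"),
                               from = c("V", "G", "V", "T"),
                               to = c("L", "S", "L", "V")),
    deletions = data.frame(scheme_pos = "102", residue = "Y")),
    id = "A10VI")

  A10HLL <- apply_mutations(A10C, mutation_set(substitutions = data.frame(
    scheme_pos = c(HALLMARK_POSITIONS, "35", "50", "89", "91"),
    from = c(unname(HALLMARK_HUMAN), "Y", "S", "L", "F"),
    to = c(unname(HALLMARK_CAMELID), "S", "A", "V", "Y"))),
    id = "A10-HLL")

  pan <- list(A10 = A10, C8WT = C8WT, C8H = C8H, C8VI = C8VI,
              A10C = A10C, A10VI = A10VI, `A10-HLL` = A10HLL)
  attr(pan, "ground_truth") <- list(
    fw_diff = c(n_sub = 14L, n_ins = 1L, n_del = 0L),
    fingerprint_split = c(`human-type` = 7L, `llama-type` = 7L),
    a10vi_vs_a10 = c(n_sub = 4L, n_ins = 0L, n_del = 1L),
    a10vi_sub_positions = c("11", "35", "78", "89"),
    hll_vs_a10c = 8L, hll_vs_a10vi = 4L)
  pan
}

#' Generate a synthetic VHH sequence with planted annotation
#'
#' Builds a VHH-like sequence on the shared synthetic scaffold with a
#' controllable hallmark state, fingerprint assignments and region lengths;
#' CDR loops are drawn at random under the given seed.  Identical seed and
#' specification give byte-identical output.
#'
#' @param hallmarks `"camelid"`, `"human"` or `"hybrid"` (hybrid plants
#'   F/G/L/W).
#' @param fingerprints named character vector mapping fingerprint scheme
#'   positions to `"human"` or `"llama"`, e.g. `c("35" = "llama")`; the
#'   first residue of the reference set is planted.
#' @param cdr_lengths named integer vector (`CDR1`, `CDR2`, `CDR3`).
#' @param seed integer seed for the random loop residues.
#' @param id sequence identifier.
#' @param ref fingerprint reference.
#' @return a `vhh_sequence` with a `ground_truth` attribute (planted
#'   hallmark state, fingerprint residues, region lengths).
#' @export
make_vhh_sequence <- function(hallmarks = "camelid", fingerprints = NULL,
                              cdr_lengths = c(CDR1 = 7, CDR2 = 5, CDR3 = 8),
                              seed = 1, id = "synthetic",
                              ref = default_fingerprints()) {
  stopifnot(hallmarks %in% c("camelid", "human", "hybrid"))
  fw <- scaffold_framework()   # 103 is added by assemble_vhh (fw4_trp)
  tet <- switch(hallmarks,
                camelid = HALLMARK_CAMELID,
                human = HALLMARK_HUMAN,
                hybrid = c(`37` = "F", `44` = "G", `45` = "L", `47` = "W"))
  fw[names(tet)] <- tet
  planted_fp <- character(0)
  if (!is.null(fingerprints)) {
    bad <- setdiff(names(fingerprints), ref$scheme_pos)
    if (length(bad) || any(names(fingerprints) %in% HALLMARK_POSITIONS))
      stop("contradictory specification: fingerprint position(s) ",
           paste(union(bad, intersect(names(fingerprints),
                                      HALLMARK_POSITIONS)), collapse = ", "))
    for (p in names(fingerprints)) {
      set <- ref[[fingerprints[[p]]]][[match(p, ref$scheme_pos)]]
      fw[p] <- set[1]
      planted_fp[p] <- set[1]
    }
  }
  loops <- with_seed(seed, lapply(cdr_lengths, function(L)
    paste(sample(setdiff(AA20, "C"), L, replace = TRUE), collapse = "")))
  out <- assemble_vhh(fw, loops$CDR1, loops$CDR2, loops$CDR3,
                      fw4_trp = TRUE, id = id)
  attr(out, "ground_truth") <- list(hallmarks = hallmarks, tetrad = tet,
                                    fingerprints = planted_fp,
                                    cdr_lengths = cdr_lengths, seed = seed)
  out
}
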