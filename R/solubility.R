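# Per-residue solubility profiling and aggregation-hotspot detection.
#
# The intrinsic scorer is a documented surrogate: a z-scaled, 7-residue
# smoothed combination of Kyte-Doolittle hydropathy, Henderson-Hasselbalch
# side-chain charge (charge promotes solubility) and Chou-Fasman beta-sheet
# propensity.  Negative values mean poorly soluble.  All reports label
# these scores "surrogate-intrinsic"; externally computed per-residue
# profiles can be supplied instead, keyed by scheme position.  The
# package's contribution - structural correction over a spatial patch and
# hotspot construction/scoring - is scorer-agnostic.

moving_average <- function(x, window) {
  half <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, 0)
}

#' Intrinsic per-residue solubility profile (surrogate scorer)
#'
#' @param vhh a `vhh_sequence`, or a plain amino-acid string.
#' @param pH solution pH; enters only the charge term (default 7).
#' @param window smoothing window in residues (default 7, centered,
#'   shrinking at the termini).
#' @param weights named numeric vector with elements `hydropathy`,
#'   `charge`, `beta`.
#' @return data frame of class `solubility_profile`: `scheme_pos` (or
#'   index), `residue`, `intrinsic` (z-scaled; negative = poorly soluble).
#' @examples
#' p <- intrinsic_profile(make_vhh_sequence(seed = 3))
#' head(p)
#' @export
intrinsic_profile <- function(vhh, pH = 7, window = 7,
                              weights = c(hydropathy = 1, charge = 0.5,
                                          beta = 0.5)) {
  if (is.character(vhh) && length(vhh) == 1)
    vhh <- list(id = "seq", residues = strsplit(toupper(vhh), "")[[1]],
                positions = as.character(seq_len(nchar(vhh))))
  res <- vhh$residues
  kd <- ifelse(res %in% names(KD_HYDROPATHY), KD_HYDROPATHY[res], 0)
  q <- abs(sidechain_charge(res, pH))
  beta <- ifelse(res %in% names(BETA_PROPENSITY),
                 BETA_PROPENSITY[res], 1) - 1
  raw <- -weights["hydropathy"] * kd + weights["charge"] * q -
    weights["beta"] * beta
  sm <- moving_average(unname(raw), window)
  sdv <- stats::sd(sm)
  z <- if (is.na(sdv) || sdv < 1e-12) sm - mean(sm) else
    (sm - mean(sm)) / sdv
  out <- data.frame(scheme_pos = vhh$positions, residue = res,
                    intrinsic = z, stringsAsFactors = FALSE)
  attr(out, "scorer") <- "surrogate-intrinsic"
  attr(out, "parameters") <- list(pH = pH, window = window,
                                  weights = weights)
  class(out) <- c("solubility_profile", "data.frame")
  out
}

#' Import an externally computed per-residue profile
#'
#' TSV with columns `scheme_pos` and `intrinsic` (and optionally
#' `residue`); bypasses the surrogate scorer.
#'
#' @param path TSV file.
#' @return a `solubility_profile` labeled `"external"`.
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(scheme_pos = "character"))
  stopifnot(all(c("scheme_pos", "intrinsic") %in% names(df)))
  if (is.null(df$residue)) df$residue <- "X"
  attr(df, "scorer") <- "external"
  class(df) <- c("solubility_profile", "data.frame")
  df
}

#' Structurally corrected solubility scores
#'
#' Corrects an intrinsic profile for the 3D neighborhood: each residue's
#' corrected score is the exposure-weighted average of the intrinsic scores
#' of all residues whose side-chain centroids lie within the patch radius
#' (including itself).  Solvent-exposed residues weigh 1, buried residues
#' are down-weighted; buried residues still receive a corrected score but
#' are excluded from hotspot membership downstream.  A uniform intrinsic
#' profile is left unchanged by construction, whatever the geometry.
#'
#' @param s a `vhh_structure` whose protein residues match the profile rows
#'   (by order).
#' @param profile a `solubility_profile` (intrinsic scores).
#' @param patch_radius maximum interaction distance in Angstrom
#'   (default 10).
#' @param sasa optional precomputed [compute_sasa()] table
#'   (`reference = "isolated"` is used when missing).
#' @param exposure_threshold relative-SASA threshold for "exposed".
#' @param buried_weight weight of buried residues in the patch average.
#' @return the profile with added columns `corrected`, `exposed`, `key`.
#' @export
structural_correction <- function(s, profile, patch_radius = 10,
                                  sasa = NULL, exposure_threshold = 0.25,
                                  buried_weight = 0.2) {
  stopifnot(inherits(s, "vhh_structure"),
            inherits(profile, "solubility_profile"))
  rt <- residue_table(s)
  if (nrow(rt) != nrow(profile))
    stop("structure has ", nrow(rt), " residues but profile has ",
         nrow(profile), " rows")
  if (is.null(sasa)) sasa <- compute_sasa(s, reference = "isolated")
  exposed <- sasa$rel_sasa >= exposure_threshold
  sc <- sidechain_atom_indices(s)
  xyz <- atom_coords(s)
  cent <- t(vapply(sc, function(i) colMeans(xyz[i, , drop = FALSE]),
                   numeric(3)))
  dd <- as.matrix(stats::dist(cent))
  w <- ifelse(exposed, 1, buried_weight)
  si <- profile$intrinsic
  corrected <- vapply(seq_len(nrow(rt)), function(i) {
    j <- which(dd[i, ] <= patch_radius)
    sum(w[j] * si[j]) / sum(w[j])
  }, 0)
  profile$corrected <- corrected
  profile$exposed <- exposed
  profile$key <- rt$key
  attr(profile, "parameters") <- c(attr(profile, "parameters"),
                                   list(patch_radius = patch_radius,
                                        exposure_threshold = exposure_threshold,
                                        buried_weight = buried_weight))
  profile
}

#' Detect and score aggregation hotspots
#'
#' Seeds are the poorest-solubility residues (corrected score below the
#' seed threshold).  Members are the solvent-exposed residues whose side
#' chains lie within the hotspot distance (minimum side-chain heavy-atom
#' distance; CA for glycine) of at least one seed's side chain; a seed is
#' its own member when exposed.  Seeds whose neighborhoods share a member
#' merge into one hotspot (single linkage).  Each hotspot is scored
#' `H = sum of the members' scores` and the list is returned worst
#' (lowest H) first.
#'
#' @param s a `vhh_structure`.
#' @param profile a corrected `solubility_profile` (from
#'   [structural_correction()]).
#' @param hotspot_distance membership distance in Angstrom (default 6).
#' @param seed_threshold hotspots nucleate where the score drops below this
#'   value (default -1 on the z scale).
#' @param score use `"corrected"` (default) or `"intrinsic"` scores for
#'   seeding and scoring.
#' @return list of class `hotspot_set`; each element has `seeds`,
#'   `members` (residue keys), `score`.  Empty list when no residue passes
#'   the seed rule.
#' @export
detect_hotspots <- function(s, profile, hotspot_distance = 6,
                            seed_threshold = -1,
                            score = c("corrected", "intrinsic")) {
  score <- match.arg(score)
  stopifnot(inherits(profile, "solubility_profile"))
  if (score == "corrected" && is.null(profile$corrected))
    stop("profile has no corrected scores; run structural_correction()")
  vals <- profile[[score]]
  rt <- residue_table(s)
  stopifnot(nrow(rt) == nrow(profile))
  exposed <- profile$exposed
  if (is.null(exposed))
    exposed <- compute_sasa(s, reference = "isolated")$rel_sasa >= 0.25
  seeds <- which(vals < seed_threshold)
  if (!length(seeds)) return(structure(list(), class = "hotspot_set",
                                       parameters = list(
                                         hotspot_distance = hotspot_distance,
                                         seed_threshold = seed_threshold,
                                         score = score)))
  sc <- sidechain_atom_indices(s)
  d <- min_distance_matrix(s, sc)
  member_sets <- lapply(seeds, function(i)
    which(exposed & d[i, ] <= hotspot_distance))
  # single-linkage merge of seeds sharing at least one member
  groups <- as.list(seq_along(seeds))
  repeat {
    merged <- FALSE
    for (a in seq_along(groups)) {
      if (is.null(groups[[a]])) next
      for (b in seq_along(groups)) {
        if (b <= a || is.null(groups[[b]])) next
        ma <- unique(unlist(member_sets[groups[[a]]]))
        mb <- unique(unlist(member_sets[groups[[b]]]))
        if (length(intersect(ma, mb))) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups[b] <- list(NULL)
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  groups <- Filter(Negate(is.null), groups)
  hs <- lapply(groups, function(g) {
    mem <- sort(unique(unlist(member_sets[g])))
    list(seeds = rt$key[seeds[g]], members = rt$key[mem],
         score = sum(vals[mem]))
  })
  hs <- Filter(function(h) length(h$members) > 0, hs)
  hs <- hs[order(vapply(hs, `[[`, 0, "score"))]
  structure(hs, class = "hotspot_set",
            parameters = list(hotspot_distance = hotspot_distance,
                              seed_threshold = seed_threshold,
                              score = score))
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("hotspot_set: %d hotspot(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  #%d score %.3f, %d members (seeds: %s)\n", i,
                x[[i]]$score, length(x[[i]]$members),
                paste(x[[i]]$seeds, collapse = ", ")))
  invisible(x)
}

#' Tabular hotspot report
#'
#' One row per hotspot with construct id, seeds, members and score;
#' suitable for side-by-side comparison of constructs by `rbind`-ing
#' several reports.  Scores carry the scorer label of the profile
#' (surrogate-intrinsic or external) in the `scorer` column.
#'
#' @param profile the corrected `solubility_profile` used.
#' @param hotspots a `hotspot_set`.
#' @param construct_id construct identifier for the report rows.
#' @return data frame: `construct`, `hotspot`, `n_members`, `seeds`,
#'   `members`, `score`, `scorer`.
#' @export
hotspot_report <- function(profile, hotspots, construct_id) {
  scorer <- attr(profile, "scorer")
  if (is.null(scorer)) scorer <- "surrogate-intrinsic"
  if (!length(hotspots))
    return(data.frame(construct = character(0), hotspot = integer(0),
                      n_members = integer(0), seeds = character(0),
                      members = character(0), score = numeric(0),
                      scorer = character(0), stringsAsFactors = FALSE))
  data.frame(
    construct = construct_id,
    hotspot = seq_along(hotspots),
    n_members = vapply(hotspots, function(h) length(h$members), 0L),
    seeds = vapply(hotspots, function(h) paste(h$seeds, collapse = ";"), ""),
    members = vapply(hotspots, function(h) paste(h$members, collapse = ";"), ""),
    score = vapply(hotspots, `[[`, 0, "score"),
    scorer = scorer, stringsAsFactors = FALSE)
}
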