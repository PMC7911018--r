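# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force loops, closed forms, or external
# implementations only.

# Exhaustive evaluation of the greedy neighbor-count clustering rule,
# written as plain loops over the matrix.
brute_force_gromos <- function(m, cutoff) {
  n <- nrow(m)
  remaining <- seq_len(n)
  labels <- integer(n)
  k <- 0
  while (length(remaining) > 0) {
    best <- NA_integer_
    best_count <- -1L
    for (i in remaining) {
      cnt <- 0L
      for (j in remaining) if (m[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best_count) { best_count <- cnt; best <- i }
    }
    members <- integer(0)
    for (j in remaining) if (m[best, j] <= cutoff) members <- c(members, j)
    k <- k + 1
    labels[members] <- k
    remaining <- setdiff(remaining, members)
  }
  labels
}

# random symmetric non-negative matrix with zero diagonal (RMSD-like)
random_rmsd_matrix <- function(n) {
  m <- matrix(stats::runif(n * n, 0, 4), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Analytic exposed area of a sphere of radius r1 occluded by spheres of
# radius r2 at center distances d (non-overlapping caps assumed).
sphere_cap_exposed_area <- function(r1, r2, d) {
  h <- pmax(0, r1 - (d^2 + r1^2 - r2^2) / (2 * d))
  4 * pi * r1^2 - sum(2 * pi * r1 * h)
}

# exhaustive all-pairs hotspot membership: residue r is a member iff it is
# exposed and any of its side-chain atoms lies within `cutoff` of any
# side-chain atom of any seed
brute_force_members <- function(s, seeds, exposed, cutoff) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  rt <- vhhumanize::residue_table(s)
  sc_atoms <- function(r) {
    i <- which(s$atoms$chain == rt$chain[r] & s$atoms$resno == rt$resno[r] &
                 s$atoms$resid != "OCC")
    sc <- i[!(s$atoms$elety[i] %in% c("N", "CA", "C", "O"))]
    if (length(sc)) sc else i[s$atoms$elety[i] == "CA"]
  }
  members <- integer(0)
  for (r in seq_len(nrow(rt))) {
    if (!exposed[r]) next
    hit <- FALSE
    for (sd in seeds) {
      for (ai in sc_atoms(r)) for (aj in sc_atoms(sd)) {
        if (sqrt(sum((xyz[ai, ] - xyz[aj, ])^2)) <= cutoff) hit <- TRUE
      }
    }
    if (hit) members <- c(members, r)
  }
  members
}

# small random coordinate structure (for contact-map property tests)
random_structure <- function(n_res, seed, id = "rand") {
  set.seed(seed)
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    p <- stats::rnorm(3, sd = 5)
    data.frame(elety = c("CA", "CB"), resid = "ALA", chain = "A",
               resno = i, x = p[1] + c(0, 1.5), y = p[2], z = p[3],
               element = "C", stringsAsFactors = FALSE)
  }))
  vhh_structure(atoms, id = id)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
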