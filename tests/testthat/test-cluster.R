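test_that("duplicate and rigidly moved conformations have zero RMSD", {
  s <- make_ring_structure(rep("A", 15))
  q <- random_rotation(5)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(q)
  sr <- s
  sr$atoms$x <- xyz[, 1] + 7; sr$atoms$y <- xyz[, 2] - 3
  sr$atoms$z <- xyz[, 3] + 1
  e <- as_ensemble(list(s, s, sr))
  m <- rmsd_matrix(e)
  expect_equal(m[1, 2], 0, tolerance = 1e-9)
  expect_equal(m[1, 3], 0, tolerance = 1e-9)
})

test_that("pairwise RMSD agrees with an independent superposition oracle", {
  set.seed(17)
  xs <- lapply(1:4, function(i) matrix(stats::rnorm(30, sd = 4), ncol = 3))
  structures <- lapply(seq_along(xs), function(i) {
    vhh_structure(data.frame(elety = "CA", resid = "GLY", chain = "A",
                             resno = 1:10, x = xs[[i]][, 1],
                             y = xs[[i]][, 2], z = xs[[i]][, 3],
                             element = "C"), id = paste0("s", i))
  })
  m <- rmsd_matrix(as_ensemble(structures))
  for (i in 1:3) for (j in (i + 1):4) {
    oracle <- bio3d::rmsd(as.vector(t(xs[[i]])), as.vector(t(xs[[j]])),
                          fit = TRUE)
    expect_lt(abs(m[i, j] - oracle), 6e-4)  # bio3d rounds to 3 decimals
  }
})

test_that("kabsch_rmsd handles the reflection branch", {
  x <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3,
              byrow = TRUE)
  y <- x
  y[, 3] <- -y[, 3]   # mirrored: proper rotation cannot reach it exactly
  expect_gt(kabsch_rmsd(x, y), 0)
  expect_equal(kabsch_rmsd(x, x), 0)
})

test_that("the automatic cutoff is the mean over unordered pairs", {
  m <- matrix(2, 3, 3); diag(m) <- 0
  expect_equal(auto_cutoff(m), 2)
  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- m2[2, 1] <- 1; m2[1, 3] <- m2[3, 1] <- 2
  m2[2, 3] <- m2[3, 2] <- 3
  expect_equal(auto_cutoff(m2), 2)
  set.seed(9)
  mr <- random_rmsd_matrix(10)
  expect_equal(auto_cutoff(mr), mean(mr[upper.tri(mr)]))
  expect_error(auto_cutoff(matrix(0, 1, 1)), "at least 2")
})

test_that("identical conformations collapse to a single cluster", {
  s <- make_ring_structure(rep("A", 10))
  e <- as_ensemble(list(s, s, s))
  m <- rmsd_matrix(e)
  cl <- gromos_cluster(m, cutoff = 0.5)
  expect_equal(length(cl$sizes), 1)
  expect_equal(cl$sizes, 3L)
})

test_that("two separated groups recover their planted sizes", {
  bx <- make_basin_ensemble(n = 24, n_frames = 20,
                            proportions = c(0.7, 0.3), loop = 16:20,
                            displacement = 10, jitter = 0.1, seed = 2)
  m <- rmsd_matrix(bx$ensemble)
  cl <- gromos_cluster(m, auto_cutoff(m))
  expect_equal(cl$sizes, c(14L, 6L))
  # recovered labels match the planted basins exactly
  tab <- table(cl$labels, bx$truth$labels)
  expect_equal(sum(apply(tab, 1, max)), 20)
})

test_that("clustering matches the brute-force greedy oracle for small N", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    m <- random_rmsd_matrix(n)
    cutoff <- stats::runif(1, 0.5, 3.5)
    got <- gromos_cluster(m, cutoff)
    expect_identical(got$labels, brute_force_gromos(m, cutoff))
  }
})

test_that("cluster invariants hold on the planted three-basin ensemble", {
  bx <- make_basin_ensemble(n = 40, n_frames = 60,
                            proportions = c(0.85, 0.10, 0.05),
                            loop = 30:36, seed = 5)
  m <- rmsd_matrix(bx$ensemble)
  cl <- gromos_cluster(m, auto_cutoff(m))
  expect_equal(sum(cl$sizes), 60)
  expect_true(all(diff(cl$sizes) <= 0))
  expect_true(all(cl$labels >= 1))
  # greedy property: each center had at least as many within-cutoff
  # neighbors (among not-yet-clustered frames) as any other candidate
  remaining <- seq_len(cl$n)
  adj <- unclass(m) <= cl$cutoff
  for (k in seq_along(cl$centers)) {
    counts <- rowSums(adj[remaining, remaining, drop = FALSE])
    expect_equal(max(counts),
                 counts[match(cl$centers[k], remaining)])
    remaining <- setdiff(remaining, which(cl$labels == k))
  }
})

test_that("representative selection is deterministic and from the top cluster", {
  bx <- make_basin_ensemble(n = 30, n_frames = 40,
                            proportions = c(0.85, 0.15), loop = 22:27,
                            seed = 8)
  m <- rmsd_matrix(bx$ensemble)
  cl <- gromos_cluster(m, auto_cutoff(m))
  r1 <- select_representative(bx$ensemble, cl)
  r2 <- select_representative(bx$ensemble, cl)
  expect_identical(r1$frames, r2$frames)
  expect_equal(cl$labels[r1$reference_frame], 1L)
  # single-member clusters are represented by themselves
  solo <- gromos_cluster(matrix(c(0, 10, 10, 0), 2), cutoff = 1)
  expect_equal(solo$centers, c(1L, 2L))
})
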