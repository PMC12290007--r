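test_that("Kabsch RMSD vanishes under rigid transforms", {
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(rnorm(3 * sample(4:30, 1)), ncol = 3)
    y <- x %*% t(random_rotation())
    y <- sweep(y, 2, rnorm(3, 0, 5), "+")
    expect_equal(kabsch_rmsd(x, x), 0, tolerance = 1e-12)
    expect_lt(kabsch_rmsd(x, y), 1e-10)
  }
})

test_that("Kabsch RMSD matches the quaternion oracle and is symmetric", {
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(4:40, 1)
    x <- matrix(rnorm(3 * n), ncol = 3)
    y <- matrix(rnorm(3 * n), ncol = 3)
    r1 <- kabsch_rmsd(x, y)
    expect_equal(r1, quaternion_rmsd(x, y), tolerance = 1e-10)
    expect_equal(r1, kabsch_rmsd(y, x), tolerance = 1e-10)
  }
  # 4-point toy set, explicit oracle cross-check
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  y <- rbind(c(0, 0, 0.1), c(1.1, 0, 0), c(0, 0.9, 0), c(0.05, 0, 1))
  expect_equal(kabsch_rmsd(x, y), quaternion_rmsd(x, y), tolerance = 1e-12)
  expect_error(kabsch_rmsd(x, y[1:3, ]), "equal sizes")
})

test_that("reflections are not absorbed: proper rotation enforced", {
  set.seed(13)
  x <- matrix(rnorm(30), ncol = 3)
  y <- x
  y[, 1] <- -y[, 1]              # mirror image
  expect_gt(kabsch_rmsd(x, y), 0.1)
  expect_equal(kabsch_rmsd(x, y), quaternion_rmsd(x, y), tolerance = 1e-10)
})

test_that("bound-frame extraction follows the profile exactly", {
  frames <- lapply(1:10, function(i)
    traj_frame(matrix(i, 1, 3), c(5, 5, 5), time = i))
  prof <- list(bound = rep(c(TRUE, FALSE), 5))
  got <- extract_bound_frames(frames, prof)
  expect_length(got, 5L)
  expect_equal(vapply(got, `[[`, numeric(1), "time"), c(1, 3, 5, 7, 9))
  expect_length(extract_bound_frames(frames,
                                     list(bound = rep(TRUE, 10))), 10L)
  expect_warning(none <- extract_bound_frames(frames,
                                              list(bound = rep(FALSE, 10))),
                 "no bound")
  expect_length(none, 0L)
  expect_error(extract_bound_frames(frames, list(bound = TRUE)), "aligned")
})

test_that("the RMSD matrix is consistent with pairwise calls", {
  set.seed(14)
  frames <- lapply(1:4, function(i)
    traj_frame(matrix(rnorm(30), ncol = 3), c(5, 5, 5), time = i))
  m <- rmsd_matrix(frames, selection = 1:10)
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(diag(m), rep(0, 4))
  expect_equal(m, t(m))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(m[i, j],
                 kabsch_rmsd(frames[[i]]$xyz, frames[[j]]$xyz))
  m2 <- rmsd_matrix(c(frames, frames[1]), selection = 1:10, stride = 2L)
  expect_equal(attr(m2, "frame_ids"), c(1L, 3L, 5L))
  expect_equal(m2[1, 2], m[1, 3])
})

test_that("GROMOS clustering handles the degenerate limits", {
  n <- 7
  m <- matrix(0.01, n, n); diag(m) <- 0
  one <- gromos_cluster(m, 0.15)
  expect_length(one$members, 1L)
  expect_equal(one$populations, 100)

  m2 <- matrix(1, n, n); diag(m2) <- 0
  all_single <- gromos_cluster(m2, 0.15)
  expect_length(all_single$members, n)
  expect_true(all(all_single$populations == 100 / n))

  m3 <- m2; m3[1, 2] <- m3[2, 1] <- NA
  expect_error(gromos_cluster(m3, 0.15), "NaN|NA")
})

test_that("GROMOS clustering equals the brute-force oracle on random matrices", {
  set.seed(15)
  for (rep in 1:40) {
    n <- sample(5:120, 1)
    m <- random_symmetric_rmsd_matrix(n)
    cutoff <- runif(1, 0.05, 0.2)
    got <- gromos_cluster(m, cutoff)
    want <- gromos_oracle(m, cutoff)
    expect_equal(lapply(got$members, sort), lapply(want, sort))
    # coverage and disjointness
    allm <- unlist(got$members)
    expect_setequal(allm, seq_len(n))
    expect_equal(length(allm), n)
    # populations non-increasing, first cluster largest
    expect_true(all(diff(lengths(got$members)) <= 0))
    expect_equal(sum(got$populations), 100)
  }
})

test_that("clustering is invariant to frame order up to the tie-break", {
  set.seed(16)
  n <- 40
  m <- random_symmetric_rmsd_matrix(n)
  perm <- sample(n)
  got <- gromos_cluster(m[perm, perm], 0.12)
  want <- gromos_oracle(m[perm, perm], 0.12)
  expect_equal(lapply(got$members, sort), lapply(want, sort))
})

test_that("cluster summaries filter by population floor", {
  # construct three well-separated blobs of sizes 11, 6, 3
  sizes <- c(12, 6, 2)
  centers <- c(0, 10, 20)
  vals <- unlist(mapply(function(c, s) c + (1:s) / 100, centers, sizes))
  m <- abs(outer(vals, vals, "-"))
  cl <- gromos_cluster(m, 0.5)
  expect_equal(lengths(cl$members), sizes)
  times <- seq_along(vals) * 10
  ssd <- rep(0.7, length(vals))
  eed <- rep(c(0.6, 1.4, 1.0), sizes)
  # floor is strict: the 10% cluster is excluded
  summ <- cluster_summary(cl, times, ssd, eed, population_floor_percent = 10)
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$population_percent, c(60, 30))
  expect_equal(summ$eed_nm, c(0.6, 1.4))
  expect_equal(summ$representative_time_ps, times[cl$centers[1:2]])

  summ_all <- cluster_summary(cl, times, ssd, eed,
                              population_floor_percent = 0)
  expect_equal(nrow(summ_all), 3L)
})
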