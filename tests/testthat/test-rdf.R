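make_classes <- function() {
  spec <- synthetic_spec(n_frames = 2L)
  sys <- generate_synthetic_system(spec, seed = 21L)
  tr <- generate_trajectory(sys, seed = 22L)
  list(sys = sys, frame = tr$frames[[1]],
       cls = classify_atoms(sys$topology, tr$frames[[1]]))
}

test_that("selection expressions resolve to the expected atom sets", {
  env <- make_classes()
  top <- env$sys$topology; cls <- env$cls

  sel <- resolve_selection("sidechain N pos 1", top, cls)
  expect_length(sel, 3L)   # guanidinium NE/NH1/NH2 of R1
  expect_true(all(top$name[sel] %in% c("NE", "NH1", "NH2")))

  expect_length(resolve_selection("CA pos 3", top, cls), 1L)
  expect_identical(top$name[resolve_selection("CA pos 3", top, cls)], "CA")

  expect_identical(resolve_selection("surface OF", top, cls), cls$OF)
  expect_identical(resolve_selection("surface OB", top, cls), cls$OB)
  expect_identical(resolve_selection("na", top, cls), cls$NA.)
  expect_identical(resolve_selection("nterm N", top, cls), cls$NTERM_N)
  expect_length(resolve_selection("cterm O", top, cls), 2L)
  expect_identical(resolve_selection("sidechain-N pos 1", top, cls), sel)

  # Calpha by residue identity: A, L, P of RKLPDA are positions 3, 4, 6
  ca <- resolve_selection("CA res ALP", top, cls)
  expect_length(ca, 3L)
  expect_setequal(top$resname[ca], c("ALA", "LEU", "PRO"))

  expect_error(resolve_selection("bogus thing", top, cls), "unknown token")
  expect_error(resolve_selection("sidechain N pos 9", top, cls),
               "out of range")

  # unhydroxylated slab: surface OF resolves to an empty set
  slab <- build_anatase_slab(2, 3, 2)
  ssys <- slab_system(slab, c(slab$box_lat, max(slab$xyz[, 3]) + 3))
  scls <- classify_atoms(ssys$topology, ssys$frame)
  expect_length(resolve_selection("surface OF", ssys$topology, scls), 0L)
})

test_that("a fixed pair lands every count in the right bin", {
  top <- system_topology(name = c("NA", "CL"), resname = c("NA", "CL"),
                         resid = 1:2)
  xyz <- rbind(c(2, 2, 2), c(2, 2, 2.25))
  f <- traj_frame(xyz, c(6, 6, 6))
  r <- compute_rdf(list(f), 1L, 2L, r_max = 1.0, bin_width = 0.002)
  expect_equal(sum(r$counts), 1)
  hit <- which(r$counts > 0)
  expect_true(r$bin_edges[hit] <= 0.25 && r$bin_edges[hit + 1] > 0.25)
  pk <- first_peak(r, window_max = 0.4)
  expect_lt(abs(pk$r_peak - 0.25), 0.002)
  expect_false(pk$outside_window)
})

test_that("counting is conserved and errors are raised for bad input", {
  set.seed(23)
  frames <- lapply(1:3, function(i)
    traj_frame(matrix(runif(60, 0, 4), ncol = 3), c(4, 4, 4)))
  r <- compute_rdf(frames, 1:8, 9:20, r_max = 1.0, bin_width = 0.01)
  manual <- sum(vapply(frames, function(f) {
    d <- surfpep:::pairwise_min_image(f$xyz[1:8, ], f$xyz[9:20, ], f$box)
    sum(d < 1.0)
  }, numeric(1)))
  expect_equal(sum(r$counts), manual)
  expect_error(compute_rdf(frames, integer(0), 9:20), "empty selection")
  expect_error(compute_rdf(frames, 1:8, 9:20, r_max = 3), "half the smallest")
})

test_that("uniform ideal-gas points give g(r) = 1 in the mid range", {
  set.seed(24)
  box <- c(4, 4, 4)
  na <- 800; nb <- 800
  frames <- lapply(1:8, function(i)
    traj_frame(matrix(runif(3 * (na + nb), 0, 4), ncol = 3), box))
  r <- compute_rdf(frames, 1:na, na + 1:nb, r_max = 0.6, bin_width = 0.02)
  win <- r$r >= 0.3 & r$r <= 0.5
  expect_lt(max(abs(r$g[win] - 1)), 0.05)
  expect_lt(abs(mean(r$g[win]) - 1), 0.02)
})

test_that("first_peak reports the windowed maximum and flags escapes", {
  # planted two-peak histogram from explicit pair placements
  top_xyz <- rbind(c(2, 2, 2), c(2, 2, 2.28), c(2, 2, 2.55))
  f <- traj_frame(top_xyz, c(6, 6, 6))
  # A = atom 1; B = atoms 2,3 at 0.28 and 0.55
  r <- compute_rdf(list(f), 1L, 2:3, r_max = 1.0, bin_width = 0.002)
  pk <- first_peak(r, window_max = 0.4)
  expect_lt(abs(pk$r_peak - 0.28), 0.002)
  # 0.55 bin has equal raw count but smaller g (r^2 normalization), so the
  # global max is inside the window
  expect_false(pk$outside_window)

  # monotone-increasing g: global max outside the window is flagged
  f2 <- traj_frame(rbind(c(2, 2, 2), c(2, 2, 2.8)), c(6, 6, 6))
  r2 <- compute_rdf(list(f2), 1L, 2L, r_max = 1.0, bin_width = 0.002)
  pk2 <- first_peak(r2, window_max = 0.4)
  expect_true(pk2$outside_window)

  expect_error(first_peak(r, window_max = 5), "outside binned range")
})

test_that("peak location is stable under bin-width halving", {
  env <- make_classes()
  spec <- synthetic_spec(n_frames = 120L)
  sys <- generate_synthetic_system(spec, seed = 25L)
  tr <- generate_trajectory(sys, seed = 26L)
  prof <- binding_profile(tr$frames, sys$topology)
  cls <- classify_atoms(sys$topology, tr$frames[[1]])
  bf <- extract_bound_frames(tr$frames, prof)
  selA <- resolve_selection("sidechain N pos 1", sys$topology, cls)
  selB <- resolve_selection("surface OF", sys$topology, cls)
  p1 <- first_peak(compute_rdf(bf, selA, selB, bin_width = 0.004))$r_peak
  p2 <- first_peak(compute_rdf(bf, selA, selB, bin_width = 0.002))$r_peak
  expect_lt(abs(p1 - p2), 0.004)
})

test_that("the bridging filter applies the dual distance criterion", {
  # hand-built geometry: 3 Na, one bridging, one surface-only, one far
  xyz <- rbind(
    c(1.0, 1.0, 1.0),    # 1: OF (surface oxygen)
    c(3.0, 3.0, 3.0),    # 2: peptide oxygen
    c(1.0, 1.0, 1.25),   # 3: Na near surface only
    c(3.0, 3.0, 2.75),   # 4: Na near peptide O only
    c(5.0, 5.0, 5.0))    # 5: Na far from both
  f <- traj_frame(xyz, c(6, 6, 6))
  cls <- list(OB = integer(0), OF = 1L, peptide_O = 2L, NA. = 3:5)
  expect_identical(bridging_na_filter(f, cls), integer(0))

  # move Na 3 to satisfy both criteria: 0.25 from OF and 0.25 from pep O
  xyz2 <- xyz
  xyz2[1, ] <- c(2, 2, 2)        # OF
  xyz2[2, ] <- c(2, 2, 2.5)      # peptide O
  xyz2[3, ] <- c(2, 2, 2.25)     # Na bridging: 0.25 to both
  f2 <- traj_frame(xyz2, c(6, 6, 6))
  expect_identical(bridging_na_filter(f2, cls), 3L)
  # tighter cutoffs exclude it
  expect_identical(bridging_na_filter(f2, cls, d_surface = 0.2), integer(0))
})

test_that("planted bridging ions are recovered exactly on synthetic frames", {
  spec <- synthetic_spec(n_frames = 80L)
  sys <- generate_synthetic_system(spec, seed = 27L)
  tr <- generate_trajectory(sys, seed = 28L)
  cls <- classify_atoms(sys$topology, tr$frames[[1]])
  for (i in seq_along(tr$frames)) {
    got <- bridging_na_filter(tr$frames[[i]], cls)
    want <- tr$truth$bridge_na[i]
    want <- as.integer(want[!is.na(want)])
    expect_identical(sort(got), sort(want))
  }
  expect_gt(sum(!is.na(tr$truth$bridge_na)), 0L)
})

test_that("conditional RDF with an always-bridging ion equals the plain RDF", {
  # static frame in which the single Na bridges by construction
  xyz <- rbind(c(2, 2, 2),       # OF
               c(2, 2, 2.5),     # peptide O
               c(2, 2, 2.25),    # Na (bridging)
               c(2.4, 2.1, 2.3), # target B atoms
               c(1.7, 2.2, 2.6))
  f <- traj_frame(xyz, c(6, 6, 6))
  cls <- list(OB = integer(0), OF = 1L, peptide_O = 2L, NA. = 3L)
  frames <- list(f, f, f)
  cond <- conditional_rdf(frames, cls, sel_b = 4:5, r_max = 1, bin_width = 0.01)
  plain <- compute_rdf(frames, 3L, 4:5, r_max = 1, bin_width = 0.01)
  expect_equal(cond$g, plain$g)
  expect_equal(cond$counts, plain$counts)
  expect_equal(cond$mean_n_a, 1)

  # no bridging ion anywhere: identically zero with zero mean count
  cls0 <- list(OB = integer(0), OF = 1L, peptide_O = 2L, NA. = 4L)
  zero <- conditional_rdf(frames, cls0, sel_b = 5L, r_max = 1,
                          bin_width = 0.01)
  expect_true(all(zero$g == 0))
  expect_equal(zero$mean_n_a, 0)
})

test_that("conditional RDF recovers the planted bridge distance", {
  spec <- synthetic_spec(n_frames = 150L)
  sys <- generate_synthetic_system(spec, seed = 29L)
  tr <- generate_trajectory(sys, seed = 30L)
  prof <- binding_profile(tr$frames, sys$topology)
  cls <- classify_atoms(sys$topology, tr$frames[[1]])
  bf <- extract_bound_frames(tr$frames, prof)
  selB <- resolve_selection("sidechain O pos 5", sys$topology, cls)
  r <- conditional_rdf(bf, cls, selB)
  pk <- first_peak(r)
  expect_lt(abs(pk$r_peak - spec$bridge_dist), 0.002)
})
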