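test_that("unwrapping reunites a peptide split across the boundary", {
  sys <- toy_ssd_system(com_z = 5)
  box <- sys$frame$box
  # template bond spectrum before wrapping
  bonds <- attr(sys$topology, "bonds")
  ref_bl <- sqrt(rowSums((sys$frame$xyz[bonds[, 1], ] -
                            sys$frame$xyz[bonds[, 2], ])^2))
  # translate so the peptide straddles x = 0, then wrap
  shifted <- sys$frame
  shifted$xyz[sys$classes$peptide, 1] <-
    shifted$xyz[sys$classes$peptide, 1] - 2.5 + 0.01
  shifted$xyz <- surfpep:::wrap_coords(shifted$xyz, box)
  spread <- diff(range(shifted$xyz[sys$classes$peptide, 1]))
  expect_gt(spread, box[1] / 2)   # genuinely split

  fixed <- unwrap_peptide(shifted, sys$topology)
  bl <- sqrt(rowSums((fixed$xyz[bonds[, 1], ] -
                        fixed$xyz[bonds[, 2], ])^2))
  expect_equal(bl, ref_bl, tolerance = 1e-9)

  # an already-whole peptide is untouched
  same <- unwrap_peptide(sys$frame, sys$topology)
  expect_equal(same$xyz, sys$frame$xyz)
})

test_that("SSD follows the two-face periodic z-distance geometry", {
  # COM z = 4.0, planes at 3.05 and 0, Lz = 10.7: min(0.95, 4.0) = 0.95
  sys <- toy_ssd_system(com_z = 4.0)
  expect_equal(compute_ssd(sys$frame, sys$classes, sys$topology), 0.95,
               tolerance = 1e-9)

  # COM on the top plane
  sys0 <- toy_ssd_system(com_z = 3.05)
  expect_equal(compute_ssd(sys0$frame, sys0$classes, sys0$topology), 0,
               tolerance = 1e-9)

  # above the box midpoint the nearer face is the bottom one via wrapping
  sys2 <- toy_ssd_system(com_z = 9.7)
  expect_equal(compute_ssd(sys2$frame, sys2$classes, sys2$topology), 1.0,
               tolerance = 1e-9)

  # mid-solvent maximum is half the water-region height
  mid <- 3.05 + (10.7 - 3.05) / 2
  sysm <- toy_ssd_system(com_z = mid)
  expect_equal(compute_ssd(sysm$frame, sysm$classes, sysm$topology),
               (10.7 - 3.05) / 2, tolerance = 1e-9)
})

test_that("SSD is invariant to lateral translation and z-mirroring", {
  sys <- toy_ssd_system(com_z = 4.0)
  ref <- compute_ssd(sys$frame, sys$classes, sys$topology)

  shifted <- sys$frame
  shifted$xyz[, 1] <- shifted$xyz[, 1] + 1.3
  shifted$xyz[, 2] <- shifted$xyz[, 2] - 0.7
  shifted$xyz <- surfpep:::wrap_coords(shifted$xyz, shifted$box)
  cls <- classify_atoms(sys$topology, shifted)
  expect_equal(compute_ssd(shifted, cls, sys$topology), ref,
               tolerance = 1e-9)

  mirrored <- sys$frame
  mirrored$xyz[, 3] <- sys$frame$box[3] - mirrored$xyz[, 3]
  clsm <- classify_atoms(sys$topology, mirrored)
  expect_equal(compute_ssd(mirrored, clsm, sys$topology), ref,
               tolerance = 1e-9)
})

test_that("EED is the distance between terminal Calpha atoms", {
  sys <- toy_ssd_system(com_z = 5)
  ca <- sys$classes$peptide_CA
  manual <- sqrt(sum((sys$frame$xyz[ca[1], ] - sys$frame$xyz[ca[6], ])^2))
  expect_equal(compute_eed(sys$frame, sys$classes), manual)
  expect_equal(manual, 0.65, tolerance = 1e-6)  # template target

  # extended template respects the virtual-bond geometric bound
  ext <- build_peptide_template("RKLPDA", 5)
  expect_lte(ext$eed, 5 * 0.40)
})

test_that("binding profiles classify states and summarise EED per state", {
  # all bound: one event, absent unbound statistics
  p1 <- profile_from_series(times = (0:9) * 10, ssd = rep(0.5, 10),
                            eed = rep(1.0, 10))
  expect_equal(p1$percent_bound, 100)
  expect_equal(nrow(p1$events), 1L)
  expect_true(is.na(p1$eed_d))
  expect_true(is.na(p1$std_d))

  # alternating 0.5 / 1.5 over 10 frames
  p2 <- profile_from_series((0:9) * 10, rep(c(0.5, 1.5), 5),
                            rep(c(0.6, 1.4), 5))
  expect_equal(p2$percent_bound, 50)
  expect_equal(p2$eed_a, 0.6)
  expect_equal(p2$eed_d, 1.4)
  expect_equal(sum(p2$events$n_frames), 10L)

  # boundary value: SSD exactly at the threshold is unbound (strict <)
  p3 <- profile_from_series(0:1, c(1.0, 0.999), c(1, 1))
  expect_equal(p3$percent_bound, 50)

  # population vs sample SD
  p4 <- profile_from_series((0:3), rep(0.5, 4), c(1, 2, 3, 4))
  expect_equal(p4$std_a, sqrt(mean((1:4 - 2.5)^2)))
  p5 <- profile_from_series((0:3), rep(0.5, 4), c(1, 2, 3, 4),
                            analysis_params(sd_type = "sample"))
  expect_equal(p5$std_a, sd(1:4))

  expect_error(profile_from_series(numeric(0), numeric(0), numeric(0)),
               "no frames")
})

test_that("debouncing merges state flickers into the surrounding state", {
  ssd <- c(0.5, 0.5, 1.5, 0.5, 0.5, 1.5, 1.5, 1.5)
  p <- profile_from_series(seq_along(ssd), ssd, rep(1, 8),
                           analysis_params(min_dwell_frames = 2L))
  expect_equal(p$bound, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # default leaves the flicker untouched
  p0 <- profile_from_series(seq_along(ssd), ssd, rep(1, 8))
  expect_equal(sum(p0$bound), 4L)
})

test_that("percent bound is invariant under re-wrapping and xy translation", {
  spec <- synthetic_spec(n_frames = 40L)
  sys <- generate_synthetic_system(spec, seed = 2L)
  tr <- generate_trajectory(sys, seed = 9L)
  ref <- binding_profile(tr$frames, sys$topology)

  moved <- lapply(tr$frames, function(f) {
    f$xyz[, 1] <- f$xyz[, 1] + 0.77
    f$xyz <- surfpep:::wrap_coords(f$xyz, f$box)
    f
  })
  got <- binding_profile(moved, sys$topology)
  expect_equal(got$percent_bound, ref$percent_bound)
  expect_equal(got$ssd, ref$ssd, tolerance = 1e-9)
})

test_that("peptide ranking sorts by fraction with alphabetical ties", {
  mk <- function(pct) structure(list(percent_bound = pct, eed_a = 1,
                                     std_a = 0.1, eed_d = 1.2, std_d = 0.1),
                                class = "binding_profile")
  tab <- rank_peptides(list(RKLPDA = mk(96.51), PLARKD = mk(100),
                            AAAAAA = mk(96.51)))
  expect_identical(tab$label, c("PLARKD", "AAAAAA", "RKLPDA"))
  expect_true(all(diff(tab$percent_bound) <= 0))
  expect_error(rank_peptides(list()), "nonempty")
})

test_that("per-frame series round-trip through TSV", {
  p <- profile_from_series((0:9) * 10, runif(10, 0.3, 2), runif(10, 0.5, 1.5))
  f <- tempfile(fileext = ".tsv")
  write_series(p, f)
  back <- read_series(f)
  expect_equal(back$ssd, p$ssd)
  expect_equal(back$percent_bound, p$percent_bound)
})
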