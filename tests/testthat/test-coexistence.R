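# Density-profile and condensate-detection analysis on constructed
# configurations with known structure.

test_that("a uniform ideal gas yields a flat profile", {
  box <- box_spec(60, 60, 240)
  n <- 600
  set.seed(1)
  frames <- lapply(1:20, function(f)
    cbind(runif(n, 0, 60), runif(n, 0, 60), runif(n, 0, 240)))
  topo <- point_topology(n, "CORELET", box)
  traj <- fake_trajectory(frames, box)
  prof <- density_profile(traj, topo, "CORELET", n_bins = 16,
                          equilibration_fraction = 0, align = FALSE)
  counts <- prof$density * 60 * 60 * (240 / 16) * prof$n_frames
  # chi-square goodness of fit against uniformity
  pval <- stats::chisq.test(counts)$p.value
  expect_gt(pval, 0.001)
  # conservation: binned mass equals the molecule count
  expect_equal(sum(prof$density) * 60 * 60 * (240 / 16), n, tolerance = 1e-9)
})

test_that("a two-block configuration gives an infinite density ratio", {
  box <- box_spec(50, 50, 200)
  n <- 64
  set.seed(2)
  frames <- lapply(1:4, function(f)
    cbind(runif(n, 0, 50), runif(n, 0, 50), runif(n, 60, 140)))
  topo <- point_topology(n, "CORELET", box)
  prof <- density_profile(fake_trajectory(frames, box), topo, "CORELET",
                          n_bins = 16, equilibration_fraction = 0)
  expect_identical(condensim:::profile_ratio(prof), Inf)
})

synthetic_profile <- function(dense, dilute, n_bins = 24, width = 4) {
  # tanh-interface slab profile centred in a box of unit bin width
  z <- seq_len(n_bins) - 0.5
  c0 <- n_bins / 2
  half <- n_bins / 5
  d <- dilute + (dense - dilute) * 0.5 *
    (tanh((z - (c0 - half)) / width * 4) - tanh((z - (c0 + half)) / width * 4))
  structure(list(z = z, density = d, species_group = "CORELET",
                 n_bins = n_bins, n_frames = 1, Lz = n_bins, bin_width = 1),
            class = "density_profile")
}

test_that("coexistence densities recover constructed plateaus", {
  # sharp step profile
  stepp <- synthetic_profile(10, 1, n_bins = 24, width = 0.5)
  cx <- coexistence_densities(stepp)
  expect_equal(cx$dense, 10, tolerance = 0.02)
  expect_equal(cx$dilute, 1, tolerance = 0.02)
  # smooth interface, 2% recovery
  smooth <- synthetic_profile(8, 0.5, n_bins = 32, width = 2)
  cx2 <- coexistence_densities(smooth)
  expect_equal(cx2$dense, 8, tolerance = 0.02)
  expect_equal(cx2$dilute, 0.5, tolerance = 0.05)
  # flat profile carries no slab
  flat <- synthetic_profile(2, 2)
  expect_error(coexistence_densities(flat), "no slab")
})

test_that("condensate detection is inclusive at exactly 3-fold", {
  prof_at <- synthetic_profile(3, 1, width = 0.5)
  prof_at$density <- c(rep(1, 10), rep(3, 4), rep(1, 10))
  expect_true(detect_condensate(prof_at))
  prof_under <- prof_at
  prof_under$density <- c(rep(1, 10), rep(2.9, 4), rep(1, 10))
  expect_false(detect_condensate(prof_under))
  # chromatin compaction alone triggers detection
  flat_cor <- prof_under
  flat_cor$density <- rep(1, 24)
  nuc4 <- prof_at
  nuc4$density <- c(rep(1, 10), rep(4, 4), rep(1, 10))
  nuc4$species_group <- "NUCLEOSOME"
  expect_true(detect_condensate(flat_cor, nuc4))
  expect_false(detect_condensate(flat_cor, flat_cor))
})

test_that("plateau estimates are stable between 16 and 32 bins", {
  box <- box_spec(40, 40, 160)
  set.seed(3)
  # synthetic slab occupying the central quarter at 12x the outside density
  n_dense <- 360; n_dilute <- 120
  frames <- lapply(1:30, function(f) {
    rbind(cbind(runif(n_dense, 0, 40), runif(n_dense, 0, 40),
                runif(n_dense, 60, 100)),
          cbind(runif(n_dilute, 0, 40), runif(n_dilute, 0, 40),
                runif(n_dilute, 0, 160)))
  })
  topo <- point_topology(n_dense + n_dilute, "CORELET", box)
  traj <- fake_trajectory(frames, box)
  est <- lapply(c(16, 32), function(nb) {
    coexistence_densities(density_profile(traj, topo, "CORELET", nb, 0,
                                          align = FALSE))
  })
  expect_equal(est[[1]]$dense, est[[2]]$dense, tolerance = 0.05)
  expect_equal(est[[1]]$dilute, est[[2]]$dilute, tolerance = 0.05)
})

test_that("phase-diagram assembly flags conflicting duplicates", {
  empty <- assemble_phase_diagram(
    data.frame(core_concentration = numeric(0), inverse_valence = numeric(0),
               acetyl_fraction = numeric(0), phase_separated = logical(0)))
  expect_equal(nrow(empty), 0)
  pts <- data.frame(core_concentration = c(1, 1, 2),
                    inverse_valence = c(0.5, 0.5, 0.25),
                    acetyl_fraction = 0.4,
                    phase_separated = c(TRUE, FALSE, TRUE))
  expect_warning(pd <- assemble_phase_diagram(pts), "conflict")
  expect_true(all(pd$conflict[1:2]))
  expect_false(pd$conflict[3])
})

test_that("profile equilibration window and empty groups are validated", {
  box <- box_spec(30, 30, 120)
  topo <- point_topology(10, "CORELET", box)
  traj <- fake_trajectory(list(matrix(5, 10, 3)), box)
  expect_error(density_profile(traj, topo, "NUCLEOSOME"), "empty species")
  expect_error(density_profile(traj, topo, "CORELET",
                               equilibration_fraction = 1),
               "equilibration")
})
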