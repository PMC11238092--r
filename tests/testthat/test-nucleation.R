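box36 <- box_spec(300, 300, 300)

test_that("single-linkage clustering matches simple chain geometry", {
  cfg <- clustering_config("CORELET", 3, stable_size = 2)
  topo <- point_topology(3, "CORELET", box36)
  # chain at 0.9 R_clust spacing links into one cluster
  topo$positions <- rbind(c(50, 50, 50), c(50 + 0.9 * 25, 50, 50),
                          c(50 + 1.8 * 25, 50, 50))
  labs <- find_clusters(initial_state(topo), topo, cfg)
  expect_equal(length(unique(labs)), 1)
  # 1.1 R_clust spacing leaves singletons
  topo$positions <- rbind(c(50, 50, 50), c(50 + 1.1 * 25, 50, 50))
  topo2 <- point_topology(2, "CORELET", box36)
  topo2$positions <- topo$positions[1:2, ]
  labs2 <- find_clusters(initial_state(topo2), topo2, cfg)
  expect_equal(length(unique(labs2)), 2)
})

test_that("cluster partitions equal the BFS oracle on random configurations", {
  L <- c(120, 120, 120)
  box <- box_spec(L[1], L[2], L[3])
  for (seed in 1:100) {
    set.seed(seed)
    m <- sample(5:40, 1)
    pts <- matrix(runif(3 * m) * L[1], m, 3)
    rcut <- runif(1, 10, 40)
    got <- condensim:::cpp_cluster(pts, L, rcut)
    want <- bfs_clusters(pts, L, rcut)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("cluster partition is invariant to relabeling and rigid shifts", {
  set.seed(42)
  L <- c(100, 100, 100)
  pts <- matrix(runif(60) * 100, 20, 3)
  base <- condensim:::cpp_cluster(pts, L, 22)
  # translation across the periodic boundary
  shifted <- sweep(pts, 2, c(63, -41, 97), `+`) %% 100
  lab2 <- condensim:::cpp_cluster(shifted, L, 22)
  # compare partitions as set-of-sets
  part <- function(lab) unname(split(seq_along(lab), lab))
  expect_setequal(lapply(part(base), sort), lapply(part(lab2), sort))
  # relabeling: permute the points
  perm <- sample(20)
  lab3 <- condensim:::cpp_cluster(pts[perm, ], L, 22)
  expect_setequal(lapply(part(base), sort),
                  lapply(part(lab3), function(ix) sort(perm[ix])))
})

make_trace <- function(n_cs, coverage = 0, times = NULL) {
  n <- length(n_cs)
  if (length(coverage) == 1) coverage <- rep(coverage, n)
  if (is.null(times)) times <- seq_len(n) - 1
  structure(data.frame(time = times, n_cs = n_cs, coverage = coverage),
            class = c("cluster_trace", "data.frame"))
}

test_that("largest-cluster trace reports dispersed and bound states", {
  cfg <- clustering_config("CORELET", 4, stable_size = 3)
  # 4 isolated molecules, one frame; then all together near the chain
  topo <- condensim:::combine_topologies(c(
    list(build_chromatin(6, 0, periodic_z = FALSE, seed = 1,
                         center = c(150, 150))),
    lapply(1:4, function(i) build_corelet(0))), box36)
  ref <- condensim:::reference_particles(topo)
  dispersed <- topo$positions
  dispersed[ref, ] <- matrix(c(30, 30, 30, 30, 230, 30, 230, 30, 30,
                               230, 230, 30), 4, 3, byrow = TRUE)
  clustered_far <- topo$positions
  clustered_far[ref, ] <- cbind(30 + c(0, 12, 24, 36), 30, 30)
  clustered_on <- topo$positions
  clustered_on[ref, ] <- cbind(150 + c(8, 20, -8, -20), 150, 25)
  traj <- fake_trajectory(list(dispersed, clustered_far, clustered_on), box36)
  trace <- largest_cluster_trace(traj, topo, cfg)
  expect_equal(trace$n_cs, c(1, 4, 4))
  expect_equal(trace$coverage[1:2], c(0, 0))
  expect_gt(trace$coverage[3], 0)
})

test_that("transition-path detection anchors on the final excursion", {
  cfg <- clustering_config("CORELET", 64, stable_size = 20)
  # flat baseline, two failed excursions, then direct passage
  n_cs <- c(rep(2, 40), 8, 12, 9, 2, 2, 10, 14, 2, 2, 2,
            6, 9, 13, 17, 20, 24, 28)
  trace <- make_trace(n_cs)
  path <- detect_transition_path(trace, cfg)
  expect_true(path$reached_stable)
  expect_equal(path$tau_nucl, trace$time[match(20, n_cs)])
  # exhaustive oracle: latest in-band frame before the crossing
  idx_n <- match(TRUE, n_cs >= 20)
  in_band <- which(n_cs[1:(idx_n - 1)] <= path$band[2])
  expect_equal(path$idx_start, max(in_band) + 1L)
  expect_equal(path$t_start, trace$time[max(in_band) + 1L])
})

test_that("non-nucleating and degenerate traces are handled", {
  cfg <- clustering_config("CORELET", 64, stable_size = 25)
  flat <- make_trace(c(rep(3, 50), rep(4, 10)))
  path <- detect_transition_path(flat, cfg)
  expect_false(path$reached_stable)
  expect_true(is.na(path$tau_nucl))
  started_high <- make_trace(c(30, rep(31, 10)))
  expect_error(detect_transition_path(started_high, cfg), "not metastable")
})

test_that("nucleation rate follows J = 1/<tau> with jackknife errors", {
  res <- data.frame(tau_nucl = c(2, 4), reached_stable = c(TRUE, TRUE))
  out <- nucleation_rate(res)
  expect_equal(out$J, 1 / 3)
  expect_equal(out$censored, 0)
  single <- data.frame(tau_nucl = 5, reached_stable = TRUE)
  out1 <- nucleation_rate(single)
  expect_equal(out1$J, 0.2)
  expect_true(is.na(out1$se))
  censored <- data.frame(tau_nucl = c(NA, NA),
                         reached_stable = c(FALSE, FALSE))
  expect_error(nucleation_rate(censored), "no nucleation")
})

test_that("delay time is exact on constructed power-law growth", {
  stable <- 20
  cfg <- clustering_config("CORELET", 64, stable_size = stable,
                           observable_multiplier = 15)
  A <- 2.5
  t0 <- 0
  # N(t) = A t^(3/2): crosses `stable` at t_n, 15x stable at the target
  times <- seq(0, 400, by = 0.5)
  n_cs <- pmax(1, A * pmax(times - t0, 0)^1.5)
  # prepend a metastable baseline strictly below the band-leaving growth
  base <- make_trace(c(rep(1, 20), n_cs[n_cs >= 1]),
                     times = c(seq(-10, -0.5, by = 0.5), times))
  path <- detect_transition_path(base, cfg)
  got <- delay_time(base, cfg, path)
  want <- ((15 * stable) / A)^(2 / 3)
  expect_equal(got, want, tolerance = 0.01)
  # multiplier 1 collapses the delay onto the first-passage time
  cfg1 <- clustering_config("CORELET", 64, stable_size = stable,
                            observable_multiplier = 1)
  expect_equal(delay_time(base, cfg1, detect_transition_path(base, cfg1)),
               path$tau_nucl)
  # doubling the multiplier scales the delay by 2^(2/3) on the power law
  cfg2 <- clustering_config("CORELET", 64, stable_size = stable,
                            observable_multiplier = 30)
  expect_equal(delay_time(base, cfg2, detect_transition_path(base, cfg2)) / got,
               2^(2 / 3), tolerance = 0.01)
})

test_that("delay time requires a growth segment", {
  cfg <- clustering_config("CORELET", 64, stable_size = 10)
  short <- make_trace(c(rep(1, 30), 5, 8, 10, 12))
  expect_error(delay_time(short, cfg), "insufficient growth")
})

test_that("pathways classify by time-averaged chromatin coverage", {
  cfg <- clustering_config("CORELET", 64, stable_size = 10,
                           coverage_threshold = 1)
  on <- make_trace(c(rep(1, 20), 4, 7, 10), coverage = c(rep(0, 20), 5, 6, 7))
  p_on <- detect_transition_path(on, cfg)
  expect_identical(classify_pathway(on, p_on$t_start, p_on$tau_nucl, cfg),
                   "ON_CHROMATIN")
  off <- make_trace(c(rep(1, 20), 4, 7, 10), coverage = 0)
  p_off <- detect_transition_path(off, cfg)
  expect_identical(classify_pathway(off, p_off$t_start, p_off$tau_nucl, cfg),
                   "OFF_CHROMATIN")
})
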