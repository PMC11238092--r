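test_that("WCA closed-form identities hold", {
  s <- 4.5
  at_cut <- wca(2^(1 / 6) * s, s)
  expect_equal(at_cut$energy, 0, tolerance = 1e-12)
  expect_equal(at_cut$force, 0, tolerance = 1e-12)
  expect_equal(wca(s, s, eps_rep = 1)$energy, 1)
  expect_equal(wca(2 * s, s)$energy, 0)
  expect_equal(wca(2 * s, s)$force, 0)
  expect_error(wca(0, s), "singular")
})

test_that("FENE closed forms and domain errors", {
  K <- 30 / 5.5^2
  R0 <- 1.5 * 5.5
  expect_equal(fene(0, K, R0)$energy, 0)
  expect_equal(fene(R0 / 2, K, R0)$energy, -0.5 * K * R0^2 * log(3 / 4))
  expect_lt(fene(0.999 * R0, K, R0)$energy, Inf)
  expect_gt(fene(0.999 * R0, K, R0)$energy, 10)
  expect_error(fene(R0, K, R0), "overstretch")
})

test_that("Flory-Krigbaum closed forms", {
  eps <- 6; rgi <- 3; rgj <- 1.5
  expect_equal(flory_krigbaum(0, eps, rgi, rgj)$energy, -eps)
  expect_true(all(flory_krigbaum(c(0, 2, 10), 0, rgi, rgj)$energy == 0))
  r_half <- sqrt((4 / 3) * (rgi^2 + rgj^2) * log(2))
  expect_equal(flory_krigbaum(r_half, eps, rgi, rgj)$energy, -eps / 2,
               tolerance = 1e-12)
})

test_that("neighbor-list energy matches the all-pairs oracle", {
  p <- default_parameters()
  box <- box_spec(40, 40, 40)
  for (seed in 1:6) {
    g <- random_gas(50, box, seed)
    topo <- condensim:::new_topology(
      g$species, seq_len(50), rep("BRD4", 50),
      data.frame(i = integer(0), j = integer(0), class = character(0)),
      g$positions, box)
    st <- initial_state(topo)
    res <- total_forces(st, topo, p)
    ref <- brute_force_energy(g$positions, g$species,
                              topo$bonds, p, box)
    expect_equal(res$energy$total, ref$total, tolerance = 1e-10)
    expect_equal(res$energy$by_class$WCA, ref$WCA, tolerance = 1e-10)
    expect_equal(res$energy$by_class$FK, ref$FK, tolerance = 1e-10)
  }
})

test_that("neighbor-list energy matches brute force on bonded systems", {
  p <- default_parameters()
  box <- box_spec(120, 120, 120)
  topo <- build_corelet(6)
  topo$box <- box
  topo <- condensim:::translate_topology(topo, c(60, 60, 60))
  st <- initial_state(topo)
  res <- total_forces(st, topo, p)
  ref <- brute_force_energy(st$positions, topo$species, topo$bonds, p, box)
  expect_equal(res$energy$total, ref$total, tolerance = 1e-10)
  expect_equal(res$energy$by_class$FENE, ref$FENE, tolerance = 1e-10)
})

test_that("forces are exact negative gradients of the reported energy", {
  p <- default_parameters()
  box <- box_spec(35, 35, 35)
  h <- 1e-6
  for (seed in 1:3) {
    g <- random_gas(24, box, seed)
    topo <- condensim:::new_topology(
      g$species, seq_len(24), rep("BRD4", 24),
      data.frame(i = integer(0), j = integer(0), class = character(0)),
      g$positions, box)
    st <- initial_state(topo)
    f <- total_forces(st, topo, p)$forces
    # probe a handful of coordinates by central differences
    set.seed(seed)
    for (probe in seq_len(8)) {
      i <- sample(24, 1); d <- sample(3, 1)
      stp <- st
      stp$positions[i, d] <- st$positions[i, d] + h
      stm <- st
      stm$positions[i, d] <- st$positions[i, d] - h
      num <- -(total_forces(stp, topo, p)$energy$total -
               total_forces(stm, topo, p)$energy$total) / (2 * h)
      # relative agreement, with an absolute floor at the finite-difference
      # cancellation noise (energies are O(100) kT)
      denom <- max(abs(f[i, d]), 1)
      expect_lt(abs(num - f[i, d]) / denom, 1e-5)
    }
  }
})

test_that("pair forces obey Newton's third law and translation invariance", {
  p <- default_parameters()
  box <- box_spec(45, 45, 45)
  g <- random_gas(40, box, 11)
  topo <- condensim:::new_topology(
    g$species, seq_len(40), rep("BRD4", 40),
    data.frame(i = integer(0), j = integer(0), class = character(0)),
    g$positions, box)
  st <- initial_state(topo)
  res <- total_forces(st, topo, p)
  expect_lt(max(abs(colSums(res$forces))), 1e-9)
  # rigid shift across the periodic boundary leaves the energy unchanged
  shifted <- st
  shifted$positions <- condensim:::wrap_positions(
    sweep(st$positions, 2, c(17.3, -29.9, 41.1), `+`), box)
  res2 <- total_forces(shifted, topo, p)
  expect_equal(res2$energy$total, res$energy$total, tolerance = 1e-9)
})

test_that("isolated repulsive-only pairs beyond the cutoff feel no force", {
  p <- default_parameters()
  box <- box_spec(60, 60, 60)
  # two plain tails (never attractive) farther than 2^(1/6) sigma apart
  topo <- condensim:::new_topology(
    rep(match("TAIL_PLAIN", condensim:::SPECIES), 2), 1:2,
    rep("CHROMATIN", 2),
    data.frame(i = integer(0), j = integer(0), class = character(0)),
    rbind(c(10, 10, 10), c(16, 10, 10)), box)
  res <- total_forces(initial_state(topo), topo, p)
  expect_equal(max(abs(res$forces)), 0)
  expect_equal(res$energy$total, 0)
})
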