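test_that("chromatin builder produces exact counts", {
  ch <- build_chromatin(400, 0.4, periodic_z = TRUE, seed = 7)
  sp <- condensim:::species_names(ch)
  expect_length(sp, 3600)                       # 400 cores + 3200 tails
  expect_equal(sum(sp == "NUCLEOSOME"), 400)
  expect_equal(sum(sp == "TAIL_ACETYL"), 1280)  # round(0.4 * 3200)
  expect_equal(sum(ch$bonds$class == "NUC_NUC"), 400)  # closed chain
  expect_equal(sum(ch$bonds$class == "NUC_TAIL"), 3200)
  validate_topology(ch)
})

test_that("acetylated-tail count is exact for every fraction and seed", {
  for (f in c(0, 0.1, 0.23, 0.5, 1)) {
    for (seed in c(1, 99)) {
      ch <- build_chromatin(25, f, periodic_z = FALSE, seed = seed)
      expect_equal(sum(condensim:::species_names(ch) == "TAIL_ACETYL"),
                   round(f * 8 * 25))
    }
  }
  # zero acetylation means no tail can attract BRD4_N
  ch0 <- build_chromatin(10, 0, periodic_z = FALSE, seed = 1)
  expect_false(any(condensim:::species_names(ch0) == "TAIL_ACETYL"))
})

test_that("acetylation pattern is deterministic in the seed", {
  a <- build_chromatin(30, 0.3, TRUE, seed = 123)
  b <- build_chromatin(30, 0.3, TRUE, seed = 123)
  c_ <- build_chromatin(30, 0.3, TRUE, seed = 124)
  expect_identical(a$species, b$species)
  expect_false(identical(a$species, c_$species))
})

test_that("chromatin builder rejects invalid inputs", {
  expect_error(build_chromatin(10, 1.2), "acetyl_fraction")
  expect_error(build_chromatin(1, 0.4), "at least 2")
  expect_error(build_chromatin(10, 0.4, TRUE, box = box_spec(50, 50, 500)),
               "incompatible")
})

test_that("BRD4 monomer is a bonded two-blob molecule", {
  b <- build_brd4()
  expect_equal(condensim:::n_particles(b), 2)
  expect_setequal(condensim:::species_names(b), c("BRD4_N", "BRD4_C"))
  expect_equal(nrow(b$bonds), 1)
  expect_identical(b$bonds$class, "BRD4_NC")
})

test_that("Corelets are stars with C-terminal tethers", {
  cl <- build_corelet(6)
  expect_equal(condensim:::n_particles(cl), 13)
  expect_equal(nrow(cl$bonds), 12)
  expect_equal(sum(cl$bonds$class == "CORE_BRD4C"), 6)
  expect_equal(sum(cl$bonds$class == "BRD4_NC"), 6)
  # all tethers attach the core to C-blobs, never N-blobs
  sp <- condensim:::species_names(cl)
  teth <- cl$bonds[cl$bonds$class == "CORE_BRD4C", ]
  other <- ifelse(sp[teth$i] == "CORE", teth$j, teth$i)
  expect_true(all(sp[other] == "BRD4_C"))
  validate_topology(cl)
  # degenerate valences
  expect_equal(condensim:::n_particles(build_corelet(0)), 1)
  expect_equal(nrow(build_corelet(0)$bonds), 0)
  expect_error(build_corelet(-1), "non-negative")
})

test_that("slab systems start as a single dense band without overlaps", {
  p <- default_parameters()
  box <- box_spec(58, 58, 235.2)
  topo <- build_slab_system(24, 6, FALSE, 0, box, seed = 3, params = p)
  expect_equal(condensim:::n_particles(topo), 24 * 13)
  st <- initial_state(topo)
  # packed configuration has no overlap beyond sigma_ij/2
  expect_gte(total_forces(st, topo, p)$min_sep_ratio, 0.5)
  # initial Corelet z coordinates form one contiguous central band
  cores <- which(condensim:::species_names(topo) == "CORE")
  z <- st$positions[cores, 3]
  expect_lt(max(z) - min(z), box$Lz / 2)
  expect_lt(abs(mean(z) - box$Lz / 2), box$Lz / 8)
})

test_that("nucleation systems start dispersed, sized by supersaturation", {
  p <- default_parameters()
  c_sat <- 1e-5
  topo <- build_nucleation_system("CORELET", n_molecules = 24, valence = 6,
                                  n_nucleosomes = 16, acetyl_fraction = 0.4,
                                  supersaturation = 3, seed = 5, params = p,
                                  c_sat = c_sat)
  # lateral area chosen so concentration = S * c_sat
  vol <- topo$box$Lx * topo$box$Ly * topo$box$Lz
  expect_equal(24 / vol, 3 * c_sat, tolerance = 1e-6)
  # dispersed start: largest cluster below the stable-nucleus threshold
  cfg <- clustering_config("CORELET", 24)
  st <- initial_state(topo)
  labs <- find_clusters(st, topo, cfg)
  expect_lt(max(table(labs)), cfg$stable_size)
  # identical seeds give identical configurations
  topo2 <- build_nucleation_system("CORELET", 24, 6, 16, 0.4, 3, seed = 5,
                                   params = p, c_sat = c_sat)
  expect_identical(topo$positions, topo2$positions)
  expect_error(
    build_nucleation_system("CORELET", 24, 6, 16, 0.4, supersaturation = 0.9,
                            params = p, c_sat = c_sat),
    "supersaturation")
})

test_that("topology tables round-trip through plain-text serialization", {
  p <- default_parameters()
  topo <- build_slab_system(6, 3, FALSE, 0, box_spec(50, 50, 120), 2, p)
  prefix <- tempfile()
  write_topology(topo, prefix)
  back <- read_topology(prefix)
  expect_identical(back$species, topo$species)
  expect_identical(back$molecule_id, topo$molecule_id)
  expect_equal(back$positions, topo$positions, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(nrow(back$bonds), nrow(topo$bonds))
})
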