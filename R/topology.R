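# System builders: chromatin chains, BRD4 monomers, Corelets, slab and
# nucleation systems, plus topology validation and bookkeeping.

# Spacing at which a NUC_NUC FENE bond balances nucleosome WCA repulsion;
# periodic chromatin chains are built straight at this spacing, so the box
# length along z is n_nucleosomes * NUC_SPACING.
NUC_SPACING <- 9.8
# Contour-to-span ratio of periodic chromatin: the chain carries twice the
# contour the box is long, so bridging interactions can loop and compact
# it (a taut chain cannot be compacted at all, and the compaction a chain
# can express is capped by its slack).
CHAIN_SLACK <- 2
TAIL_RADIUS <- 5.75       # tail blob distance from its nucleosome centre
CORE_CBLOB_RADIUS <- 8.9  # C-blob tether distance from the Corelet core
BRD4_BOND_REST <- 5.35    # N-blob to C-blob rest separation

#' Box specification
#'
#' @param Lx,Ly,Lz Box edge lengths in nm (all periodic).
#' @param z_fixed Whether the z edge is held fixed under lateral pressure
#'   coupling (it always is; the flag is informational).
#' @export
box_spec <- function(Lx, Ly, Lz, z_fixed = TRUE) {
  stopifnot(Lx > 0, Ly > 0, Lz > 0)
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz,
                 periodic = c(TRUE, TRUE, TRUE), z_fixed = z_fixed),
            class = "box_spec")
}

box_lengths <- function(box) c(box$Lx, box$Ly, box$Lz)

new_topology <- function(species, molecule_id, molecule_kind, bonds,
                         positions, box = NULL, acetylation = NULL) {
  structure(list(
    species = as.integer(species),           # index into SPECIES
    molecule_id = as.integer(molecule_id),
    molecule_kind = molecule_kind,            # one entry per molecule
    bonds = bonds,                            # data.frame(i, j, class)
    positions = positions,
    box = box
  ), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d particles, %d molecules, %d bonds\n",
              n_particles(x), length(x$molecule_kind), nrow(x$bonds)))
  tab <- table(SPECIES[x$species])
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$box))
    cat(sprintf("  box: %.4g x %.4g x %.4g nm\n", x$box$Lx, x$box$Ly, x$box$Lz))
  invisible(x)
}

n_particles <- function(topology) length(topology$species)

species_names <- function(topology) SPECIES[topology$species]

#' Per-molecule summary table
#' @param topology A `topology`.
#' @return data.frame with molecule id, kind and particle count.
#' @export
molecule_table <- function(topology) {
  ids <- sort(unique(topology$molecule_id))
  data.frame(
    molecule_id = ids,
    kind = topology$molecule_kind[ids],
    n_particles = as.integer(table(factor(topology$molecule_id, levels = ids)))
  )
}

#' Per-molecule reference particles
#'
#' One particle per condensing molecule, used for clustering and density
#' profiles: the CORE particle of a Corelet, the C-blob of a free BRD4
#' molecule.
#' @param topology A `topology`.
#' @return Integer particle indices ordered by molecule id.
#' @export
reference_particles <- function(topology) {
  kind <- topology$molecule_kind[topology$molecule_id]
  sp <- species_names(topology)
  idx <- which((kind == "CORELET" & sp == "CORE") |
               (kind == "BRD4" & sp == "BRD4_C"))
  idx[order(topology$molecule_id[idx])]
}

#' Build a single two-blob BRD4 molecule
#'
#' One N-terminal and one C-terminal blob joined by a FENE bond.
#' @param center Position of the C-blob.
#' @param direction Unit vector from C- to N-blob.
#' @export
build_brd4 <- function(center = c(0, 0, 0), direction = c(0, 0, 1)) {
  direction <- direction / sqrt(sum(direction^2))
  pos <- rbind(center + BRD4_BOND_REST * direction, center)
  new_topology(
    species = match(c("BRD4_N", "BRD4_C"), SPECIES),
    molecule_id = c(1L, 1L),
    molecule_kind = "BRD4",
    bonds = data.frame(i = 1L, j = 2L, class = "BRD4_NC"),
    positions = pos
  )
}

# Near-uniform directions on the unit sphere (deterministic).
fibonacci_sphere <- function(n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a Corelet of given valence
#'
#' A central oligomerization-platform core particle with `valence` BRD4
#' molecules tethered by their C-terminal blobs (FENE bonds to the core);
#' blobs are placed radially without overlap.
#'
#' @param valence Number of tethered BRD4 molecules (>= 0).
#' @export
build_corelet <- function(valence) {
  if (valence < 0) stop("valence must be non-negative")
  valence <- as.integer(valence)
  dirs <- fibonacci_sphere(valence)
  pos <- matrix(0, 1 + 2L * valence, 3)
  species <- integer(1 + 2L * valence)
  species[1] <- match("CORE", SPECIES)
  bonds <- list()
  for (k in seq_len(valence)) {
    u <- dirs[k, ]
    ic <- 2L * k       # C-blob row
    inn <- 2L * k + 1L # N-blob row
    pos[ic, ] <- CORE_CBLOB_RADIUS * u
    pos[inn, ] <- (CORE_CBLOB_RADIUS + BRD4_BOND_REST) * u
    species[ic] <- match("BRD4_C", SPECIES)
    species[inn] <- match("BRD4_N", SPECIES)
    bonds[[length(bonds) + 1L]] <- data.frame(i = 1L, j = ic, class = "CORE_BRD4C")
    bonds[[length(bonds) + 1L]] <- data.frame(i = inn, j = ic, class = "BRD4_NC")
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(0), j = integer(0), class = character(0))
  new_topology(species, rep(1L, nrow(pos)), "CORELET", bonds, pos)
}

#' Build a chromatin chain
#'
#' A chain of nucleosome core particles along z, each decorated with 8
#' histone-tail blobs, with sequential FENE bonds (closed across the z
#' boundary when `periodic_z`). Exactly `round(acetyl_fraction * 8 n)` tails
#' are flagged acetylated, chosen uniformly at random by `seed`.
#'
#' @param n_nucleosomes Number of nucleosomes (>= 2).
#' @param acetyl_fraction Fraction of the 8n tails in the BRD4-attractive
#'   acetylated state, in `[0, 1]`.
#' @param periodic_z Close the chain across the z boundary; requires the
#'   chain contour (`n * 9.8 / slack` nm) to match the box when a box is
#'   given.
#' @param seed Integer seed controlling the acetylation pattern.
#' @param center x-y position of the chain axis.
#' @param box Optional `box_spec`; checked for compatibility.
#' @param slack Ratio of chain contour length to its end-to-end span along
#'   z. 1 builds a straight, taut chain; values > 1 lay the excess contour
#'   on a helix of integer `turns` around the axis, leaving the chain free
#'   to loop and compact locally (a taut chain cannot be compacted by
#'   bridging interactions at all).
#' @param turns Helix turns used to absorb the slack (integer, so the
#'   periodic closure matches); `NULL` picks the fewest turns that keep
#'   the helix radius within a quarter of the lateral box.
#' @export
build_chromatin <- function(n_nucleosomes, acetyl_fraction, periodic_z = TRUE,
                            seed = 1L, center = c(0, 0), box = NULL,
                            slack = 1, turns = NULL) {
  if (n_nucleosomes < 2) stop("need at least 2 nucleosomes")
  if (acetyl_fraction < 0 || acetyl_fraction > 1)
    stop("acetyl_fraction must be in [0, 1]")
  stopifnot(slack >= 1)
  n <- as.integer(n_nucleosomes)
  span <- n * NUC_SPACING / slack
  if (periodic_z && !is.null(box) && abs(span - box$Lz) > 0.05 * box$Lz)
    stop(sprintf(
      "chain span (%.1f nm at slack %.2f) incompatible with periodic box Lz = %.1f nm",
      span, slack, box$Lz))

  # helix radius absorbing the contour excess: per-nucleosome arc =
  # sqrt(dz^2 + (2 pi R turns / n)^2) = NUC_SPACING
  dz <- span / n
  lat <- sqrt(max(0, NUC_SPACING^2 - dz^2))
  if (is.null(turns)) {
    r_max <- if (!is.null(box)) 0.25 * min(box$Lx, box$Ly) else 16
    turns <- max(2L, ceiling(n * lat / (2 * pi * r_max)))
  }
  r_helix <- n * lat / (2 * pi * max(1L, as.integer(turns)))

  tail_dirs <- rbind(
    expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  )
  tail_dirs <- as.matrix(tail_dirs) / sqrt(3)

  npart <- n * 9L
  pos <- matrix(0, npart, 3)
  species <- integer(npart)
  molecule_id <- rep(1L, npart)
  for (i in seq_len(n)) {
    base <- (i - 1L) * 9L
    zc <- (i - 0.5) * dz
    phi <- 2 * pi * as.integer(turns) * (i - 0.5) / n
    cc <- c(center[1] + r_helix * cos(phi), center[2] + r_helix * sin(phi), zc)
    pos[base + 1L, ] <- cc
    species[base + 1L] <- match("NUCLEOSOME", SPECIES)
    for (t in 1:8) {
      pos[base + 1L + t, ] <- cc + TAIL_RADIUS * tail_dirs[t, ]
      species[base + 1L + t] <- match("TAIL_PLAIN", SPECIES)
    }
  }

  tail_idx <- which(species == match("TAIL_PLAIN", SPECIES))
  n_ac <- round(acetyl_fraction * 8 * n)
  if (n_ac > 0) {
    chosen <- with_seed(seed, sample(tail_idx, n_ac))
    species[chosen] <- match("TAIL_ACETYL", SPECIES)
  }

  nuc_idx <- seq(1L, npart, by = 9L)
  bb <- data.frame(i = nuc_idx[-n], j = nuc_idx[-1], class = "NUC_NUC")
  if (periodic_z)
    bb <- rbind(bb, data.frame(i = nuc_idx[n], j = nuc_idx[1], class = "NUC_NUC"))
  tails <- data.frame(
    i = rep(nuc_idx, each = 8L),
    j = setdiff(seq_len(npart), nuc_idx),
    class = "NUC_TAIL"
  )
  new_topology(species, molecule_id, "CHROMATIN", rbind(bb, tails), pos, box)
}

translate_topology <- function(topology, vec) {
  topology$positions <- sweep(topology$positions, 2, vec, `+`)
  topology
}

rotate_topology <- function(topology, R, about = c(0, 0, 0)) {
  p <- sweep(topology$positions, 2, about, `-`)
  topology$positions <- sweep(p %*% t(R), 2, about, `+`)
  topology
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

combine_topologies <- function(fragments, box) {
  off_p <- 0L
  off_m <- 0L
  parts <- lapply(fragments, function(fr) {
    b <- fr$bonds
    b$i <- b$i + off_p
    b$j <- b$j + off_p
    out <- list(species = fr$species, molecule_id = fr$molecule_id + off_m,
                kind = fr$molecule_kind, bonds = b, pos = fr$positions)
    off_p <<- off_p + n_particles(fr)
    off_m <<- off_m + length(fr$molecule_kind)
    out
  })
  new_topology(
    species = unlist(lapply(parts, `[[`, "species")),
    molecule_id = unlist(lapply(parts, `[[`, "molecule_id")),
    molecule_kind = unlist(lapply(parts, `[[`, "kind")),
    bonds = do.call(rbind, lapply(parts, `[[`, "bonds")),
    positions = do.call(rbind, lapply(parts, `[[`, "pos")),
    box = box
  )
}

#' Structural validation of a topology
#'
#' Checks bond references, the Corelet star structure (1 core, v C-blobs,
#' v N-blobs, v tether and v intramolecular bonds), the two-particle BRD4
#' structure, the 8-tails-per-nucleosome rule and chromatin chain
#' connectivity.
#' @param topology A `topology`.
#' @return Invisibly `TRUE`; errors describe the first violation found.
#' @export
validate_topology <- function(topology) {
  np <- n_particles(topology)
  b <- topology$bonds
  if (nrow(b) && (any(b$i < 1 | b$i > np) || any(b$j < 1 | b$j > np)))
    stop("bond references a non-existent particle")
  sp <- species_names(topology)
  for (m in seq_along(topology$molecule_kind)) {
    sel <- topology$molecule_id == m
    kind <- topology$molecule_kind[m]
    msp <- sp[sel]
    midx <- which(sel)
    mb <- b[b$i %in% midx | b$j %in% midx, ]
    if (kind == "CORELET") {
      v <- sum(msp == "BRD4_C")
      if (sum(msp == "CORE") != 1 || sum(msp == "BRD4_N") != v ||
          length(msp) != 1 + 2 * v)
        stop("malformed Corelet (molecule ", m, ")")
      if (sum(mb$class == "CORE_BRD4C") != v || sum(mb$class == "BRD4_NC") != v)
        stop("malformed Corelet bond set (molecule ", m, ")")
      tether_j <- with(mb[mb$class == "CORE_BRD4C", ], ifelse(sp[i] == "CORE", j, i))
      if (length(tether_j) && !all(sp[tether_j] == "BRD4_C"))
        stop("Corelet tethers must attach to C-blobs")
    } else if (kind == "BRD4") {
      if (!setequal(msp, c("BRD4_N", "BRD4_C")) || length(msp) != 2)
        stop("malformed BRD4 molecule ", m)
    } else if (kind == "CHROMATIN") {
      n_nuc <- sum(msp == "NUCLEOSOME")
      if (sum(msp %in% c("TAIL_PLAIN", "TAIL_ACETYL")) != 8 * n_nuc)
        stop("each nucleosome carries exactly 8 tails")
      nb <- sum(mb$class == "NUC_NUC")
      if (nb != n_nuc - 1 && nb != n_nuc)
        stop("chromatin backbone must be a single (optionally closed) chain")
    }
  }
  invisible(TRUE)
}

relax_positions <- function(topology, params, n_steps = 400, max_disp = 0.1) {
  tab <- pair_tables(params)
  bc <- bond_constants(params, topology$bonds$class)
  topology$positions <- cpp_minimize(
    topology$positions, topology$species - 1L, tab,
    topology$bonds$i - 1L, topology$bonds$j - 1L, bc$K, bc$R0^2,
    box_lengths(topology$box), as.integer(n_steps), max_disp)
  topology
}

check_packing <- function(topology, params, min_ratio = 0.5) {
  fr <- total_forces(initial_state(topology), topology, params)
  if (fr$min_sep_ratio < min_ratio)
    stop("packing failed: particle overlap beyond sigma_ij/2 after relaxation")
  invisible(TRUE)
}

#' Build a direct-coexistence slab system
#'
#' Corelets are packed into a dense slab spanning the x-y cross-section at
#' the box centre in z, optionally threaded by a periodic chromatin chain
#' along z, then relaxed by capped steepest descent.
#'
#' @param n_corelets Number of Corelets.
#' @param valence BRD4 molecules per Corelet.
#' @param with_chromatin Add a periodic chromatin chain through the slab.
#' @param acetyl_fraction Acetylated tail fraction (chromatin systems).
#' @param box A `box_spec`. With chromatin the chain contour fixes
#'   `Lz = n_nucleosomes * 9.8` nm; `n_nucleosomes` is derived from `Lz`.
#' @param seed Integer seed (placement jitter, acetylation pattern).
#' @param params Model parameters.
#' @param lattice_spacing Initial slab lattice constant (nm).
#' @export
build_slab_system <- function(n_corelets, valence, with_chromatin = FALSE,
                              acetyl_fraction = 0, box, seed = 1L,
                              params = default_parameters(),
                              lattice_spacing = 18) {
  n_corelets <- as.integer(n_corelets)
  frags <- list()
  nuc_pos <- NULL
  if (with_chromatin) {
    n_nuc <- max(2L, round(box$Lz * CHAIN_SLACK / NUC_SPACING))
    box <- box_spec(box$Lx, box$Ly, n_nuc * NUC_SPACING / CHAIN_SLACK)
    frags[[1]] <- build_chromatin(n_nuc, acetyl_fraction, periodic_z = TRUE,
                                  seed = split_seed(seed, 1L),
                                  center = c(box$Lx / 2, box$Ly / 2),
                                  box = box, slack = CHAIN_SLACK)
    nuc_pos <- frags[[1]]$positions[
      species_names(frags[[1]]) == "NUCLEOSOME", , drop = FALSE]
  }
  a <- lattice_spacing
  nx <- max(1L, floor(box$Lx / a))
  ny <- max(1L, floor(box$Ly / a))
  sites <- expand.grid(
    x = (seq_len(nx) - 0.5) * box$Lx / nx,
    y = (seq_len(ny) - 0.5) * box$Ly / ny
  )
  if (nrow(sites) < 1) stop("packing failed: no lattice sites available")
  layers <- ceiling(n_corelets / nrow(sites)) + if (with_chromatin) 2L else 0L
  if (layers * a > 0.8 * box$Lz)
    stop("packing failed: slab would fill the box; enlarge Lz or the box cross-section")
  clear_of_chain <- function(at) {
    is.null(nuc_pos) ||
      min(mindist1(nuc_pos[, 1] - at[1], box$Lx)^2 +
            mindist1(nuc_pos[, 2] - at[2], box$Ly)^2 +
            mindist1(nuc_pos[, 3] - at[3], box$Lz)^2) > 13^2
  }
  placed <- 0L
  with_seed(split_seed(seed, 2L), {
    for (l in seq_len(layers)) {
      zc <- (box$Lz / 2 + (l - (layers + 1) / 2) * a) %% box$Lz
      ord <- sample(nrow(sites))
      for (s in ord) {
        if (placed >= n_corelets) break
        at <- c(sites$x[s], sites$y[s], zc) + runif(3, -1.5, 1.5)
        if (!clear_of_chain(at)) next
        placed <- placed + 1L
        cor <- build_corelet(valence)
        cor <- rotate_topology(cor, random_rotation())
        cor <- translate_topology(cor, at)
        frags[[length(frags) + 1L]] <- cor
      }
    }
  })
  if (placed < n_corelets)
    stop("packing failed: could not place all Corelets clear of the chain")
  topo <- combine_topologies(frags, box)
  topo$positions <- wrap_positions(topo$positions, box)
  topo <- relax_positions(topo, params)
  check_packing(topo, params)
  validate_topology(topo)
  topo
}

wrap_positions <- function(pos, box) {
  L <- box_lengths(box)
  for (d in 1:3) pos[, d] <- pos[, d] - L[d] * floor(pos[, d] / L[d])
  pos
}

#' Build a supersaturated nucleation system
#'
#' Condensing molecules (Corelets or free BRD4) are dispersed uniformly at
#' random around a periodic chromatin chain. The lateral box area is chosen
#' so that the initial molecule concentration equals
#' `supersaturation * c_sat`, where the saturation density `c_sat` comes
#' from the stored coexistence reference (see [saturation_density()]) unless
#' supplied directly.
#'
#' @param kind `"CORELET"` or `"ENDOGENOUS"` (free BRD4 monomers).
#' @param n_molecules Number of condensing molecules.
#' @param valence Corelet valence (CORELET only).
#' @param n_nucleosomes Chromatin length; fixes `Lz = n * 9.8` nm.
#' @param acetyl_fraction Acetylated tail fraction.
#' @param supersaturation Ratio S of initial to saturation concentration
#'   (> 1).
#' @param seed Integer seed.
#' @param params Model parameters.
#' @param c_sat Saturation number density (molecules/nm^3); looked up from
#'   the stored reference when `NULL`.
#' @param min_separation Minimum initial reference-point separation (nm).
#' @return A `topology` with relaxed initial positions.
#' @export
build_nucleation_system <- function(kind = c("CORELET", "ENDOGENOUS"),
                                    n_molecules, valence = NULL,
                                    n_nucleosomes, acetyl_fraction,
                                    supersaturation, seed = 1L,
                                    params = default_parameters(),
                                    c_sat = NULL, min_separation = NULL,
                                    chain_slack = CHAIN_SLACK) {
  kind <- match.arg(kind)
  if (supersaturation <= 1)
    stop("supersaturation must exceed 1 (metastable start)")
  if (kind == "CORELET" && is.null(valence))
    stop("valence required for Corelet systems")
  if (is.null(c_sat))
    c_sat <- saturation_density(kind = kind,
                                valence = if (kind == "CORELET") valence else NA)
  n_molecules <- as.integer(n_molecules)
  Lz <- n_nucleosomes * NUC_SPACING / chain_slack
  conc <- supersaturation * c_sat
  A <- n_molecules / (conc * Lz)
  Lxy <- sqrt(A)
  box <- box_spec(Lxy, Lxy, Lz)
  chrom <- build_chromatin(n_nucleosomes, acetyl_fraction, periodic_z = TRUE,
                           seed = split_seed(seed, 1L),
                           center = c(Lxy / 2, Lxy / 2), box = box,
                           slack = chain_slack)
  if (is.null(min_separation))
    min_separation <- if (kind == "CORELET") 27 else 14
  # molecules are placed uniformly, keeping clear only of the sterically
  # occupied chain itself (chain-proximal positions as likely as bulk)
  nuc_pos <- chrom$positions[species_names(chrom) == "NUCLEOSOME", ,
                             drop = FALSE]
  centers <- with_seed(split_seed(seed, 2L),
                       dart_throw(n_molecules, box, min_separation,
                                  obstacles = nuc_pos, obstacle_sep = 13))
  frags <- list(chrom)
  with_seed(split_seed(seed, 3L), {
    for (m in seq_len(n_molecules)) {
      frag <- if (kind == "CORELET") build_corelet(valence) else build_brd4()
      frag <- rotate_topology(frag, random_rotation())
      frags[[length(frags) + 1L]] <- translate_topology(frag, centers[m, ])
    }
  })
  topo <- combine_topologies(frags, box)
  topo$positions <- wrap_positions(topo$positions, box)
  topo <- relax_positions(topo, params, n_steps = 250)
  check_packing(topo, params)
  topo
}

# Random sequential placement with a pairwise minimum distance (minimum
# image) and optional obstacle points (e.g. nucleosomes) that candidates
# must keep clear of. The minimum distance is relaxed stepwise if
# placement stalls.
dart_throw <- function(n, box, min_sep, obstacles = NULL, obstacle_sep = 13) {
  L <- box_lengths(box)
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  sep <- min_sep
  tries <- 0L
  while (placed < n) {
    cand <- runif(3) * L
    ok <- TRUE
    if (!is.null(obstacles)) {
      dx <- mindist1(obstacles[, 1] - cand[1], L[1])
      dy <- mindist1(obstacles[, 2] - cand[2], L[2])
      dz <- mindist1(obstacles[, 3] - cand[3], L[3])
      if (min(dx^2 + dy^2 + dz^2) < obstacle_sep^2) ok <- FALSE
    }
    if (ok && placed > 0) {
      dx <- mindist1(pts[1:placed, 1] - cand[1], L[1])
      dy <- mindist1(pts[1:placed, 2] - cand[2], L[2])
      dz <- mindist1(pts[1:placed, 3] - cand[3], L[3])
      if (min(dx^2 + dy^2 + dz^2) < sep^2) ok <- FALSE
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > 2000L) {
        sep <- sep * 0.9
        tries <- 0L
        if (sep < 5) stop("packing failed: cannot disperse molecules in the box")
      }
    }
  }
  pts
}

mindist1 <- function(d, L) {
  d <- d - L * round(d / L)
  d
}

#' Build a dispersed (gas) system at a given box and composition
#'
#' Corelets placed uniformly at random (minimum pairwise separation, clear
#' of the chain) in the given box, optionally around a periodic chromatin
#' chain with the standard contour slack. Used by condensation scans,
#' which start from the mixed state and ask whether a dense phase forms.
#'
#' @inheritParams build_slab_system
#' @export
build_dispersed_system <- function(n_corelets, valence, with_chromatin = FALSE,
                                   acetyl_fraction = 0, box, seed = 1L,
                                   params = default_parameters(),
                                   min_separation = 27) {
  n_corelets <- as.integer(n_corelets)
  frags <- list()
  nuc_pos <- NULL
  if (with_chromatin) {
    n_nuc <- max(2L, round(box$Lz * CHAIN_SLACK / NUC_SPACING))
    box <- box_spec(box$Lx, box$Ly, n_nuc * NUC_SPACING / CHAIN_SLACK)
    frags[[1]] <- build_chromatin(n_nuc, acetyl_fraction, periodic_z = TRUE,
                                  seed = split_seed(seed, 1L),
                                  center = c(box$Lx / 2, box$Ly / 2),
                                  box = box, slack = CHAIN_SLACK)
    nuc_pos <- frags[[1]]$positions[
      species_names(frags[[1]]) == "NUCLEOSOME", , drop = FALSE]
  }
  centers <- with_seed(split_seed(seed, 2L),
                       dart_throw(n_corelets, box, min_separation,
                                  obstacles = nuc_pos))
  with_seed(split_seed(seed, 3L), {
    for (m in seq_len(n_corelets)) {
      frag <- rotate_topology(build_corelet(valence), random_rotation())
      frags[[length(frags) + 1L]] <- translate_topology(frag, centers[m, ])
    }
  })
  topo <- combine_topologies(frags, box)
  topo$positions <- wrap_positions(topo$positions, box)
  topo <- relax_positions(topo, params, n_steps = 250)
  check_packing(topo, params)
  topo
}

#' Initial simulation state from a built topology
#' @param topology A `topology` with positions and a box.
#' @export
initial_state <- function(topology) {
  if (is.null(topology$box)) stop("topology has no box")
  structure(list(positions = topology$positions, box = topology$box,
                 time = 0), class = "sim_state")
}
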