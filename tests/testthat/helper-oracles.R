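# Independent reference implementations used as oracles. These deliberately
# avoid the package's neighbor-list machinery: energies are direct O(N^2)
# sums over all pairs, clustering is breadth-first search on the full
# distance matrix.

min_image <- function(d, L) d - L * round(d / L)

# All-pairs energy (WCA + truncated/shifted FK + FENE) under minimum image.
brute_force_energy <- function(pos, species, bonds, params, box) {
  L <- c(box$Lx, box$Ly, box$Lz)
  sp <- params$species
  sig <- sp$sigma
  rg <- sp$rg
  tol <- params$fk_cut_tol
  n <- nrow(pos)
  e_wca <- 0
  e_fk <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d <- min_image(pos[i, ] - pos[j, ], L)
      r <- sqrt(sum(d^2))
      si <- species[i]; sj <- species[j]
      sij <- (sig[si] + sig[sj]) / 2
      if (r < 2^(1 / 6) * sij) {
        s6 <- (sij / r)^6
        e_wca <- e_wca + 4 * params$wca_epsilon * (s6^2 - s6) + params$wca_epsilon
      }
      eps <- params$eps[si, sj]
      if (eps > tol) {
        alpha <- 3 / (4 * (rg[si]^2 + rg[sj]^2))
        rcut2 <- log(eps / tol) / alpha
        if (r^2 < rcut2) e_fk <- e_fk + (-eps * exp(-alpha * r^2) + tol)
      }
    }
  }
  e_fene <- 0
  if (nrow(bonds)) {
    bc <- condensim:::bond_constants(params, bonds$class)
    for (b in seq_len(nrow(bonds))) {
      d <- min_image(pos[bonds$i[b], ] - pos[bonds$j[b], ], L)
      r2 <- sum(d^2)
      e_fene <- e_fene - 0.5 * bc$K[b] * bc$R0[b]^2 * log(1 - r2 / bc$R0[b]^2)
    }
  }
  list(WCA = e_wca, FK = e_fk, FENE = e_fene, total = e_wca + e_fk + e_fene)
}

# Single-linkage clustering by BFS on the full distance matrix.
bfs_clusters <- function(pts, L, rcut) {
  m <- nrow(pts)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      d <- min_image(pts[i, ] - pts[j, ], L)
      adj[i, j] <- sum(d^2) <= rcut^2
    }
  }
  lab <- integer(m)
  comp <- 0L
  for (s in seq_len(m)) {
    if (lab[s] > 0) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & lab == 0L)
      lab[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  # relabel by smallest member index to match the package convention
  vapply(lab, function(cc) min(which(lab == cc)), integer(1))
}

# A small random mixed-species gas used by force/energy tests.
random_gas <- function(n, box, seed, species_pool = NULL, min_sep = 2.5) {
  if (is.null(species_pool))
    species_pool <- match(c("BRD4_N", "BRD4_C", "TAIL_ACETYL", "CORE"),
                          condensim:::SPECIES)
  set.seed(seed)
  L <- c(box$Lx, box$Ly, box$Lz)
  pos <- matrix(NA_real_, n, 3)
  k <- 0L
  while (k < n) {
    cand <- runif(3) * L
    ok <- TRUE
    if (k > 0) {
      dx <- min_image(pos[1:k, 1] - cand[1], L[1])
      dy <- min_image(pos[1:k, 2] - cand[2], L[2])
      dz <- min_image(pos[1:k, 3] - cand[3], L[3])
      ok <- min(dx^2 + dy^2 + dz^2) >= min_sep^2
    }
    if (ok) {
      k <- k + 1L
      pos[k, ] <- cand
    }
  }
  list(positions = pos,
       species = sample(species_pool, n, replace = TRUE))
}

# Wrap a list of position frames into a minimal trajectory object for the
# analysis functions.
fake_trajectory <- function(frames, box, times = NULL) {
  nfr <- length(frames)
  if (is.null(times)) times <- seq_len(nfr) - 1
  structure(list(
    frames = frames, times = times,
    box = data.frame(Lx = rep(box$Lx, nfr), Ly = rep(box$Ly, nfr),
                     Lz = rep(box$Lz, nfr)),
    energy = data.frame(WCA = numeric(nfr), FK = numeric(nfr),
                        FENE = numeric(nfr)),
    lateral_pressure = numeric(nfr), min_sep_ratio = 1,
    stopped_at_step = -1L, config = NULL,
    final_state = structure(list(positions = frames[[nfr]], box = box,
                                 time = times[nfr]), class = "sim_state")
  ), class = "trajectory")
}

# Minimal topology holding bare molecules of one species (used to exercise
# profile/cluster analysis without a full build).
point_topology <- function(n, kind = "CORELET", box = NULL) {
  sp <- if (kind == "CORELET") "CORE" else "NUCLEOSOME"
  condensim:::new_topology(
    species = rep(match(sp, condensim:::SPECIES), n),
    molecule_id = seq_len(n),
    molecule_kind = rep(if (kind == "CORELET") "CORELET" else "CHROMATIN", n),
    bonds = data.frame(i = integer(0), j = integer(0), class = character(0)),
    positions = matrix(0, n, 3), box = box)
}
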