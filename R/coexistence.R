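# Direct-coexistence slab analysis: density profiles along z, coexistence
# densities, finite-condensate detection (3-fold criterion), critical
# valence scans and phase-diagram assembly.

profile_particle_indices <- function(topology, species_group) {
  kind <- topology$molecule_kind[topology$molecule_id]
  sp <- species_names(topology)
  idx <- switch(species_group,
    CORELET = which(kind == "CORELET" & sp == "CORE"),
    CORELET_ALL = which(kind == "CORELET"),
    BRD4 = which(kind == "BRD4" & sp == "BRD4_C"),
    NUCLEOSOME = which(sp == "NUCLEOSOME"),
    stop("unknown species group: ", species_group))
  if (!length(idx)) stop("empty species group: ", species_group)
  idx
}

#' Time-averaged density profile along z
#'
#' Histograms molecule reference points (Corelet cores, free-BRD4 C-blobs,
#' or nucleosome particles) along the box z axis over the post-equilibration
#' frames. Each frame's histogram is circularly re-centred on the slab
#' (the circular centre of mass of the distribution) before averaging, so
#' a drifting slab does not smear the profile.
#'
#' @param trajectory A `trajectory`.
#' @param topology The matching `topology`.
#' @param species_group `"CORELET"`, `"BRD4"` or `"NUCLEOSOME"`.
#' @param n_bins Number of z bins (>= 8).
#' @param equilibration_fraction Leading fraction of frames discarded.
#' @param align Recentre per-frame histograms on the slab.
#' @return A `density_profile`: bin centres (nm) and time-averaged number
#'   densities (molecules/nm^3).
#' @export
density_profile <- function(trajectory, topology, species_group = "CORELET",
                            n_bins = 24, equilibration_fraction = 0.5,
                            align = TRUE) {
  stopifnot(n_bins >= 8)
  idx <- profile_particle_indices(topology, species_group)
  nfr <- length(trajectory$frames)
  first <- floor(equilibration_fraction * nfr) + 1L
  if (first > nfr)
    stop("trajectory shorter than the equilibration window")
  Lz <- trajectory$box$Lz[1]
  binw <- Lz / n_bins
  acc <- numeric(n_bins)
  for (f in first:nfr) {
    z <- trajectory$frames[[f]][idx, 3]
    z <- z - Lz * floor(z / Lz)
    counts <- tabulate(pmin(n_bins, floor(z / binw) + 1L), nbins = n_bins)
    if (align) {
      theta <- 2 * pi * z / Lz
      ang <- atan2(sum(sin(theta)), sum(cos(theta))) %% (2 * pi)
      shift <- round(n_bins / 2 - ang / (2 * pi) * n_bins)
      counts <- counts[((seq_len(n_bins) - 1L - shift) %% n_bins) + 1L]
    }
    area <- trajectory$box$Lx[f] * trajectory$box$Ly[f]
    acc <- acc + counts / (area * binw)
  }
  structure(list(
    z = (seq_len(n_bins) - 0.5) * binw,
    density = acc / (nfr - first + 1L),
    species_group = species_group,
    n_bins = n_bins, n_frames = nfr - first + 1L, Lz = Lz, bin_width = binw
  ), class = "density_profile")
}

profile_ratio <- function(profile) {
  d <- profile$density
  if (max(d) == 0) return(NaN)
  if (min(d) == 0) return(Inf)
  max(d) / min(d)
}

#' Dilute and dense coexistence densities from a slab profile
#'
#' The dense plateau is the mean over bins above 70% of the profile
#' maximum; the dilute plateau the mean over bins below 30% of the maximum,
#' excluding bins adjacent to interfacial or dense bins. Standard errors
#' are over the bins entering each plateau.
#'
#' @param profile A `density_profile`.
#' @return list with `dilute`, `dense`, `dilute_se`, `dense_se`.
#' @export
coexistence_densities <- function(profile) {
  d <- profile$density
  r <- profile_ratio(profile)
  if (is.nan(r) || r < 1.5)
    stop("no slab: density profile shows no plateau separation")
  hi <- d >= 0.7 * max(d)
  lo <- d <= 0.3 * max(d)
  n <- length(d)
  nb_prev <- c(n, seq_len(n - 1))
  nb_next <- c(seq.int(2, n), 1)
  interfacial <- !hi & !lo
  lo_keep <- lo & !(hi[nb_prev] | hi[nb_next] | interfacial[nb_prev] | interfacial[nb_next])
  if (!any(lo_keep)) lo_keep <- d == min(d)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(dilute = mean(d[lo_keep]), dense = mean(d[hi]),
       dilute_se = se(d[lo_keep]), dense_se = se(d[hi]))
}

#' Detect a finite-size condensate from density profiles
#'
#' A condensate is flagged when the maximum and minimum bin densities along
#' z differ at least 3-fold (inclusive) for either the condensing-molecule
#' profile or the nucleosome profile; zero-count minimum bins count as an
#' infinite ratio. The nucleosome criterion catches chromatin compaction in
#' systems where the Corelet enrichment alone is weak.
#'
#' @param profile Condensing-molecule `density_profile`.
#' @param nucleosome_profile Optional nucleosome `density_profile`.
#' @export
detect_condensate <- function(profile, nucleosome_profile = NULL) {
  ratios <- profile_ratio(profile)
  if (!is.null(nucleosome_profile))
    ratios <- c(ratios, profile_ratio(nucleosome_profile))
  ratios <- ratios[!is.nan(ratios)]
  length(ratios) > 0 && any(ratios >= 3)
}

# Ratio of dense to dilute plateau means (70%/30% thresholds with
# interfacial-bin exclusion). Single empty bins in a small-number gas make
# the raw max/min ratio trip spuriously; plateau means carry the same
# 3-fold discrimination with far less counting noise.
plateau_ratio <- function(profile) {
  cx <- tryCatch(coexistence_densities(profile), error = function(e) NULL)
  if (is.null(cx)) return(1)
  if (cx$dilute <= 0) return(Inf)
  cx$dense / cx$dilute
}

# Phase-separation verdict for one replica: 3-fold criterion on plateau
# means of the time-averaged profile over the final `window` of the run
# (Corelet profile, or either profile when chromatin is present).
slab_phase_separated <- function(trajectory, topology, with_chromatin,
                                 n_bins = 16, window = 1 / 3) {
  eq <- 1 - window
  ratios <- plateau_ratio(density_profile(trajectory, topology, "CORELET",
                                          n_bins, eq))
  if (with_chromatin)
    ratios <- c(ratios, plateau_ratio(
      density_profile(trajectory, topology, "NUCLEOSOME", n_bins, eq)))
  any(ratios >= 3)
}

#' Desk-scale coexistence/condensation protocol
#'
#' Bundles the system size, box, starting state, run length and replica
#' count used for critical-valence scans and for the self-interaction
#' calibration. The defaults are the package's desk-scale study
#' conditions (see the methods vignette): a dispersed start at a fixed
#' reference concentration, scored for condensation by the 3-fold density
#' criterion (on plateau means) over the final third of the run.
#'
#' A `"slab"` start (the classic direct-coexistence geometry) is also
#' available and is used for coexistence-density measurement; at desk
#' scale it is not used for the scans because a pre-built slab stays
#' kinetically frozen over any affordable run length, regardless of
#' whether it is thermodynamically stable.
#'
#' @param n_corelets Corelets in the box.
#' @param box A `box_spec`; the default holds 48 Corelets at the
#'   reference concentration 3e-5 molecules/nm^3.
#' @param with_chromatin Thread a periodic chromatin chain through the box.
#' @param acetyl_fraction Acetylated tail fraction (chromatin runs).
#' @param start `"dispersed"` or `"slab"`.
#' @param n_steps,dt,output_every Integration settings.
#' @param replicas Independent replicas per scan point.
#' @param n_bins Profile bins for the 3-fold criterion.
#' @export
coexistence_protocol <- function(n_corelets = 48,
                                 box = box_spec(58, 58, 476),
                                 with_chromatin = FALSE,
                                 acetyl_fraction = 0,
                                 start = c("dispersed", "slab"),
                                 n_steps = 200000L, dt = 2e-4,
                                 output_every = 2500L,
                                 replicas = 3L, n_bins = 14) {
  start <- match.arg(start)
  list(n_corelets = n_corelets, box = box, with_chromatin = with_chromatin,
       acetyl_fraction = acetyl_fraction, start = start, n_steps = n_steps,
       dt = dt, output_every = output_every, replicas = replicas,
       n_bins = n_bins)
}

run_slab_replica <- function(valence, params, protocol, seed) {
  topo <- if (identical(protocol$start, "slab"))
    build_slab_system(protocol$n_corelets, valence, protocol$with_chromatin,
                      protocol$acetyl_fraction, protocol$box, seed = seed,
                      params = params)
  else
    build_dispersed_system(protocol$n_corelets, valence,
                           protocol$with_chromatin,
                           protocol$acetyl_fraction, protocol$box,
                           seed = seed, params = params)
  # full-length runs: near-percolation cluster fluctuations in the gas
  # make size-based early stopping unreliable for scan verdicts
  cfg <- run_config(
    n_steps = protocol$n_steps, dt = protocol$dt,
    output_every = protocol$output_every, seed = seed)
  traj <- run(initial_state(topo), topo, params, cfg)
  list(topology = topo, trajectory = traj,
       phase_separated = slab_phase_separated(traj, topo,
                                              protocol$with_chromatin,
                                              protocol$n_bins))
}

slab_majority <- function(valence, params, protocol, seed) {
  ps <- vapply(seq_len(protocol$replicas), function(r) {
    run_slab_replica(valence, params, protocol,
                     split_seed(seed, r))$phase_separated
  }, logical(1))
  list(majority = sum(ps) > protocol$replicas / 2, n_ps = sum(ps),
       n = protocol$replicas)
}

#' Scan valences for the critical valence
#'
#' Runs direct-coexistence slab replicas per valence and returns the
#' smallest valence at which the majority of replicas phase separate
#' (3-fold density criterion sustained over the final third of the run).
#' A non-monotone majority pattern raises an "ambiguous scan" error with
#' the full table attached.
#'
#' @param valences Ascending integer valences.
#' @param protocol A [coexistence_protocol()].
#' @param params Model parameters.
#' @param seed Base seed; replicas use deterministically derived seeds.
#' @return list with `critical_valence` (NA if no valence separates) and
#'   the per-valence `table`.
#' @export
scan_critical_valence <- function(valences, protocol = coexistence_protocol(),
                                  params = default_parameters(), seed = 1L) {
  stopifnot(!is.unsorted(valences, strictly = TRUE), protocol$replicas >= 2)
  rows <- lapply(seq_along(valences), function(k) {
    v <- valences[k]
    res <- slab_majority(v, params, protocol, split_seed(seed, 1000L + k))
    data.frame(valence = v, n_ps = res$n_ps, replicas = res$n,
               phase_separated = res$majority)
  })
  tab <- do.call(rbind, rows)
  flags <- tab$phase_separated
  if (any(flags) && any(diff(flags) < 0)) {
    cond <- structure(
      class = c("condensim_ambiguous_scan", "error", "condition"),
      list(message = "ambiguous scan: phase separation not monotone in valence; raise replicas",
           call = sys.call(), table = tab))
    stop(cond)
  }
  crit <- if (any(flags)) min(tab$valence[flags]) else NA_integer_
  list(critical_valence = crit, table = tab)
}

#' Assemble a tidy phase diagram
#'
#' @param points data.frame with columns `core_concentration`,
#'   `inverse_valence`, `acetyl_fraction`, `phase_separated` and optionally
#'   `dilute_density`, `dense_density`. Duplicate keys with conflicting
#'   phase flags are flagged in a `conflict` column (never silently
#'   overwritten).
#' @return data.frame of class `phase_diagram`.
#' @export
assemble_phase_diagram <- function(points) {
  cols <- c("core_concentration", "inverse_valence", "acetyl_fraction",
            "phase_separated")
  if (!nrow(points)) {
    out <- points
    out$conflict <- logical(0)
    class(out) <- c("phase_diagram", class(out))
    return(out)
  }
  stopifnot(all(cols %in% names(points)))
  key <- do.call(paste, c(points[, cols[1:3]], sep = "|"))
  conflict <- vapply(key, function(k) {
    length(unique(points$phase_separated[key == k])) > 1
  }, logical(1))
  if (any(conflict))
    warning("conflicting phase flags at duplicate phase points; flagged in `conflict`")
  out <- points
  out$conflict <- unname(conflict)
  class(out) <- c("phase_diagram", class(out))
  out
}

#' Saturation density from the stored coexistence reference
#'
#' Returns the dilute-phase (saturation) number density measured by the
#' package's desk-scale direct-coexistence runs at the shipped calibrated
#' parameters (regenerate with `scripts/calibrate.R`).
#'
#' @param kind `"CORELET"` or `"ENDOGENOUS"`.
#' @param valence Corelet valence (ignored for endogenous BRD4).
#' @return Number density in molecules/nm^3.
#' @export
saturation_density <- function(kind = "CORELET", valence = 6) {
  path <- system.file("extdata", "coexistence_reference.csv",
                      package = "condensim")
  if (path == "") stop("coexistence reference table not installed")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  row <- tab[tab$kind == kind &
               (tab$kind != "CORELET" | tab$valence == valence), , drop = FALSE]
  if (!nrow(row))
    stop(sprintf("unknown saturation concentration for kind=%s valence=%s",
                 kind, valence))
  row$dilute_density[1]
}
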