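# Cluster detection, largest-cluster tracking, nucleation first-passage
# statistics, delay-time extrapolation and on-/off-chromatin pathway
# classification.

#' Clustering configuration for nucleation analysis
#'
#' Molecules are clustered by single linkage on one reference point each
#' (the CORE particle of a Corelet, the C-blob of a free BRD4 molecule)
#' with cutoff `r_clust`: 25 nm for Corelets, 12.5 nm for endogenous BRD4,
#' the distances at which nonbonded intermolecular interactions become
#' negligible for any orientation. Chromatin coverage uses the same cutoff
#' between member reference points and nucleosomes.
#'
#' The stable-nucleus threshold defaults to the full-scale proportions
#' (200 of 512 Corelets, 600 of 5832 BRD4), rescaled to the simulated
#' molecule count with a floor of 10.
#'
#' @param kind `"CORELET"` or `"ENDOGENOUS"`.
#' @param n_molecules Number of condensing molecules in the system.
#' @param r_clust Clustering cutoff (nm); defaults by kind.
#' @param stable_size Stable-nucleus size (molecules); defaults by scaling.
#' @param observable_multiplier Ratio of the experimentally observable
#'   droplet size to the stable nucleus size (default 15).
#' @param coverage_threshold Mean nucleosome coverage (count), in excess
#'   of the translation-null, at or above which a transition path counts
#'   as on-chromatin.
#' @param contact_threshold Mean number of acetylated-tail contacts (tails
#'   within 5 nm of a member N-blob) required for an on-chromatin call:
#'   in a desk-sized box a bulk cluster can be born next to the chain and,
#'   being nearly immobile on the run timescale, stay there; requiring
#'   molecular contact separates chance proximity from actual
#'   chromatin-bound assembly.
#' @export
clustering_config <- function(kind = c("CORELET", "ENDOGENOUS"),
                              n_molecules,
                              r_clust = NULL, stable_size = NULL,
                              observable_multiplier = 15,
                              coverage_threshold = 1,
                              contact_threshold = 1) {
  kind <- match.arg(kind)
  if (is.null(r_clust)) r_clust <- if (kind == "CORELET") 25 else 12.5
  if (is.null(stable_size))
    stable_size <- default_stable_size(kind, n_molecules)
  stopifnot(r_clust > 0, stable_size >= 2)
  structure(list(kind = kind, n_molecules = as.integer(n_molecules),
                 r_clust = r_clust, r_cut = r_clust,
                 stable_size = as.integer(stable_size),
                 observable_multiplier = observable_multiplier,
                 coverage_threshold = coverage_threshold,
                 contact_threshold = contact_threshold),
            class = "clustering_config")
}

default_stable_size <- function(kind, n_molecules) {
  ref <- if (kind == "CORELET") c(200, 512) else c(600, 5832)
  max(10L, round(ref[1] * n_molecules / ref[2]))
}

#' Cluster molecules at a single frame
#'
#' Single-linkage components of the graph connecting molecule reference
#' points within `r_clust` under the minimum image; component labels are
#' the smallest member molecule index (deterministic).
#'
#' @param state A `sim_state`.
#' @param topology A `topology`.
#' @param config A `clustering_config`.
#' @return Integer labels, one per condensing molecule.
#' @export
find_clusters <- function(state, topology, config) {
  ref <- reference_particles(topology)
  cpp_cluster(state$positions[ref, , drop = FALSE],
              box_lengths(state$box), config$r_clust)
}

#' Largest-cluster time series with chromatin coverage
#'
#' Tracks per frame the number of molecules in the biggest cluster (N_CS)
#' and the number of nucleosomes within `r_cut` of any member molecule's
#' reference point (`coverage`). A third column, `coverage_null`, holds the
#' coverage the same cluster would have at a random lateral position: the
#' member positions are rigidly translated in x-y by `n_null` deterministic
#' uniform offsets and the coverage is averaged. In small boxes a bulk
#' cluster can graze the chromatin chain by geometry alone; the null column
#' quantifies that incidental contact so that pathway classification can
#' use coverage in excess of chance (see [classify_pathway()]).
#'
#' @param trajectory A `trajectory`.
#' @param topology A `topology`.
#' @param config A `clustering_config`.
#' @param n_null Random lateral translations per frame for the null
#'   coverage (0 disables).
#' @return A `cluster_trace` data.frame with `time`, `n_cs`, `coverage`,
#'   `coverage_null` and `contacts` (acetylated tails within 5 nm of a
#'   member N-blob).
#' @export
largest_cluster_trace <- function(trajectory, topology, config,
                                  n_null = 12L) {
  ref <- reference_particles(topology)
  nuc <- which(species_names(topology) == "NUCLEOSOME")
  actail <- which(species_names(topology) == "TAIL_ACETYL")
  nblob <- which(species_names(topology) == "BRD4_N")
  molid <- topology$molecule_id
  nfr <- length(trajectory$frames)
  n_cs <- integer(nfr)
  cov <- numeric(nfr)
  cov0 <- numeric(nfr)
  contacts <- numeric(nfr)
  offsets <- if (n_null > 0)
    with_seed(20231L, matrix(runif(2L * n_null), n_null, 2L)) else NULL
  for (f in seq_len(nfr)) {
    pos <- trajectory$frames[[f]]
    L <- c(trajectory$box$Lx[f], trajectory$box$Ly[f], trajectory$box$Lz[f])
    lab <- cpp_cluster(pos[ref, , drop = FALSE], L, config$r_clust)
    tab <- tabulate(lab)
    big <- which.max(tab)
    n_cs[f] <- tab[big]
    if (length(nuc)) {
      mem_ref <- ref[lab == big]
      members <- pos[mem_ref, , drop = FALSE]
      nucpos <- pos[nuc, , drop = FALSE]
      cov[f] <- cpp_count_within(members, nucpos, L, config$r_cut)
      if (length(actail)) {
        mem_n <- nblob[molid[nblob] %in% molid[mem_ref]]
        contacts[f] <- cpp_count_within(pos[actail, , drop = FALSE],
                                        pos[mem_n, , drop = FALSE], L, 5)
      }
      if (n_null > 0) {
        cov0[f] <- mean(vapply(seq_len(n_null), function(k) {
          shifted <- members
          shifted[, 1] <- shifted[, 1] + offsets[k, 1] * L[1]
          shifted[, 2] <- shifted[, 2] + offsets[k, 2] * L[2]
          cpp_count_within(shifted, nucpos, L, config$r_cut)
        }, numeric(1)))
      }
    }
  }
  structure(data.frame(time = trajectory$times, n_cs = n_cs, coverage = cov,
                       coverage_null = cov0, contacts = contacts),
            class = c("cluster_trace", "data.frame"))
}

#' Detect the nucleation transition path in a largest-cluster trace
#'
#' The metastable baseline band is the mean +/- 3 SD of N_CS over the
#' initial window. The transition path starts at the last departure from
#' the band before N_CS first reaches the stable size without re-entering
#' the band; `tau_nucl` is the first time N_CS >= stable size.
#'
#' @param trace A `cluster_trace`.
#' @param config A `clustering_config`.
#' @param baseline_fraction Initial fraction of frames defining the band
#'   (at least 5 frames are used).
#' @return list with `t_start`, `tau_nucl`, `reached_stable`, `band`,
#'   `idx_start`, `idx_nucl`.
#' @export
detect_transition_path <- function(trace, config, baseline_fraction = 0.05) {
  n <- nrow(trace)
  if (trace$n_cs[1] >= config$stable_size)
    stop("not metastable at start: initial largest cluster exceeds the stable size")
  nb <- min(n, max(5L, ceiling(baseline_fraction * n)))
  base <- trace$n_cs[seq_len(nb)]
  band <- c(mean(base) - 3 * stats::sd(base), mean(base) + 3 * stats::sd(base))
  if (anyNA(band)) band <- c(base[1], base[1])
  idx_nucl <- match(TRUE, trace$n_cs >= config$stable_size)
  if (is.na(idx_nucl))
    return(list(t_start = NA_real_, tau_nucl = NA_real_,
                reached_stable = FALSE, band = band,
                idx_start = NA_integer_, idx_nucl = NA_integer_))
  inside <- which(trace$n_cs[seq_len(idx_nucl - 1L)] <= band[2])
  idx_start <- if (length(inside)) max(inside) + 1L else 1L
  list(t_start = trace$time[idx_start], tau_nucl = trace$time[idx_nucl],
       reached_stable = TRUE, band = band,
       idx_start = idx_start, idx_nucl = idx_nucl)
}

#' Nucleation rate from an ensemble of first-passage times
#'
#' `J = 1 / mean(tau_nucl)` over the replicas that reached the stable
#' size, with a jackknife standard error; censored (non-nucleating)
#' replicas are counted separately, never imputed.
#'
#' @param results data.frame with columns `tau_nucl` and `reached_stable`
#'   (one row per replica), as produced by [run_nucleation_ensemble()].
#' @return list with `J`, `se`, `n`, `censored`.
#' @export
nucleation_rate <- function(results) {
  taus <- results$tau_nucl[results$reached_stable]
  censored <- sum(!results$reached_stable)
  if (!length(taus)) stop("no nucleation observed")
  J <- 1 / mean(taus)
  se <- NA_real_
  n <- length(taus)
  if (n >= 2) {
    jk <- vapply(seq_len(n), function(i) 1 / mean(taus[-i]), numeric(1))
    se <- sqrt((n - 1) / n * sum((jk - mean(jk))^2))
  }
  list(J = J, se = se, n = n, censored = censored)
}

#' Delay time until the cluster reaches observable size
#'
#' Extrapolates the post-nucleation growth segment under diffusion-limited
#' growth (cluster radius ~ t^(1/2), so N ~ t^(3/2)): N_CS^(2/3) is fitted
#' linearly in time, anchored at (tau_nucl, stable_size^(2/3)), and the
#' delay time is the extrapolated crossing of
#' `observable_multiplier * stable_size`.
#'
#' @param trace A `cluster_trace` that reached the stable size.
#' @param config A `clustering_config`.
#' @param path Optional precomputed [detect_transition_path()] result.
#' @return Delay time (tau_d).
#' @export
delay_time <- function(trace, config, path = NULL) {
  if (is.null(path)) path <- detect_transition_path(trace, config)
  if (!path$reached_stable) stop("trace never reached the stable size")
  seg <- seq.int(path$idx_nucl, nrow(trace))
  if (length(seg) < 5) stop("insufficient growth data: fewer than 5 post-nucleation frames")
  s23 <- config$stable_size^(2 / 3)
  tt <- trace$time[seg] - path$tau_nucl
  yy <- trace$n_cs[seg]^(2 / 3) - s23
  b <- sum(tt * yy) / sum(tt * tt)
  if (!is.finite(b) || b <= 0)
    stop("insufficient growth data: no positive growth trend after nucleation")
  target <- (config$observable_multiplier * config$stable_size)^(2 / 3)
  path$tau_nucl + (target - s23) / b
}

#' Classify a nucleation pathway as on- or off-chromatin
#'
#' On-chromatin iff the mean chromatin coverage of the largest cluster over
#' the transition path `[t_start, tau_nucl]`, in excess of the incidental
#' coverage a randomly placed cluster of the same shape would collect
#' (`coverage_null`, zero when absent), reaches the configured coverage
#' threshold. In large boxes the null is essentially zero and the rule
#' reduces to a plain time-averaged coverage threshold.
#'
#' @param trace A `cluster_trace`.
#' @param t_start,tau_nucl Transition-path bounds (tau_d).
#' @param config A `clustering_config`.
#' @param t_end Optional end of the averaging window. The default is
#'   `tau_nucl`; ensemble analyses pass the end of the recorded growth
#'   segment, since nucleation and growth regimes are distinguished by
#'   the cluster's average coverage and the transition path alone spans
#'   too few frames for a stable average.
#' @return `"ON_CHROMATIN"` or `"OFF_CHROMATIN"`.
#' @export
classify_pathway <- function(trace, t_start, tau_nucl, config,
                             t_end = NULL) {
  if (is.null(t_end)) t_end <- tau_nucl
  sel <- trace$time >= t_start & trace$time <= t_end
  null_cov <- if (!is.null(trace$coverage_null))
    mean(trace$coverage_null[sel]) else 0
  excess <- mean(trace$coverage[sel]) - null_cov
  bound <- if (!is.null(trace$contacts))
    mean(trace$contacts[sel]) >= config$contact_threshold else TRUE
  if (bound && excess >= config$coverage_threshold)
    "ON_CHROMATIN" else "OFF_CHROMATIN"
}

#' Run an ensemble of nucleation simulations
#'
#' Builds and runs `n_replicas` independent supersaturated systems
#' (deterministically seeded), tracks the largest cluster in each, detects
#' the transition path and aggregates pathway probabilities, the
#' nucleation rate and the mean delay time. Individual replica failures
#' are recorded and skipped.
#'
#' @param system list with `kind`, `n_molecules`, `valence`,
#'   `n_nucleosomes`, `acetyl_fraction`, `supersaturation` and optionally
#'   `c_sat` (see [build_nucleation_system()]).
#' @param params Model parameters.
#' @param n_replicas Number of replicas (>= 2).
#' @param seed Base seed.
#' @param n_steps,dt,output_every Integration settings per replica.
#' @param post_frames Frames recorded beyond the stable-size crossing (the
#'   growth segment used for the delay-time fit).
#' @param config Optional `clustering_config` (defaults by system).
#' @return list with `P_on`, `J` (list from [nucleation_rate()]),
#'   `mean_tau_delay`, and the per-replica `table`.
#' @export
run_nucleation_ensemble <- function(system, params, n_replicas, seed = 1L,
                                    n_steps = 200000L, dt = 4e-5,
                                    output_every = 1000L, post_frames = 12L,
                                    config = NULL) {
  stopifnot(n_replicas >= 2)
  if (is.null(config))
    config <- clustering_config(system$kind, system$n_molecules)
  rows <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    sr <- split_seed(seed, r)
    rows[[r]] <- tryCatch({
      topo <- build_nucleation_system(
        kind = system$kind, n_molecules = system$n_molecules,
        valence = system$valence, n_nucleosomes = system$n_nucleosomes,
        acetyl_fraction = system$acetyl_fraction,
        supersaturation = system$supersaturation, seed = sr,
        params = params, c_sat = system$c_sat)
      ref <- reference_particles(topo)
      cfg <- run_config(
        n_steps = n_steps, dt = dt, output_every = output_every, seed = sr,
        stop = list(ref_idx = ref, r_clust = config$r_clust,
                    size = config$stable_size,
                    check_every = output_every,
                    post_steps = post_frames * output_every))
      traj <- run(initial_state(topo), topo, params, cfg)
      trace <- largest_cluster_trace(traj, topo, config)
      path <- detect_transition_path(trace, config)
      pathway <- NA_character_
      tau_delay <- NA_real_
      if (path$reached_stable) {
        pathway <- classify_pathway(trace, path$t_start, path$tau_nucl,
                                    config, t_end = max(trace$time))
        tau_delay <- tryCatch(delay_time(trace, config, path),
                              error = function(e) NA_real_)
      }
      data.frame(replica = r, seed = sr, tau_nucl = path$tau_nucl,
                 tau_delay = tau_delay, pathway = pathway,
                 reached_stable = path$reached_stable, error = NA_character_)
    }, error = function(e) {
      data.frame(replica = r, seed = sr, tau_nucl = NA_real_,
                 tau_delay = NA_real_, pathway = NA_character_,
                 reached_stable = FALSE, error = conditionMessage(e))
    })
  }
  tab <- do.call(rbind, rows)
  ok <- tab$reached_stable
  P_on <- if (any(ok)) mean(tab$pathway[ok] == "ON_CHROMATIN") else NA_real_
  J <- tryCatch(nucleation_rate(tab), error = function(e) NULL)
  list(P_on = P_on, J = J,
       mean_tau_delay = if (any(ok)) mean(tab$tau_delay[ok], na.rm = TRUE)
                        else NA_real_,
       table = tab, config = config)
}
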