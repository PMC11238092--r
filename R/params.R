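# Model constants and reduced-unit conventions.
#
# Reduced units: kT = 1, lengths in nm, time in tau_d (Corelet core
# self-diffusion time). Species sizes follow structural data (nucleosome
# core ~10 nm, ferritin core ~12 nm) and ideal-chain radii of gyration
# (Rg ~ 0.38*sqrt(N_aa) nm) for the polymer blobs.

# Self-interaction strength (kT) between BRD4 C-terminal blobs obtained by
# calibrating the chromatin-free critical valence to 6 with
# calibrate_self_interaction(); see scripts/calibrate.R.
CALIBRATED_EPS_CC <- 3.5

# Presets for the BRD4 N-blob / acetylated-tail attraction (kT, the
# Flory-Krigbaum prefactor): "strong" represents bromodomain engagement of
# acetylated tails, "weak" the JQ1-inhibited (bromodomain-blocked) state.
# Because steric repulsion keeps the blobs near WCA contact, the pair well
# depth actually sampled is ~0.41x the prefactor; the strong preset is
# chosen so the contact well is ~4 kT, i.e. strongly bound on the thermal
# scale while remaining integrable at the production time step (see the
# methods vignette).
EPS_NT_PRESETS <- c(strong = 10, weak = 0)

#' Default coarse-grained model parameters
#'
#' Returns the complete parameter set of the model in reduced units
#' (kT = 1, nm, tau_d): per-species WCA diameters, radii of gyration and
#' friction coefficients; FENE bond constants per bond class
#' (Kremer-Grest convention, K = 30 kT/sigma_b^2, R0 = 1.5 sigma_b); and
#' the pairwise Flory-Krigbaum attraction table. Only two attractive
#' entries exist: the BRD4 C-blob self-attraction `eps_cc` and the
#' BRD4 N-blob / acetylated-tail attraction selected by `nt_preset`.
#' Non-acetylated tails never attract anything.
#'
#' Friction is uniform per particle and fixed so that the bare-core
#' diffusion time over its own diameter defines the time unit (tau_d = 1);
#' see the methods vignette for why a uniform friction is used.
#'
#' @param nt_preset `"strong"` (default) or `"weak"` (0 kT; the JQ1
#'   mimic). Switching presets changes no other entry.
#' @param eps_cc C-blob self-attraction in kT; defaults to the calibrated
#'   value shipped with the package.
#' @return An object of class `model_params`.
#' @export
default_parameters <- function(nt_preset = c("strong", "weak"), eps_cc = NULL) {
  nt_preset <- match.arg(nt_preset)
  if (is.null(eps_cc)) eps_cc <- CALIBRATED_EPS_CC
  stopifnot(is.numeric(eps_cc), length(eps_cc) == 1L, eps_cc >= 0)

  sigma <- c(NUCLEOSOME = 10, TAIL_PLAIN = 2, TAIL_ACETYL = 2,
             BRD4_N = 4.5, BRD4_C = 6.5, CORE = 12)
  rg <- c(NUCLEOSOME = NA, TAIL_PLAIN = 1.5, TAIL_ACETYL = 1.5,
          BRD4_N = 3, BRD4_C = 5, CORE = NA)
  # Uniform per-particle friction, normalized so the bare-core diffusion
  # time over its own diameter defines the time unit (tau_d = 1). Friction
  # is a free transport parameter in overdamped dynamics (it cannot change
  # equilibrium averages); a uniform value maximizes molecule mobility per
  # stable time step, which sets how much simulated time a CPU hour buys.
  gamma_core <- 1 / 24
  species <- data.frame(
    species = SPECIES,
    sigma = unname(sigma[SPECIES]),
    rg = unname(rg[SPECIES]),
    gamma = gamma_core,
    stringsAsFactors = FALSE
  )

  bond_pairs <- list(
    NUC_NUC    = c("NUCLEOSOME", "NUCLEOSOME"),
    NUC_TAIL   = c("NUCLEOSOME", "TAIL_PLAIN"),
    BRD4_NC    = c("BRD4_N", "BRD4_C"),
    CORE_BRD4C = c("CORE", "BRD4_C")
  )
  sigma_b <- vapply(bond_pairs, function(p) mean(sigma[p]), numeric(1))
  bonds <- data.frame(
    class = names(bond_pairs),
    sigma_bond = unname(sigma_b),
    K = unname(30 / sigma_b^2),
    R0 = unname(1.5 * sigma_b),
    stringsAsFactors = FALSE
  )

  eps <- matrix(0, 6, 6, dimnames = list(SPECIES, SPECIES))
  eps["BRD4_C", "BRD4_C"] <- eps_cc
  eps_nt <- unname(EPS_NT_PRESETS[nt_preset])
  eps["BRD4_N", "TAIL_ACETYL"] <- eps_nt
  eps["TAIL_ACETYL", "BRD4_N"] <- eps_nt

  p <- structure(list(
    kT = 1,
    wca_epsilon = 1,
    species = species,
    bonds = bonds,
    eps = eps,
    nt_preset = nt_preset,
    eps_cc = eps_cc,
    eps_nt = eps_nt,
    fk_cut_tol = 1e-4
  ), class = "model_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (!isTRUE(all.equal(p$eps, t(p$eps))))
    stop("interaction table must be symmetric")
  if (any(p$eps < 0)) stop("interaction strengths must be non-negative")
  if (p$eps["TAIL_PLAIN", "BRD4_N"] != 0)
    stop("non-acetylated tails must not attract BRD4_N")
  if (any(p$species$sigma <= 0)) stop("WCA diameters must be positive")
  polymer <- c("TAIL_PLAIN", "TAIL_ACETYL", "BRD4_N", "BRD4_C")
  if (any(is.na(p$species$rg[p$species$species %in% polymer])))
    stop("polymer blob species need a radius of gyration")
  if (any(p$bonds$K <= 0) || any(p$bonds$R0 <= 0))
    stop("bond constants must be positive")
  invisible(p)
}

#' Look up a pair attraction strength
#'
#' @param params A `model_params` object.
#' @param a,b Species names (e.g. `"BRD4_C"`).
#' @return Attraction magnitude in kT (0 for purely repulsive pairs).
#' @export
epsilon <- function(params, a, b) {
  stopifnot(a %in% SPECIES, b %in% SPECIES)
  params$eps[a, b]
}

species_row <- function(params, sp) {
  params$species[match(sp, params$species$species), , drop = FALSE]
}

# Precompute the 6x6 pair tables consumed by the C++ engine:
# Lorentz-mixed WCA diameters, WCA cutoffs, and truncated-shifted
# Flory-Krigbaum parameters (cut where |U| < fk_cut_tol).
pair_tables <- function(params) {
  sig <- params$species$sigma
  rg <- params$species$rg
  n <- length(sig)
  sig_ij <- outer(sig, sig, function(a, b) (a + b) / 2)
  sig2 <- sig_ij^2
  wca_cut2 <- 2^(1 / 3) * sig2
  fk_eps <- params$eps
  rg2sum <- outer(rg^2, rg^2, `+`)
  fk_alpha <- matrix(0, n, n)
  fk_cut2 <- matrix(0, n, n)
  fk_shift <- matrix(0, n, n)
  active <- fk_eps > params$fk_cut_tol & !is.na(rg2sum)
  fk_alpha[active] <- 3 / (4 * rg2sum[active])
  fk_cut2[active] <- log(fk_eps[active] / params$fk_cut_tol) / fk_alpha[active]
  fk_shift[active] <- params$fk_cut_tol
  fk_eps[!active] <- 0
  list(sig2 = sig2, wca_cut2 = wca_cut2, fk_eps = unname(fk_eps),
       fk_alpha = fk_alpha, fk_cut2 = fk_cut2, fk_shift = fk_shift,
       eps_rep = params$wca_epsilon)
}

# Per-particle friction. Baseline is the uniform species table; particles
# belonging to Corelet molecules are renormalized so that every Corelet
# carries the same total friction as the valence-6 reference (core keeps
# gamma_core, each of the 2v arm blobs gets (12 gamma_core)/(2v) =
# 1/(4v) in reduced units). Whole-molecule diffusivity is then
# valence-independent, which removes a kinetic artifact in which smaller
# (low-valence) Corelets aggregate faster simply because they carry fewer
# friction-bearing beads; valence-6 systems are unchanged.
particle_frictions <- function(topology, params) {
  gam <- params$species$gamma[topology$species]
  gamma_core <- params$species$gamma[match("CORE", params$species$species)]
  kind <- topology$molecule_kind[topology$molecule_id]
  in_corelet <- kind == "CORELET"
  sp <- SPECIES[topology$species]
  arm <- in_corelet & sp %in% c("BRD4_N", "BRD4_C")
  if (any(arm)) {
    msize <- table(factor(topology$molecule_id,
                          levels = seq_along(topology$molecule_kind)))
    v <- (as.integer(msize[topology$molecule_id]) - 1L) / 2
    gam[arm] <- 12 * gamma_core / (2 * v[arm])
  }
  gam
}

bond_constants <- function(params, classes) {
  idx <- match(classes, params$bonds$class)
  if (anyNA(idx)) stop("unknown bond class: ", paste(classes[is.na(idx)], collapse = ", "))
  list(K = params$bonds$K[idx], R0 = params$bonds$R0[idx])
}

#' Serialize model parameters to a YAML config
#'
#' @param params A `model_params` object.
#' @param path Output file.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  out <- list(
    kT = params$kT,
    wca_epsilon = params$wca_epsilon,
    nt_preset = params$nt_preset,
    eps_cc = params$eps_cc,
    fk_cut_tol = params$fk_cut_tol,
    species = lapply(seq_len(nrow(params$species)), function(i)
      as.list(params$species[i, ])),
    bonds = lapply(seq_len(nrow(params$bonds)), function(i)
      as.list(params$bonds[i, ]))
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read model parameters from a YAML config written by [write_params()]
#'
#' @param path Input file.
#' @return A `model_params` object.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  p <- default_parameters(nt_preset = raw$nt_preset, eps_cc = raw$eps_cc)
  p$kT <- raw$kT
  p$wca_epsilon <- raw$wca_epsilon
  p$fk_cut_tol <- raw$fk_cut_tol
  p$species <- do.call(rbind, lapply(raw$species, as.data.frame))
  p$bonds <- do.call(rbind, lapply(raw$bonds, as.data.frame))
  validate_params(p)
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Coarse-grained model parameters (kT = 1, nm, tau_d)\n")
  cat(sprintf("  eps_CC = %.3g kT; eps_NT = %.3g kT (preset '%s')\n",
              x$eps_cc, x$eps_nt, x$nt_preset))
  cat("  species:\n")
  print(x$species, row.names = FALSE)
  cat("  bonds:\n")
  print(x$bonds, row.names = FALSE)
  invisible(x)
}

#' Calibrate the BRD4 C-blob self-attraction against a target critical valence
#'
#' Scans an ascending list of candidate self-interaction strengths and
#' returns the smallest one for which chromatin-free direct-coexistence
#' slab simulations phase-separate at `target_critical_valence` but not at
#' `target_critical_valence - 1` (majority over replicas). The full scan
#' log is attached as attribute `"scan"`.
#'
#' @param target_critical_valence Integer >= 2.
#' @param candidate_epsilons Monotonically increasing candidate strengths (kT).
#' @param protocol Slab protocol from [coexistence_protocol()]; controls
#'   system size, run length and replica count of each scan point.
#' @param seed Base seed; replica seeds are derived deterministically.
#' @return The selected epsilon (kT), with the scan table attached.
#' @export
calibrate_self_interaction <- function(target_critical_valence,
                                       candidate_epsilons,
                                       protocol = coexistence_protocol(),
                                       seed = 1L) {
  stopifnot(target_critical_valence >= 2,
            length(candidate_epsilons) >= 1,
            !is.unsorted(candidate_epsilons, strictly = TRUE))
  rows <- list()
  chosen <- NA_real_
  for (k in seq_along(candidate_epsilons)) {
    eps <- candidate_epsilons[k]
    params <- default_parameters(eps_cc = eps)
    ps_at <- slab_majority(target_critical_valence, params, protocol,
                           seed = split_seed(seed, 2L * k))
    ps_below <- slab_majority(target_critical_valence - 1L, params, protocol,
                              seed = split_seed(seed, 2L * k + 1L))
    rows[[length(rows) + 1L]] <- data.frame(
      eps_cc = eps, valence = target_critical_valence,
      phase_separated = ps_at$majority, n_ps = ps_at$n_ps,
      replicas = ps_at$n)
    rows[[length(rows) + 1L]] <- data.frame(
      eps_cc = eps, valence = target_critical_valence - 1L,
      phase_separated = ps_below$majority, n_ps = ps_below$n_ps,
      replicas = ps_below$n)
    if (ps_at$majority && !ps_below$majority) {
      chosen <- eps
      break
    }
  }
  scan <- do.call(rbind, rows)
  if (is.na(chosen)) {
    message(paste(utils::capture.output(print(scan)), collapse = "\n"))
    stop("calibration failed: no candidate epsilon brackets the target critical valence")
  }
  structure(chosen, scan = scan)
}
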