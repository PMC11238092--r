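# Closed-form pair potentials (reference implementations, vectorized) and
# the neighbor-accelerated total force/energy evaluation.

#' WCA repulsive pair potential
#'
#' `U(r) = 4 eps [ (sigma/r)^12 - (sigma/r)^6 ] + eps` for
#' `r < 2^(1/6) sigma`, zero beyond; the force `-dU/dr` is continuous at
#' the cutoff.
#'
#' @param r Pair distance(s), > 0 (nm).
#' @param sigma_ij Lorentz-mixed WCA diameter (nm).
#' @param eps_rep Repulsion scale (kT).
#' @return list with `energy` and `force` (`-dU/dr`, positive = repulsive).
#' @export
wca <- function(r, sigma_ij, eps_rep = 1) {
  if (any(r <= 0)) stop("singular separation: r must be positive")
  rc <- 2^(1 / 6) * sigma_ij
  s6 <- (sigma_ij / r)^6
  inside <- r < rc
  u <- ifelse(inside, 4 * eps_rep * (s6^2 - s6) + eps_rep, 0)
  f <- ifelse(inside, 24 * eps_rep * (2 * s6^2 - s6) / r, 0)
  list(energy = u, force = f)
}

#' FENE bond potential
#'
#' `U(r) = -K R0^2 / 2 * ln(1 - (r/R0)^2)`; the restoring force diverges as
#' r approaches R0.
#'
#' @param r Bond length(s), `0 <= r < R0`.
#' @param K Spring constant (kT/nm^2).
#' @param R0 Maximum extension (nm).
#' @return list with `energy` and `force` (`-dU/dr`, negative = restoring).
#' @export
fene <- function(r, K, R0) {
  if (any(r < 0)) stop("bond length must be non-negative")
  if (any(r >= R0)) stop("overstretched bond: r >= R0")
  frac <- 1 - (r / R0)^2
  list(energy = -0.5 * K * R0^2 * log(frac), force = -K * r / frac)
}

#' Flory-Krigbaum blob attraction
#'
#' Gaussian-overlap attraction between polymer blobs,
#' `U(r) = -eps exp(-3 r^2 / (4 (Rg_i^2 + Rg_j^2)))`, parameterized by the
#' blob radii of gyration and a tunable depth.
#'
#' @param r Pair distance(s) (nm), >= 0.
#' @param eps_ij Attraction magnitude (kT), >= 0.
#' @param rg_i,rg_j Radii of gyration (nm).
#' @return list with `energy` and `force` (`-dU/dr`).
#' @export
flory_krigbaum <- function(r, eps_ij, rg_i, rg_j) {
  stopifnot(all(r >= 0), all(eps_ij >= 0))
  alpha <- 3 / (4 * (rg_i^2 + rg_j^2))
  e <- eps_ij * exp(-alpha * r^2)
  list(energy = -e, force = -2 * alpha * r * e)
}

#' Total forces and energy report
#'
#' Evaluates all pair terms (WCA + truncated-and-shifted Flory-Krigbaum)
#' under the minimum-image convention with a cell list, plus FENE bonds,
#' and returns exact negative gradients of the reported energy.
#'
#' @param state A `sim_state`.
#' @param topology A `topology`.
#' @param params A `model_params`.
#' @return list with `forces` (N x 3), `energy` (list: `total` and
#'   `by_class` over WCA/FENE/FK), `lateral_virial` and `min_sep_ratio`
#'   (smallest pair distance relative to sigma_ij).
#' @export
total_forces <- function(state, topology, params = default_parameters()) {
  tab <- pair_tables(params)
  bc <- bond_constants(params, topology$bonds$class)
  res <- cpp_total_forces(state$positions, topology$species - 1L, tab,
                          topology$bonds$i - 1L, topology$bonds$j - 1L,
                          bc$K, bc$R0^2, box_lengths(state$box))
  e <- res$energy
  list(forces = res$forces,
       energy = list(total = sum(e), by_class = as.list(e)),
       lateral_virial = res$lateral_virial,
       min_sep_ratio = res$min_sep_ratio)
}
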