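# Configuration parsing, deterministic seeding, trajectory/table I/O and
# preset scenario definitions.

#' Deterministic seed splitting
#'
#' Derives an independent 31-bit stream seed from a base seed and an index
#' via a counter-based (splitmix64) generator, so that a single scenario
#' seed fans out reproducibly to per-replica seeds.
#'
#' @param seed Base integer seed.
#' @param index Stream index.
#' @export
split_seed <- function(seed, index) {
  cpp_split_seed(as.integer(seed), as.integer(index))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Write a trajectory as XYZ plus a metadata sidecar
#'
#' Frames go to `<prefix>.xyz` (species label + coordinates per row, one
#' block per frame, the frame time in the comment line); per-frame box
#' dimensions and energies go to `<prefix>_meta.tsv`.
#'
#' @param trajectory A `trajectory`.
#' @param topology The matching `topology`.
#' @param prefix Output path prefix.
#' @export
write_trajectory <- function(trajectory, topology, prefix) {
  sp <- species_names(topology)
  n <- length(sp)
  con <- file(paste0(prefix, ".xyz"), "w")
  on.exit(close(con))
  for (f in seq_along(trajectory$frames)) {
    pos <- trajectory$frames[[f]]
    writeLines(c(as.character(n),
                 sprintf("t= %.8g tau_d", trajectory$times[f])), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", sp, pos[, 1], pos[, 2], pos[, 3]),
               con)
  }
  meta <- cbind(frame = seq_along(trajectory$frames),
                time = trajectory$times, trajectory$box, trajectory$energy,
                lateral_pressure = trajectory$lateral_pressure)
  utils::write.table(meta, paste0(prefix, "_meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read an XYZ trajectory written by [write_trajectory()]
#'
#' @param prefix Path prefix used at write time.
#' @return list with `frames` (list of N x 3 matrices), `species`,
#'   `times`, and the metadata table (`meta`).
#' @export
read_trajectory <- function(prefix) {
  lines <- readLines(paste0(prefix, ".xyz"))
  frames <- list()
  times <- numeric(0)
  species <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    times <- c(times, as.numeric(sub("t= ([-0-9.eE+]+).*", "\\1", lines[i + 1L])))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(block, " ", fixed = TRUE)
    if (is.null(species)) species <- vapply(parts, `[[`, character(1), 1L)
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), n, 3, byrow = TRUE)
    i <- i + 2L + n
  }
  meta_path <- paste0(prefix, "_meta.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.table(meta_path, header = TRUE, sep = "\t") else NULL
  list(frames = frames, species = species, times = times, meta = meta)
}

#' Serialize a topology to a plain-text table pair
#'
#' Particles (species, molecule id/kind, x/y/z) to `<prefix>_particles.tsv`,
#' bonds to `<prefix>_bonds.tsv`; box dimensions in the particle-table
#' header comment.
#'
#' @param topology A `topology`.
#' @param prefix Path prefix.
#' @export
write_topology <- function(topology, prefix) {
  pt <- data.frame(species = species_names(topology),
                   molecule_id = topology$molecule_id,
                   molecule_kind = topology$molecule_kind[topology$molecule_id],
                   x = topology$positions[, 1], y = topology$positions[, 2],
                   z = topology$positions[, 3])
  path <- paste0(prefix, "_particles.tsv")
  header <- if (!is.null(topology$box))
    sprintf("# box %.8g %.8g %.8g", topology$box$Lx, topology$box$Ly,
            topology$box$Lz) else "# box NA NA NA"
  writeLines(header, path)
  suppressWarnings(utils::write.table(pt, path, sep = "\t", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  utils::write.table(topology$bonds, paste0(prefix, "_bonds.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_topology
#' @export
read_topology <- function(prefix) {
  path <- paste0(prefix, "_particles.tsv")
  header <- readLines(path, n = 1L)
  box_vals <- suppressWarnings(as.numeric(strsplit(header, " ")[[1]][3:5]))
  pt <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  bonds <- utils::read.table(paste0(prefix, "_bonds.tsv"), header = TRUE,
                             sep = "\t")
  ids <- sort(unique(pt$molecule_id))
  kind <- vapply(ids, function(m) pt$molecule_kind[match(m, pt$molecule_id)],
                 character(1))
  new_topology(match(pt$species, SPECIES), pt$molecule_id, kind, bonds,
               as.matrix(pt[, c("x", "y", "z")]),
               if (!anyNA(box_vals)) box_spec(box_vals[1], box_vals[2],
                                              box_vals[3]) else NULL)
}

# ---------------------------------------------------------------------------
# Run configuration files
# ---------------------------------------------------------------------------

config_schema <- function() {
  list(
    scenario = list(preset = NA_character_, scale = "desk"),
    system = list(kind = "CORELET", n_molecules = 48L, valence = 6L,
                  n_nucleosomes = 32L, acetyl_fraction = 0.4,
                  supersaturation = NA_real_, with_chromatin = TRUE,
                  n_corelets = NA_integer_, Lx = NA_real_, Ly = NA_real_,
                  Lz = NA_real_),
    params = list(nt_preset = "strong", eps_cc = NA_real_),
    run = list(dt = 1e-5, n_steps = 100000L, ensemble = "NVT",
               lateral_pressure = NA_real_, output_every = 1000L, seed = 1L),
    analysis = list(r_clust = NA_real_, stable_size = NA_integer_,
                    observable_multiplier = 15, coverage_threshold = 1,
                    n_bins = 16L, equilibration_fraction = 0.5)
  )
}

#' Parse and validate a run-configuration file
#'
#' YAML with sections `scenario`, `system`, `params`, `run`, `analysis`.
#' Unknown keys are rejected by name; missing keys take the documented
#' defaults, which are materialized in the returned object so that
#' [emit_config()] followed by `parse_config()` is idempotent.
#'
#' @param path YAML file.
#' @return A validated, fully defaulted `condensim_config` list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  bad_sections <- setdiff(names(raw), names(schema))
  if (length(bad_sections))
    stop("unknown config section: ", paste(bad_sections, collapse = ", "))
  cfg <- schema
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(schema[[sec]]))
    if (length(bad))
      stop(sprintf("unknown config key: %s.%s", sec, bad[1]))
    cfg[[sec]] <- utils::modifyList(schema[[sec]], raw[[sec]])
  }
  structure(cfg, class = "condensim_config")
}

#' @rdname parse_config
#' @param config A `condensim_config`.
#' @export
emit_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), as.list), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Scenario presets
# ---------------------------------------------------------------------------

#' Preset scenario definitions
#'
#' Named, fully specified simulation experiments at two scales. `"desk"`
#' presets preserve the composition ratios of the `"paper"` scale (valence,
#' acetylation fraction, stable-size proportion) at reduced particle
#' counts, sized for a single workstation CPU.
#'
#' * `slab_valence_scan` — chromatin-free direct-coexistence slabs over a
#'   valence range (critical-valence determination).
#' * `chromatin_slab_scan` — slabs threaded by acetylated chromatin
#'   (apparent critical valence vs acetylation).
#' * `nucleation_acetyl_scan` — valence-6 Corelet nucleation ensembles over
#'   acetylation fractions 0.1-0.4 with strong BRD4-tail attraction.
#' * `nucleation_jq1` — the same ensembles with the weak (JQ1-mimic)
#'   attraction preset.
#' * `nucleation_rate_delay` — strong vs weak attraction at 40% acetylation
#'   (rate and delay-time comparison).
#'
#' @param name Preset name.
#' @param scale `"desk"` or `"paper"`.
#' @return A preset list consumed by [run_scenario()].
#' @export
scenario_preset <- function(name = c("slab_valence_scan",
                                     "chromatin_slab_scan",
                                     "nucleation_acetyl_scan",
                                     "nucleation_jq1",
                                     "nucleation_rate_delay"),
                            scale = c("desk", "paper")) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  desk <- scale == "desk"
  common <- list(name = name, scale = scale)
  if (name == "slab_valence_scan") {
    c(common, list(
      type = "slab",
      valences = 2:8,
      protocol = if (desk) coexistence_protocol() else
        coexistence_protocol(n_corelets = 343, box = box_spec(120, 120, 561),
                             n_steps = 5e6, replicas = 3)))
  } else if (name == "chromatin_slab_scan") {
    c(common, list(
      type = "slab",
      valences = 1:6,
      protocol = if (desk)
        coexistence_protocol(n_corelets = 12, with_chromatin = TRUE,
                             acetyl_fraction = 0.4,
                             box = box_spec(58, 58, 118),
                             n_steps = 500000L, n_bins = 8)
      else
        coexistence_protocol(n_corelets = 43, with_chromatin = TRUE,
                             acetyl_fraction = 0.4,
                             box = box_spec(120, 120, 400 * NUC_SPACING / CHAIN_SLACK),
                             n_steps = 5e6, replicas = 3)))
  } else {
    sys_desk <- list(kind = "CORELET", n_molecules = 32L, valence = 6L,
                     n_nucleosomes = 32L, supersaturation = NUCLEATION_S)
    sys_paper <- list(kind = "CORELET", n_molecules = 512L, valence = 6L,
                      n_nucleosomes = 345L, supersaturation = NUCLEATION_S)
    base <- c(common, list(type = "nucleation",
                           system = if (desk) sys_desk else sys_paper,
                           n_replicas = if (desk) 10L else 7L,
                           n_steps = if (desk) NUCLEATION_STEPS else 5e6,
                           dt = NUCLEATION_DT))
    if (name == "nucleation_acetyl_scan") {
      c(base, list(acetyl_fractions = c(0.1, 0.2, 0.3, 0.4),
                   nt_preset = "strong"))
    } else if (name == "nucleation_jq1") {
      c(base, list(acetyl_fractions = c(0.1, 0.2, 0.3, 0.4),
                   nt_preset = "weak"))
    } else {
      c(base, list(acetyl_fractions = 0.4,
                   nt_preset = c("strong", "weak"),
                   n_replicas = if (desk) 7L else 7L))
    }
  }
}

#' Run a preset scenario
#'
#' Executes a [scenario_preset()] (optionally with shallowly merged
#' overrides), writes the echoed configuration, analysis tables and a
#' machine-readable summary into `out_dir`, and returns the summary. Fully
#' reproducible from the echoed configuration and seed.
#'
#' @param preset A preset list or preset name.
#' @param overrides Named list merged shallowly over the preset.
#' @param seed Base seed.
#' @param out_dir Output directory (created if missing).
#' @export
run_scenario <- function(preset, overrides = list(), seed = 1L,
                         out_dir = tempfile("scenario_")) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  preset <- utils::modifyList(preset, overrides)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(c(preset[!vapply(preset, is.function, logical(1))],
                     list(seed = seed)),
                   file.path(out_dir, "config_echo.yaml"))
  if (preset$type == "slab") {
    scan <- scan_critical_valence(preset$valences, preset$protocol,
                                  default_parameters(), seed = seed)
    utils::write.table(scan$table, file.path(out_dir, "valence_scan.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary <- list(critical_valence = scan$critical_valence,
                    inverse_critical_valence =
                      if (is.na(scan$critical_valence)) NA else
                        1 / scan$critical_valence)
  } else {
    rows <- list()
    for (nt in preset$nt_preset) {
      params <- default_parameters(nt_preset = nt)
      for (f in preset$acetyl_fractions) {
        system <- utils::modifyList(preset$system, list(acetyl_fraction = f))
        ens <- run_nucleation_ensemble(
          system, params, n_replicas = preset$n_replicas,
          seed = split_seed(seed, round(1000 * f) + ifelse(nt == "weak", 1L, 0L)),
          n_steps = preset$n_steps, dt = preset$dt)
        tab <- ens$table
        tab$acetyl_fraction <- f
        tab$nt_preset <- nt
        rows[[length(rows) + 1L]] <- list(tab = tab, ens = ens, f = f, nt = nt)
      }
    }
    per_rep <- do.call(rbind, lapply(rows, `[[`, "tab"))
    utils::write.table(per_rep, file.path(out_dir, "replicas.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary <- list(conditions = lapply(rows, function(r)
      list(acetyl_fraction = r$f, nt_preset = r$nt, P_on = r$ens$P_on,
           J = if (is.null(r$ens$J)) NA else r$ens$J$J,
           mean_tau_delay = r$ens$mean_tau_delay)))
  }
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(summary)
}

# Desk-scale nucleation study conditions (see the methods vignette):
# supersaturation, step budget and time step shared by the nucleation
# presets and the acceptance analyses. S = 1.75 over the measured
# saturation density puts the initial gas at ~3e-5 molecules/nm^3, just
# below the R_clust percolation density, so runs start dispersed yet
# nucleate within a few tens of tau_d.
NUCLEATION_S <- 1.75
NUCLEATION_STEPS <- 140000L
NUCLEATION_DT <- 2e-4
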