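#' Default configuration
#'
#' The complete configuration bundle of the reference setup, as a plain
#' nested list mirroring the YAML configuration schema: `model`
#' ([chip_params()] fields), `clones` (list of [clone_spec()] fields),
#' `inflammation`, `pk`, `graft` (dose, composition, donor VAF) and
#' `trial` (cohort size, doses, seed, archetype).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    model = list(
      n_stages = 15L, p_hsc_hom = 2 / 365.25, p_last_hom = 1,
      prolif_fold_max = 4, prolif_floor = 0.25,
      a_hpc_max = 0.50, s_p_star = 0.002,
      d_mature = 2.3, M_star = 3.1e8, H_star = 1250,
      variant = "baseline"
    ),
    clones = list(),
    inflammation = list(mode = "off", host_baseline = 0, hill_theta = 1,
                        lambda_selfrenewal = 0, lambda_prolif = 0,
                        lambda_amplification = 0, mu_selfrenewal = 0,
                        mu_amplification = 0, mu_prolif = 0,
                        disadvantage_delta = 0),
    pk = list(ka = 0.6680, ke = 0.3629, gamma = 0.33,
              dose_times = list()),
    graft = list(dose_cd34_per_kg = 4.7e6, hsc_fraction = 2.66e-4,
                 n_cd34_stages = 15L, donor_vaf = 0),
    trial = list(n = 1000L, seed = 1L, archetype = "saturated",
                 doses = c(1e6, 5e6, 1e7, 1.5e7))
  )
}

config_schema <- function() {
  list(
    model = list(required = c("M_star", "H_star"),
                 allowed = names(default_config()$model)),
    clones = list(required = character(0),
                  allowed = c("clone_id", "mult_prolif_hsc",
                              "mult_prolif_hpc", "mult_selfrenewal_hsc",
                              "mult_selfrenewal_hpc", "mult_clearance",
                              "sens_hsc", "sens_hpc", "homing_hsc",
                              "homing_hpc", "zygosity", "infl_production",
                              "infl_responsive")),
    inflammation = list(required = character(0),
                        allowed = names(default_config()$inflammation)),
    pk = list(required = character(0),
              allowed = names(default_config()$pk)),
    graft = list(required = character(0),
                 allowed = c(names(default_config()$graft), "composition")),
    trial = list(required = character(0),
                 allowed = names(default_config()$trial))
  )
}

check_keys <- function(x, allowed, required, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("configuration error in '%s': unknown key(s) %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("configuration error in '%s': missing required key(s) %s",
                 where, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, validates it against the schema (unknown
#' keys are rejected, required keys and value constraints are checked by
#' the respective constructors) and assembles the model objects.
#'
#' @param path YAML file path, or a configuration list as produced by
#'   [default_config()].
#' @return list with the validated raw `config` plus assembled objects:
#'   `params` (calibrated), `clones`, `inflammation`, `pk`, `graft_spec`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path))
      stop("configuration file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else path
  base <- default_config()
  check_keys(cfg, names(base), character(0), "top level")
  schema <- config_schema()
  for (sec in names(schema)) {
    if (is.null(cfg[[sec]])) next
    if (sec == "clones") {
      for (k in seq_along(cfg$clones))
        check_keys(cfg$clones[[k]], schema$clones$allowed, character(0),
                   sprintf("clones[%d]", k))
    } else {
      check_keys(cfg[[sec]], schema[[sec]]$allowed, schema[[sec]]$required,
                 sec)
    }
  }
  merged <- base
  for (sec in setdiff(names(base), "clones"))
    merged[[sec]] <- utils::modifyList(base[[sec]],
                                       as.list(cfg[[sec]] %||% list()))
  merged$clones <- cfg$clones %||% list()

  params <- calibrate_homeostasis(do.call(chip_params, merged$model))$params
  clones <- lapply(merged$clones, function(cl) do.call(clone_spec, cl))
  inflammation <- do.call(inflammation_params, merged$inflammation)
  pk_cfg <- merged$pk
  pk_cfg$dose_times <- unlist(pk_cfg$dose_times)
  pk <- do.call(pk_params, pk_cfg)
  list(config = merged, params = params, clones = clones,
       inflammation = inflammation, pk = pk, graft_spec = merged$graft,
       trial = merged$trial)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration to YAML
#'
#' @param config a configuration list (see [default_config()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Trajectory as a long table
#'
#' @param traj a `chip_trajectory`.
#' @return data.frame with columns `time_days`, `clone_id`,
#'   `compartment_index` (0 = HSC, `n_stages + 1` = mature),
#'   `cells_per_kg`, and `burden` if an inflammation mode is active.
#' @export
trajectory_table <- function(traj) {
  d <- dim(traj$u)
  clones <- dimnames(traj$u)[[2]]
  out <- expand.grid(time_days = traj$times, clone_id = clones,
                     compartment_index = seq_len(d[3]) - 1L,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$cells_per_kg <- as.vector(traj$u)
  if (!is.null(traj$burden))
    out$burden <- rep(traj$burden, times = d[2] * d[3])
  out
}

#' Write simulation results to a directory
#'
#' Writes each trajectory as a CSV (`<name>_trajectory.csv`, long format
#' from [trajectory_table()]), each table as `<name>.csv`, and a JSON
#' run manifest (`manifest.json`) holding the seed, solver tolerances,
#' package version and an MD5 hash of the configuration so a rerun can
#' be matched to its inputs.
#'
#' @param trajectories named list of `chip_trajectory` objects (may be
#'   empty).
#' @param tables named list of data.frames (may be empty).
#' @param out_dir output directory (created if needed).
#' @param config configuration list stored alongside (optional).
#' @param seed seed to record in the manifest.
#' @param tolerances named list of solver tolerances to record.
#' @return invisibly, the manifest as a list.
#' @export
write_results <- function(trajectories = list(), tables = list(),
                          out_dir = ".", config = NULL, seed = NA,
                          tolerances = list(rtol = 1e-6, atol = 1e-3)) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (nm in names(trajectories))
    utils::write.csv(trajectory_table(trajectories[[nm]]),
                     file.path(out_dir, paste0(nm, "_trajectory.csv")),
                     row.names = FALSE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  config_hash <- NA_character_
  if (!is.null(config)) {
    cfg_path <- file.path(out_dir, "config.yaml")
    write_config(config, cfg_path)
    config_hash <- unname(tools::md5sum(cfg_path))
  }
  manifest <- list(
    package = "chipgraft",
    version = as.character(utils::packageVersion("chipgraft")),
    seed = seed, tolerances = tolerances, config_hash = config_hash,
    files = c(paste0(names(trajectories), "_trajectory.csv"),
              paste0(names(tables), ".csv"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
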