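# Run configuration: YAML/JSON model description, defaults, validation,
# and the resolved-config echo written next to every set of results.

default_run_config <- function() {
  list(
    geometry = list(r_core_um = 5.10, delta_r_um = 1.25),
    transport = list(d_core_cm2_s = 2.6e-15, d_shell_cm2_s = 2.6e-12,
                     kappa = 1, burst_pct = 10),
    dose = list(a_load0_ug = 1030, drug = "bevacizumab", mw_g_mol = NULL),
    grid = list(n_core = 100, n_shell = NULL),
    solver = list(rel_tol = 1e-6, abs_tol = 1e-9, horizon_days = 180,
                  dt_days = 1)
  )
}

#' Read a model configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration with
#' blocks `geometry` (`r_core_um`, `delta_r_um`), `transport`
#' (`d_core_cm2_s`, `d_shell_cm2_s`, `kappa`, `burst_pct`), `dose`
#' (`a_load0_ug`, `drug`, `mw_g_mol`), `grid` (`n_core`, `n_shell`) and
#' `solver` (`rel_tol`, `abs_tol`, `horizon_days`, `dt_days`). Missing
#' optional entries fall back to the package defaults; missing required
#' geometry/transport keys are an error naming the key.
#'
#' @param path Configuration file path.
#' @return A resolved configuration list of class `cs_config`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("unsupported config format '", ext,
                     "' (use .yaml, .yml or .json)", call. = FALSE))
  resolve_config(raw)
}

#' Resolve a configuration list against the defaults
#'
#' @param raw A (possibly partial) configuration list.
#' @return A validated configuration of class `cs_config`.
#' @export
resolve_config <- function(raw = list()) {
  cfg <- utils::modifyList(default_run_config(), raw, keep.null = TRUE)
  required <- list(geometry = c("r_core_um", "delta_r_um"),
                   transport = c("d_core_cm2_s", "d_shell_cm2_s",
                                 "kappa", "burst_pct"))
  for (block in names(required)) {
    for (key in required[[block]]) {
      v <- cfg[[block]][[key]]
      if (is.null(v) || !is.numeric(v) || !is.finite(v)) {
        stop(sprintf("config is missing or has a non-numeric value for %s$%s",
                     block, key), call. = FALSE)
      }
    }
  }
  structure(cfg, class = "cs_config")
}

# Object builders from a resolved config.
config_geometry <- function(cfg) geometry(cfg$geometry$r_core_um, cfg$geometry$delta_r_um)
config_transport <- function(cfg) {
  transport_params(cfg$transport$d_core_cm2_s, cfg$transport$d_shell_cm2_s,
                   kappa = cfg$transport$kappa, burst = cfg$transport$burst_pct)
}
config_dose <- function(cfg) {
  dose_spec(cfg$dose$a_load0_ug, drug = cfg$dose$drug,
            mw_g_mol = cfg$dose$mw_g_mol)
}
config_grid <- function(cfg) {
  build_grid(config_geometry(cfg), n_core = cfg$grid$n_core,
             n_shell = cfg$grid$n_shell)
}
config_settings <- function(cfg, horizon = NULL) {
  h <- if (is.null(horizon)) cfg$solver$horizon_days else horizon
  solver_settings(rel_tol = cfg$solver$rel_tol, abs_tol = cfg$solver$abs_tol,
                  save_times = seq(0, h, by = cfg$solver$dt_days))
}

#' MD5 hash of a resolved configuration
#'
#' Serialises the configuration to canonical JSON and hashes the result,
#' so every output file set can carry the fingerprint of the exact
#' configuration that produced it.
#'
#' @param cfg A `cs_config` object.
#' @return Character MD5 digest.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

write_resolved_config <- function(cfg, out_dir) {
  path <- file.path(out_dir, "resolved_config.json")
  payload <- c(unclass(cfg), list(config_md5 = config_hash(cfg)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}
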