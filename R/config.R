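#' Run configuration
#'
#' A validated bundle of everything one experiment needs: preset name,
#' protocol, morphology overrides, solver steps, output directory and seed.
#' Defaults reproduce the main myelinated-axon (15 wraps) depolarization
#' experiment.
#'
#' @param preset axonal preset name
#' @param protocol "dadf" or "hadf"
#' @param dt_spike spike-window step (ms)
#' @param dt_subthreshold conditioning step (ms; NULL = protocol default)
#' @param max_seg_internode internode compartment cap (um)
#' @param window_ms spike window (ms)
#' @param site_stride evaluate every k-th presynaptic site
#' @param periaxonal_ends "sealed" or "grounded"
#' @param out_dir output directory or NULL
#' @param seed RNG seed recorded with the run (the pipeline itself is
#'   deterministic)
#' @return list of class \code{run_config}
#' @export
run_config <- function(preset = "Myelin1", protocol = "dadf",
                       dt_spike = 6.25e-3, dt_subthreshold = NULL,
                       max_seg_internode = 25, window_ms = 30,
                       site_stride = 1L, periaxonal_ends = "sealed",
                       out_dir = NULL, seed = 1L) {
  if (!preset %in% preset_names()) {
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(preset_names(), collapse = ", "))
  }
  if (!protocol %in% c("dadf", "hadf")) stop("protocol must be 'dadf' or 'hadf'")
  structure(
    list(
      schema_version = 1L,
      preset = preset, protocol = protocol,
      dt_spike = dt_spike, dt_subthreshold = dt_subthreshold,
      max_seg_internode = max_seg_internode, window_ms = window_ms,
      site_stride = as.integer(site_stride),
      periaxonal_ends = periaxonal_ends,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' Missing keys take their defaults; unknown keys are rejected with the
#' offending name. An empty file yields the full default configuration
#' (Myelin1, d-ADF).
#'
#' @param path YAML file
#' @return \code{\link{run_config}}
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(run_config))
  bad <- setdiff(names(raw), c(allowed, "schema_version"))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  }
  do.call(run_config, raw[intersect(names(raw), allowed)])
}

#' Stable hash of a configuration
#' @param config \code{run_config}
#' @return md5 string
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # serialize deterministically as canonical JSON text
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Write the summary and tables of a completed experiment
#'
#' Emits \code{summary.json} (space constants, extent, fractions, first-site
#' facilitation, with units and the configuration hash), \code{profiles.csv}
#' and \code{sites.csv} into \code{dir}.
#'
#' @param result \code{adf_result} from \code{\link{run_experiment}}
#' @param dir output directory (created if needed)
#' @param config optional \code{run_config} used for the run (hash embedded)
#' @return path of the summary file, invisibly
#' @export
write_summary <- function(result, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scv <- function(s) if (s$status == "ok") s$value else NA_real_
  summary <- list(
    preset = result$preset,
    protocol = result$protocol,
    complete = TRUE,
    space_constant_subthreshold_um = scv(result$space_constants$dv),
    space_constant_subthreshold_status = result$space_constants$dv$status,
    space_constant_area_um = scv(result$space_constants$area),
    space_constant_area_status = result$space_constants$area$status,
    space_constant_overshoot_um = scv(result$space_constants$overshoot),
    space_constant_overshoot_status = result$space_constants$overshoot$status,
    extent_um = if (result$extent$status == "ok") result$extent$value else NA_real_,
    extent_status = result$extent$status,
    fraction_ge5_pct = result$fraction$fraction_pct,
    qualifying_mean_distance_um = result$fraction$mean_dist,
    qualifying_sd_distance_um = result$fraction$sd_dist,
    n_sites = result$fraction$n_sites,
    first_site_distance_um = result$first_site$distance_um,
    first_site_adf_pct = result$first_site$adf_pct,
    first_site_conditioning_mv = result$first_site$cond_dv_mv,
    first_site_q_ratio = result$first_site$q_ratio,
    n_compartments = result$n_compartments,
    config_hash = if (!is.null(config)) config_hash(config) else NA_character_
  )
  jsonlite::write_json(
    summary, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  prof <- do.call(rbind, lapply(names(result$profiles), function(nm) {
    p <- result$profiles[[nm]]
    data.frame(
      profile = nm, quantity = attr(p, "quantity"),
      distance_um = p$distance, value = p$value
    )
  }))
  utils::write.csv(prof, file.path(dir, "profiles.csv"), row.names = FALSE)
  utils::write.csv(result$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  invisible(file.path(dir, "summary.json"))
}
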