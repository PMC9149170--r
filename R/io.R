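#' Load a model configuration file
#'
#' Reads a YAML configuration with up to three top-level sections:
#' `params` (any entry of [default_params()], nested maps for `kcat`,
#' `km`, `ka`, `ki`, `hill`, `growth_sigmoid`), `allocation` (`phi` map,
#' `resp_cap`, `cap_enabled`) and `regime` (fields of [feed_regime()]).
#' Missing entries fall back to package defaults, so a config need only
#' state what it overrides.
#'
#' @param path YAML file path.
#' @return list with elements `params` (`kinetic_params`), `alloc`
#'   (`proteome_allocation`), `regime` (`feed_regime`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  p_over <- cfg$params %||% list()
  p_over <- lapply(p_over, function(x) if (is.list(x)) unlist(x) else x)
  params <- do.call(default_params, p_over)
  al <- cfg$allocation %||% list()
  alloc <- if (length(al)) {
    proteome_allocation(unlist(al$phi),
                        resp_cap = al$resp_cap %||% params$resp_cap,
                        cap_enabled = al$cap_enabled %||% params$cap_enabled)
  } else {
    batch_allocation()
  }
  rg <- cfg$regime %||% list()
  regime <- if (length(rg)) {
    feed_regime(mode = rg$mode %||% "chemostat",
                D_avg = rg$D_avg %||% 0.1,
                TC = rg$TC, TF = rg$TF, D_feed = rg$D_feed,
                glc_feed = rg$glc_feed %||% 41.7)
  } else {
    feed_regime("chemostat", D_avg = 0.1)
  }
  list(params = params, alloc = alloc, regime = regime)
}

#' Write a model configuration file
#'
#' Serializes parameters, allocation and regime to YAML such that
#' [load_config()] reproduces them exactly.
#'
#' @param config list with `params`, `alloc`, `regime` (as returned by
#'   [load_config()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  p <- config$params
  keep <- c("kcat", "km", "ka", "ki", "hill", "growth_sigmoid",
            "maintenance_rate", "km_atp_mnt", "po_ratio", "w_tca",
            "g6p_per_x", "pyr_per_x", "atp_per_x", "dor_x",
            "k_ak", "k_ak_relax", "g_per_cmol", "protein_g_per_gx",
            "resp_cap", "cap_enabled", "axp_total", "nad_total")
  plist <- lapply(unclass(p)[keep], function(x)
    if (!is.null(names(x))) as.list(x) else x)
  al <- config$alloc
  rg <- config$regime
  out <- list(
    params = plist,
    allocation = list(phi = as.list(al$phi), resp_cap = al$resp_cap,
                      cap_enabled = al$cap_enabled),
    regime = Filter(function(x) !is.null(x) && !all(is.na(x)),
                    list(mode = rg$mode, D_avg = rg$D_avg, TC = rg$TC,
                         TF = rg$TF, D_feed = rg$D_feed,
                         glc_feed = rg$glc_feed)))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write a tidy TSV table
#'
#' Single header line, tab separation, '.' decimal marks.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(path)
}

#' Read a tidy TSV table
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' JSON provenance record: package version, command, seed, config hash
#' (MD5 of the config file, if any), wall time and output files.
#'
#' @param path manifest path (JSON).
#' @param command command name.
#' @param seed RNG seed used.
#' @param config_path config file (hashed if present).
#' @param outputs character vector of output file paths.
#' @param wall_time_s elapsed seconds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed, config_path = NULL,
                           outputs = character(), wall_time_s = NA) {
  manifest <- list(
    package = "protalloc",
    version = as.character(utils::packageVersion("protalloc")),
    command = command,
    rng_seed = seed,
    config = if (!is.null(config_path) && file.exists(config_path))
      list(path = config_path,
           md5 = unname(tools::md5sum(config_path))) else NULL,
    outputs = as.list(outputs),
    wall_time_s = wall_time_s,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}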