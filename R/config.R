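# Run configuration (defaults = reference values), YAML/JSON loading with
# strict key checking, and result persistence with provenance metadata.

#' Default run configuration
#'
#' All model parameter groups with their reference values. Every field
#' has a default, so an empty configuration file resolves to the
#' reference simulation.
#'
#' @return A nested named list with groups `tube_law`, `blood`,
#'   `geometry`, `circuit`, `systemic`, `protocol`, `numerics`, `seed`.
#' @export
default_config <- function() {
  list(
    tube_law = list(a = 0.03, c = 0.1, d = 0.08),
    blood = list(viscosity_mmHg_s = 2.63e-5, density_kg_m3 = 1060),
    geometry = list(arm_length_m = 1, cuff_length_m = 0.14),
    circuit = list(r_systemic = 100, c_art = 0.03, c_ven = 0.9,
                   r_ven_open = 10, collapse_threshold = 30,
                   collapse_width = 2),
    systemic = list(sbp = 120, pp = 40, hr = 60, venous = 10),
    protocol = list(rate = 6, start = 6, max_pressure = NA,
                    hold = 60),
    numerics = list(dt = 5e-4, pre_roll = 10, method = "euler",
                    ptm_reference = "proximal"),
    seed = 1L)
}

merge_config <- function(base, new, path = "") {
  for (nm in names(new)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key '", key, "'")
    if (is.list(base[[nm]]) && !is.null(new[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], as.list(new[[nm]]), key)
    else base[[nm]] <- new[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Defaults overlaid by an optional YAML or JSON file, overlaid by
#' explicit overrides. Unknown keys raise an error naming the offending
#' key.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL`.
#' @param overrides named nested list applied after the file.
#' @return A resolved configuration list (see [default_config()]).
#' @examples
#' cfg <- load_config(overrides = list(systemic = list(sbp = 123, pp = 48,
#'                                                     hr = 73),
#'                                     protocol = list(rate = 6.8)))
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    file_cfg <- switch(ext,
                       yaml = , yml = yaml::read_yaml(path),
                       json = jsonlite::fromJSON(path,
                                                 simplifyVector = TRUE),
                       stop("unsupported config format '.", ext,
                            "' (use YAML or JSON)"))
    if (length(file_cfg)) cfg <- merge_config(cfg, file_cfg)
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

#' Build parameter objects from a configuration
#'
#' @param cfg a resolved configuration from [load_config()].
#' @return A list of the parameter objects (`input`, `protocol`,
#'   `circuit`, `geometry`, `tube`, `blood`) plus `numerics` and `seed`.
#' @export
config_objects <- function(cfg) {
  pmax_ <- cfg$protocol$max_pressure
  if (is.null(pmax_) || is.na(pmax_)) pmax_ <- NULL
  list(input = systemic_input(cfg$systemic$sbp, cfg$systemic$pp,
                              cfg$systemic$hr, cfg$systemic$venous),
       protocol = cuff_protocol(cfg$protocol$rate, cfg$protocol$start,
                                pmax_, cfg$protocol$hold),
       circuit = circuit_params(cfg$circuit$r_systemic, cfg$circuit$c_art,
                                cfg$circuit$c_ven, cfg$circuit$r_ven_open,
                                cfg$circuit$collapse_threshold,
                                cfg$circuit$collapse_width),
       geometry = arm_geometry(cfg$geometry$arm_length_m,
                               cfg$geometry$cuff_length_m),
       tube = tube_law(cfg$tube_law$a, cfg$tube_law$c, cfg$tube_law$d),
       blood = blood_properties(cfg$blood$viscosity_mmHg_s,
                                cfg$blood$density_kg_m3),
       numerics = cfg$numerics, seed = cfg$seed)
}

#' Run one simulation from a configuration
#'
#' @param cfg a resolved configuration from [load_config()].
#' @return An [simulate_arm()] result.
#' @export
simulate_from_config <- function(cfg) {
  ob <- config_objects(cfg)
  simulate_arm(ob$input, ob$protocol, ob$circuit, ob$geometry, ob$tube,
               ob$blood, dt = ob$numerics$dt,
               pre_roll = ob$numerics$pre_roll,
               method = ob$numerics$method,
               ptm_reference = ob$numerics$ptm_reference)
}

# short FNV-1a content hash of the serialized configuration (32-bit
# arithmetic carried in doubles; R integers are 31-bit signed)
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  xor32 <- function(a, b) {
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536)) +
      65536 * bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  }
  mul32 <- function(a, b) {
    ((a %% 65536) * b %% 2^32 + ((a %/% 65536) * b %% 65536) * 65536) %% 2^32
  }
  h <- 2166136261
  for (b in bytes) h <- mul32(xor32(h, b), 16777619)
  sprintf("%08x", h)
}

result_meta <- function(cfg, seed = cfg$seed) {
  list(package = "cuffsim",
       version = as.character(utils::packageVersion("cuffsim")),
       config_hash = config_hash(cfg), seed = seed)
}

#' Write analysis artifacts with provenance metadata
#'
#' Time series and per-beat tables go to CSV, metrics and sensitivity
#' results to JSON; every artifact set gets a JSON sidecar embedding the
#' configuration, its hash, the seed and the package version. The
#' directory is created if missing.
#'
#' @param x an `arm_sim`, `response_metrics`, or `sobol_analysis` object.
#' @param dir output directory.
#' @param cfg the configuration the object was produced from (for the
#'   sidecar); defaults to [default_config()].
#' @param name file stem; defaults to a class-specific stem.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir, cfg = default_config(), name = NULL) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  meta <- result_meta(cfg)
  paths <- character(0)
  wjson <- function(obj, p) {
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    p
  }
  if (inherits(x, "arm_sim")) {
    stem <- file.path(dir, name %||% "run")
    p1 <- paste0(stem, ".csv")
    df <- as.data.frame(x)
    names(df) <- c("t_s", "p_sys", "p_cuff", "p_art_distal", "p_ven_distal")
    write.csv(format(df, digits = 9, trim = TRUE), p1, row.names = FALSE,
              quote = FALSE)
    paths <- c(p1, wjson(c(meta, list(config = cfg)),
                         paste0(stem, "_meta.json")))
  } else if (inherits(x, "response_metrics")) {
    stem <- file.path(dir, name %||% "metrics")
    vals <- as.list(setNames(unlist(x[.METRIC_COLS]), .METRIC_LABELS))
    paths <- wjson(c(vals, list(onset_beat = x$onset$beat,
                                onset_p_cuff = x$onset$p_cuff), meta),
                   paste0(stem, ".json"))
  } else if (inherits(x, "sobol_analysis")) {
    stem <- file.path(dir, name %||% "sobol")
    r <- x$result
    p1 <- wjson(list(S1 = as.data.frame(r$S1), ST = as.data.frame(r$ST),
                     S1_ci = as.data.frame(r$S1_ci),
                     ST_ci = as.data.frame(r$ST_ci),
                     n = r$n, n_used = r$n_used, seed = r$seed,
                     estimators = as.list(r$estimators), meta = meta),
               paste0(stem, ".json"))
    # wide table: rows = parameters, S1/ST column pairs per metric
    wide <- data.frame(parameter = rownames(r$S1))
    for (m in colnames(r$S1)) {
      wide[[paste0(m, "_S1")]] <- r$S1[, m]
      wide[[paste0(m, "_ST")]] <- r$ST[, m]
    }
    p2 <- paste0(stem, ".csv")
    write.csv(wide, p2, row.names = FALSE)
    paths <- c(p1, p2)
  } else stop("no write_results method for class ", class(x)[1])
  invisible(paths)
}

#' Read back a simulation CSV written by [write_results()]
#'
#' @param path path to the CSV.
#' @return A data frame with the five series columns.
#' @export
read_simulation <- function(path) {
  df <- read.csv(path)
  need <- c("t_s", "p_sys", "p_cuff", "p_art_distal", "p_ven_distal")
  if (!all(need %in% names(df)))
    stop("not a simulation series file: ", path)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
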