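# Pipeline configuration: schema-validated, defaults filled, fully
# serialized into every derivative for provenance.

default_config <- function() {
  list(
    dataset_root = NULL,
    output_root = NULL,
    seed = 1L,
    log_level = "info",
    subjects = NULL,               # optional subject filter
    stages = list(staging = TRUE, flagging = TRUE, ica = TRUE),
    line_freq = 60,
    notch_harmonics = 1,
    window_s = 1,
    envelope = list(pL = 0.3, pU = 0.7, k = 6),
    fractions = list(p_ch = 0.2, p_t = 0.2),
    k_neighbors = 3,
    bridge = list(r_median_min = 0.98, r_dispersion_max = 0.01),
    low_r = list(pL = 0.3, pU = 0.7, k = 6, p_ch = 0.2, p_t = 0.2),
    max_gap_s = 5,
    ica = list(method = "extended_infomax", max_steps = 512,
               exclude_gap = TRUE, amica_binary = NULL,
               low_power_share = 0.001,
               envelope = list(pL = 0.3, pU = 0.7, k = 6), p_t = 0.2),
    overwrite = FALSE
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("config: unknown key(s): %s",
          paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) && is.list(user[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], paste0(path, ".", k))
    else defaults[k] <- list(user[[k]])  # keep explicit NULLs
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config file (or takes a list), rejects unknown keys with an
#' error naming them, fills every documented default, and normalizes types.
#' Normalization is idempotent: validating an already-normalized config is a
#' fixed point.
#'
#' @param x path to a YAML file, or a (possibly partial) config list.
#' @return a normalized `pipeline_config` list.
#' @export
validate_config <- function(x) {
  user <- if (is.character(x)) {
    if (!file.exists(x)) stopf("validate_config: '%s' not found", x)
    yaml::read_yaml(x) %||% list()
  } else if (is.list(x)) unclass(x) else stopf("validate_config: need a path or a list")
  cfg <- merge_config(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  for (k in c("line_freq", "window_s", "max_gap_s", "notch_harmonics", "k_neighbors"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  if (!cfg$line_freq %in% c(50, 60))
    warnf("config: unusual line_freq %g (expected 50 or 60)", cfg$line_freq)
  structure(cfg, class = "pipeline_config")
}
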