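#' Read and write cell-model configurations
#'
#' Model configurations are stored as JSON (or YAML) with keys `death_rate`,
#' `theta`, `beta1` and `G`; the response entries are objects with a `family`
#' name and a `params` object, mirroring the [response_fn] constructors, e.g.
#'
#' ```json
#' {
#'   "death_rate": 0.5, "theta": 0.8,
#'   "beta1": {"family": "constant", "params": {"value": 0.5}},
#'   "G": {"family": "hill_increasing",
#'         "params": {"gmax": 1.8467, "n": 4, "h": 0.5}}
#' }
#' ```
#'
#' Unknown keys are rejected; configurations round-trip through
#' `write_model_config()`.
#'
#' @param path file path; `.yaml`/`.yml` selects YAML, anything else JSON.
#' @param model a [cell_model()] built from [response_fn] families (custom
#'   functions cannot be serialised).
#' @return `read_model_config()` returns a [cell_model()];
#'   `write_model_config()` returns `path` invisibly.
#' @name model_config
NULL

#' @rdname model_config
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
                 class = "delaychart_error_config")
  }
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  required <- c("death_rate", "theta", "beta1", "G")
  unknown <- setdiff(names(cfg), required)
  missing <- setdiff(required, names(cfg))
  problems <- c(
    if (length(unknown)) paste0("unknown key(s): ", toString(unknown)),
    if (length(missing)) paste0("missing key(s): ", toString(missing))
  )
  if (length(problems)) {
    rlang::abort(paste0("invalid model config: ",
                        paste(problems, collapse = "; ")),
                 class = "delaychart_error_config")
  }
  cell_model(
    death_rate = as.numeric(cfg$death_rate),
    theta = as.numeric(cfg$theta),
    beta1 = response_from_config(cfg$beta1, "beta1"),
    G = response_from_config(cfg$G, "G")
  )
}

response_from_config <- function(entry, what) {
  if (!is.list(entry) || !all(c("family", "params") %in% names(entry)) ||
      length(setdiff(names(entry), c("family", "params"))) > 0) {
    rlang::abort(
      paste0("invalid `", what, "` entry: need exactly {family, params}"),
      class = "delaychart_error_config"
    )
  }
  p <- entry$params
  switch(entry$family,
    constant = response_constant(p$value),
    hill_increasing = response_hill(p$gmax, p$n, p$h),
    linear_clamped = response_linear(p$a, p$b),
    rlang::abort(paste0("unknown response family: ", entry$family),
                 class = "delaychart_error_config")
  )
}

#' @rdname model_config
#' @export
write_model_config <- function(model, path) {
  ser <- function(r) {
    if (r$family == "custom") {
      rlang::abort("custom response functions cannot be serialised",
                   class = "delaychart_error_config")
    }
    list(family = r$family, params = r$params)
  }
  cfg <- list(
    death_rate = model$death_rate, theta = model$theta,
    beta1 = ser(model$beta1), G = ser(model$G)
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path, precision = 15)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
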