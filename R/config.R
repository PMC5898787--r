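#' Read a flat configuration file
#'
#' Configurations are flat, human-editable `key = value` text: blank lines
#' and `#` comments are ignored, optional `[section]` headers are allowed
#' purely as visual grouping.  Keys are either model parameter names (see
#' [synplast_params()], e.g. `M_GR = 5`, `k11 = 0`), scenario constants
#' prefixed with `scenario.` (see [scenario_constants()], e.g.
#' `scenario.cortisol_high = 20`), or `out_dir`.  Values merge over the
#' package defaults; unknown keys and invalid values (negative rates,
#' `M_MR >= M_GR`, ...) are rejected with an error naming the key.
#'
#' @param path Path to a configuration file; an empty or absent `path`
#'   (`NULL`) yields the defaults.
#' @return A list of class `synplast_config` with elements `params`
#'   (a `synplast_params`), `scenario` (scenario-constant overrides) and
#'   `out_dir`.
#' @examples
#' f <- tempfile()
#' writeLines(c("[cascade]", "M_GR = 4", "scenario.cortisol_high = 10"), f)
#' cfg <- load_config(f)
#' cfg$params$M_GR
#' @export
load_config <- function(path = NULL) {
  entries <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("load_config(): no such file: ", path, call. = FALSE)
    }
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    lines <- lines[!grepl("^\\[.*\\]$", lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        stop("load_config(): cannot parse line: '", ln, "'", call. = FALSE)
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!nzchar(key)) {
        stop("load_config(): empty key in line: '", ln, "'", call. = FALSE)
      }
      entries[[key]] <- val
    }
  }
  params_over <- list()
  scen_over <- list()
  out_dir <- NULL
  param_names <- names(synplast_params())
  scen_names <- names(scenario_constants())
  for (key in names(entries)) {
    val <- entries[[key]]
    if (identical(key, "out_dir")) {
      out_dir <- val
    } else if (startsWith(key, "scenario.")) {
      nm <- sub("^scenario\\.", "", key)
      if (!nm %in% scen_names) {
        stop("load_config(): unknown scenario constant '", key, "'",
             call. = FALSE)
      }
      scen_over[[nm]] <- .parse_config_value(val, key)
    } else {
      if (!key %in% param_names) {
        stop("load_config(): unknown configuration key '", key, "'",
             call. = FALSE)
      }
      params_over[[key]] <- .parse_config_value(val, key)
    }
  }
  params <- tryCatch(
    do.call(synplast_params, params_over),
    error = function(e) stop("load_config(): ", conditionMessage(e),
                             call. = FALSE)
  )
  structure(list(params = params, scenario = scen_over, out_dir = out_dir),
            class = "synplast_config")
}

.parse_config_value <- function(val, key) {
  if (val %in% c("TRUE", "true", "FALSE", "false")) {
    return(val %in% c("TRUE", "true"))
  }
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val  # character (e.g. scurve_shape, a_sign_convention)
}

#' Write a configuration file
#'
#' Serialises the fully resolved configuration (every parameter and every
#' scenario constant, not just the overrides) so that outputs carry their
#' complete provenance; `load_config(write_config(cfg, f))` reproduces
#' `cfg` exactly.
#'
#' @param config A `synplast_config` from [load_config()], or a
#'   `synplast_params` object (wrapped with default scenario constants).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "synplast_params")) {
    config <- structure(list(params = config, scenario = list(),
                             out_dir = NULL), class = "synplast_config")
  }
  stopifnot(inherits(config, "synplast_config"))
  fmt <- function(v) {
    if (is.logical(v)) {
      if (v) "TRUE" else "FALSE"
    } else if (is.character(v)) {
      v
    } else {
      format(v, digits = 17)
    }
  }
  lines <- c("# synplast configuration (fully resolved)", "[parameters]")
  p <- config$params
  lines <- c(lines, vapply(names(p), function(nm) {
    paste(nm, "=", fmt(p[[nm]]))
  }, character(1)))
  k <- scenario_constants()
  k[names(config$scenario)] <- config$scenario
  lines <- c(lines, "", "[scenario]", vapply(names(k), function(nm) {
    paste0("scenario.", nm, " = ", fmt(k[[nm]]))
  }, character(1)))
  if (!is.null(config$out_dir)) {
    lines <- c(lines, "", paste("out_dir =", config$out_dir))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
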