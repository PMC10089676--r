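.cli_config_keys <- c("rules", "include", "exclude", "format",
                      "severity_overrides", "ignore", "verify")
.verify_config_keys <- c("n_runs", "epochs", "seed", "modes", "device")

#' Toolkit configuration
#'
#' Defaults for the lint / verify / fingerprint workflow. Precedence is
#' CLI flags over file configuration over these defaults. Unknown keys are
#' rejected so typos cannot silently change behavior.
#'
#' @param rules Optional rules-file override path.
#' @param include,exclude Glob patterns for project linting.
#' @param format Output format, `"text"` or `"json"`.
#' @param severity_overrides Named character vector, rule id -> severity.
#' @param ignore Rule ids to suppress.
#' @param verify List with `n_runs` (default 5, matching the standard
#'   five-repetition protocol), `epochs` (default 25), `seed` (default 0),
#'   `modes` (default `"deterministic"`), `device` (default `"cpu"`).
#' @return A `detml_config`.
#' @export
cli_config <- function(rules = NULL, include = "*.py", exclude = character(0),
                       format = "text", severity_overrides = character(0),
                       ignore = character(0), verify = list()) {
  if (!format %in% c("text", "json")) {
    detml_stop("format must be 'text' or 'json'", class = "detml_config_error")
  }
  unknown <- setdiff(names(verify), .verify_config_keys)
  if (length(unknown)) {
    detml_stop("unknown verify config key(s): %s",
               paste(unknown, collapse = ", "), class = "detml_config_error")
  }
  verify_full <- utils::modifyList(
    list(n_runs = 5L, epochs = 25L, seed = 0L,
         modes = "deterministic", device = "cpu"),
    verify)
  structure(list(rules = rules, include = include, exclude = exclude,
                 format = format, severity_overrides = severity_overrides,
                 ignore = ignore, verify = verify_full),
            class = "detml_config")
}

#' Load configuration from a `detml.yml` file
#'
#' @param path Path to a YAML configuration file with any subset of the
#'   keys accepted by [cli_config()]; unknown keys raise a config error.
#' @return A `detml_config`.
#' @export
load_cli_config <- function(path) {
  if (!file.exists(path)) {
    detml_stop("config file '%s' not found", path, class = "detml_config_error")
  }
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    detml_stop("cannot parse config '%s': %s", path, conditionMessage(e),
               class = "detml_config_error")
  })
  doc <- doc %||% list()
  unknown <- setdiff(names(doc), .cli_config_keys)
  if (length(unknown)) {
    detml_stop("unknown config key(s) in '%s': %s", path,
               paste(unknown, collapse = ", "), class = "detml_config_error")
  }
  if (!is.null(doc$severity_overrides)) {
    doc$severity_overrides <- unlist(doc$severity_overrides)
  }
  do.call(cli_config, doc)
}

# the lint-engine view of a toolkit config
as_lint_config <- function(config) {
  lint_config(include = config$include, exclude = config$exclude,
              ignore = config$ignore,
              severity_overrides = config$severity_overrides)
}
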