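# Rule evaluation against a syntax model.
#
# Matching semantics (v1 pattern language): exact qualified-name equality
# after alias resolution for call sites, attribute-assignment targets and
# keyword-argument names; ALL-CAPS patterns also match environment-variable
# writes. A requirement satisfied anywhere in the file counts: the linter
# validates presence, not execution order.

.finding <- function(rule, source_id, line, col, symbol, severity = rule$severity,
                     message = rule$message) {
  list(rule_id = rule$id, source = source_id, line = as.integer(line),
       col = as.integer(col), symbol = symbol, severity = severity,
       message = message, suggestion = rule$alternative)
}

.matches_call <- function(model, patterns) {
  model$calls$qualified %in% patterns
}

.matches_env_write <- function(model, patterns) {
  model$env_refs$access == "write" & model$env_refs$name %in% patterns
}

.constant_truthiness <- function(v) {
  if (is.null(v) || (length(v) == 1L && is.na(v))) return(NA)
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  if (is.character(v)) return(nzchar(v))
  NA
}

#' Check that every required seed is set
#'
#' One finding per seed rule whose patterns match no call site, no
#' environment-variable write, and no constant keyword argument (the hash
#' seed is satisfiable only by an env write; the XGBoost seed only by a
#' `seed=`/`random_state=` keyword).
#'
#' @param model A `detml_syntax_model`.
#' @param profile A `detml_profile` for a detected framework.
#' @return List of findings (possibly empty).
#' @export
check_seed_requirements <- function(model, profile) {
  findings <- list()
  for (r in profile$seed_rules) {
    satisfied <- any(.matches_call(model, r$patterns)) ||
      any(.matches_env_write(model, r$patterns)) ||
      any(model$kwargs$name %in% r$patterns &
            !vapply(model$kwargs$value, is.null, logical(1)))
    if (!satisfied) {
      findings[[length(findings) + 1L]] <-
        .finding(r, model$source_id, 1L, 0L, symbol = r$patterns[1L])
    }
  }
  findings
}

#' Check determinism flags and environment variables
#'
#' One finding per flag/env rule not satisfied. A flag rule is satisfied by
#' a matching call site, by an attribute assignment of the required constant
#' to the flagged target, or by a keyword argument with the required
#' constant. A flag explicitly set to the *negation* of its required value
#' (e.g. enabling cuDNN benchmark) fires an error at that line even though
#' the target was "set".
#'
#' @inheritParams check_seed_requirements
#' @return List of findings.
#' @export
check_determinism_enforcement <- function(model, profile) {
  findings <- list()
  for (r in c(profile$flag_rules, profile$env_rules)) {
    required <- r$required_value %||% TRUE
    satisfied <- FALSE
    # call-site satisfaction; a constant first argument contradicting the
    # required value is a violation at that call
    hit <- which(.matches_call(model, r$patterns))
    for (i in hit) {
      arg <- model$calls$first_arg_truthy[i]
      if (!is.na(arg) && arg != required) {
        findings[[length(findings) + 1L]] <- .finding(
          r, model$source_id, model$calls$line[i], model$calls$col[i],
          symbol = model$calls$qualified[i],
          message = paste0(r$message, " (explicitly set to the ",
                           "nondeterministic value here)"))
      } else {
        satisfied <- TRUE
      }
    }
    # attribute assignment satisfaction
    tgt <- which(model$assignments$target %in% r$patterns)
    for (i in tgt) {
      val <- .constant_truthiness(model$assignments$value[[i]])
      if (!is.na(val) && val == required) {
        satisfied <- TRUE
      } else if (!is.na(val)) {
        findings[[length(findings) + 1L]] <- .finding(
          r, model$source_id, model$assignments$line[i], 0L,
          symbol = model$assignments$target[i],
          message = paste0(r$message, " (explicitly set to the ",
                           "nondeterministic value here)"))
      }
    }
    # keyword-argument satisfaction
    kw <- which(model$kwargs$name %in% r$patterns)
    for (i in kw) {
      val <- .constant_truthiness(model$kwargs$value[[i]])
      if (!is.na(val) && val == required) satisfied <- TRUE
    }
    # env write satisfaction
    if (any(.matches_env_write(model, r$patterns))) satisfied <- TRUE
    if (!satisfied &&
        !any(vapply(findings, function(f) f$rule_id == r$id, logical(1)))) {
      findings[[length(findings) + 1L]] <-
        .finding(r, model$source_id, 1L, 0L, symbol = r$patterns[1L])
    }
  }
  findings
}

#' Check for forbidden and discouraged calls
#'
#' One finding per call site matching a `forbidden_call` or
#' `discouraged_pattern` rule, carrying the rule's suggested deterministic
#' alternative when one exists. Findings are ordered by (source, line, col).
#'
#' @inheritParams check_seed_requirements
#' @return List of findings.
#' @export
check_forbidden_calls <- function(model, profile) {
  findings <- list()
  for (r in c(profile$forbidden_rules, profile$discouraged_rules)) {
    hit <- which(.matches_call(model, r$patterns))
    for (i in hit) {
      findings[[length(findings) + 1L]] <- .finding(
        r, model$source_id, model$calls$line[i], model$calls$col[i],
        symbol = model$calls$qualified[i])
    }
  }
  .sort_findings(findings)
}

.sort_findings <- function(findings) {
  if (length(findings) < 2L) return(findings)
  key <- order(vapply(findings, `[[`, "", "source"),
               vapply(findings, `[[`, 1L, "line"),
               vapply(findings, `[[`, 1L, "col"),
               vapply(findings, `[[`, "", "rule_id"))
  findings[key]
}

#' Detect which ML frameworks a source uses
#'
#' A framework is detected iff any of its profile's import roots appears in
#' the model's imported top-level modules.
#'
#' @param model A `detml_syntax_model`.
#' @param registry A `detml_registry` (frameworks known to the toolkit).
#' @return Character vector of detected framework ids (never `"general"`).
#' @export
detect_frameworks <- function(model, registry) {
  fw <- setdiff(.framework_ids, "general")
  fw[vapply(fw, function(f) {
    any(.import_roots[[f]] %in% model$import_roots)
  }, logical(1))]
}

#' Lint configuration
#'
#' @param include,exclude Glob patterns selecting project files
#'   (for [lint_project()]).
#' @param ignore Rule ids whose findings are dropped.
#' @param severity_overrides Named character vector mapping rule id to a
#'   replacement severity.
#' @return A `detml_lint_config` list.
#' @export
lint_config <- function(include = "*.py", exclude = character(0),
                        ignore = character(0),
                        severity_overrides = character(0)) {
  if (length(severity_overrides)) {
    bad <- setdiff(unname(severity_overrides), .rule_severities)
    if (length(bad)) {
      detml_stop("invalid severity override value(s): %s",
                 paste(bad, collapse = ", "), class = "detml_config_error")
    }
  }
  structure(list(include = include, exclude = exclude, ignore = ignore,
                 severity_overrides = severity_overrides),
            class = "detml_lint_config")
}

.apply_config <- function(findings, config) {
  findings <- Filter(function(f) !(f$rule_id %in% config$ignore), findings)
  if (length(config$severity_overrides)) {
    findings <- lapply(findings, function(f) {
      ov <- config$severity_overrides[f$rule_id]
      if (!is.na(ov)) f$severity <- unname(ov)
      f
    })
  }
  findings
}

.make_report <- function(sources, frameworks, findings) {
  sev <- vapply(findings, `[[`, "", "severity")
  counts <- c(error = sum(sev == "error"),
              warning = sum(sev == "warning"),
              info = sum(sev == "info"))
  structure(list(
    sources = sources,
    frameworks = sort(frameworks),
    findings = findings,
    counts = counts,
    passed = counts[["error"]] == 0L
  ), class = "detml_lint_report")
}

#' Lint one Python source
#'
#' Runs parse, framework detection, and every applicable check (seed
#' requirements, determinism flags/env vars, forbidden and discouraged
#' calls) for the detected frameworks plus the general rules. Sources with
#' no known ML imports pass vacuously: general seed rules are only enforced
#' once at least one ML framework is in use. A syntax error the analyzer
#' cannot tokenize past yields a single `PARSE-ERROR` finding and a failed
#' report. Output is deterministic: identical input bytes and registry give
#' an identical report.
#'
#' @param path Path to a `.py` file (or `NULL` when `text` is given).
#' @param text Source text, overrides `path`.
#' @param registry A `detml_registry`; defaults to the packaged ruleset.
#' @param config A [lint_config()].
#' @return A `detml_lint_report`.
#' @examples
#' r <- lint_file(text = "import torch\n", registry = load_rules())
#' r$passed    # FALSE: seeds and flags missing
#' @export
lint_file <- function(path = NULL, text = NULL, registry = load_rules(),
                      config = lint_config()) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) {
      detml_stop("cannot read source file '%s'", path %||% "<null>",
                 class = "detml_io_error")
    }
    text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
    source_id <- path
  } else {
    source_id <- if (!is.null(path)) path else "<memory>"
  }

  model <- tryCatch(parse_python_source(text, source_id),
                    detml_parse_error = function(e) e)
  if (inherits(model, "detml_parse_error")) {
    line <- suppressWarnings(
      as.integer(sub(".*line ([0-9]+).*", "\\1", conditionMessage(model))))
    pe <- list(rule_id = "PARSE-ERROR", source = source_id,
               line = if (is.na(line)) 1L else line, col = 0L,
               symbol = NA_character_, severity = "error",
               message = conditionMessage(model), suggestion = NULL)
    return(.make_report(source_id, character(0), list(pe)))
  }

  frameworks <- detect_frameworks(model, registry)
  findings <- list()
  if (length(frameworks)) {
    seen <- character(0)
    for (fw in frameworks) {
      profile <- rule_profile(registry, fw)
      # drop general rules already evaluated for a previous framework
      dedup <- function(rules) Filter(function(r) !(r$id %in% seen), rules)
      profile$seed_rules <- dedup(profile$seed_rules)
      profile$flag_rules <- dedup(profile$flag_rules)
      profile$env_rules <- dedup(profile$env_rules)
      profile$forbidden_rules <- dedup(profile$forbidden_rules)
      profile$discouraged_rules <- dedup(profile$discouraged_rules)
      findings <- c(findings,
                    check_seed_requirements(model, profile),
                    check_determinism_enforcement(model, profile),
                    check_forbidden_calls(model, profile))
      seen <- c(seen, vapply(c(profile$seed_rules, profile$flag_rules,
                               profile$env_rules, profile$forbidden_rules,
                               profile$discouraged_rules), `[[`, "", "id"))
    }
  }
  findings <- .apply_config(.sort_findings(findings), config)
  .make_report(source_id, frameworks, findings)
}

#' Lint every Python file under a directory
#'
#' Recursive over the configuration's include/exclude globs; per-file
#' reports are merged, summary counts are additive, and the merged report
#' fails iff any file has an error finding. A root with no matching files
#' yields a passing report over zero sources.
#'
#' @param root Project root directory.
#' @inheritParams lint_file
#' @return A merged `detml_lint_report`.
#' @export
lint_project <- function(root, registry = load_rules(), config = lint_config()) {
  if (!dir.exists(root)) {
    detml_stop("project root '%s' does not exist", root,
               class = "detml_io_error")
  }
  files <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
  keep <- Reduce(`|`, lapply(config$include, function(g) {
    grepl(utils::glob2rx(g), basename(files)) |
      grepl(utils::glob2rx(g), files)
  }), rep(FALSE, length(files)))
  for (g in config$exclude) {
    keep <- keep & !grepl(utils::glob2rx(g), files) &
      !grepl(utils::glob2rx(g), basename(files))
  }
  files <- files[keep]
  reports <- lapply(file.path(root, files), lint_file,
                    registry = registry, config = config)
  merged <- .make_report(
    sources = file.path(root, files),
    frameworks = unique(unlist(lapply(reports, `[[`, "frameworks"))) %||% character(0),
    findings = .sort_findings(do.call(c, c(lapply(reports, `[[`, "findings"),
                                           list(list()))))
  )
  if (!length(files)) {
    merged$notice <- "no matching source files under root"
  }
  merged
}

#' Render a lint report
#'
#' @param report A `detml_lint_report`.
#' @param format `"text"` for human-readable output, `"json"` for a
#'   machine-readable document with stable key order
#'   (sources, frameworks, findings, summary, passed).
#' @return A character scalar.
#' @export
render_report <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      sources = as.list(report$sources),
      frameworks = as.list(report$frameworks),
      findings = lapply(report$findings, function(f) {
        list(rule_id = f$rule_id, source = f$source, line = f$line,
             col = f$col, symbol = f$symbol, severity = f$severity,
             message = f$message,
             suggestion = f$suggestion %||% NA_character_)
      }),
      summary = as.list(report$counts),
      passed = report$passed
    )
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                         digits = NA)))
  }
  lines <- c(sprintf("detml lint: %d source(s), frameworks: %s",
                     length(report$sources),
                     if (length(report$frameworks))
                       paste(report$frameworks, collapse = ", ") else "none"))
  for (f in report$findings) {
    lines <- c(lines, sprintf("%s:%d:%d [%s] %s: %s", f$source, f$line, f$col,
                              f$severity, f$rule_id, f$message))
    if (!is.null(f$suggestion)) {
      lines <- c(lines, sprintf("    suggestion: %s", f$suggestion))
    }
  }
  lines <- c(lines, sprintf("errors: %d  warnings: %d  info: %d",
                            report$counts[["error"]],
                            report$counts[["warning"]],
                            report$counts[["info"]]),
             if (report$passed) "PASSED" else "FAILED")
  paste(lines, collapse = "\n")
}

#' @export
print.detml_lint_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
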