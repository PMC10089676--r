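# Generator of lintable Python source fixtures with known expected
# findings. Fixtures are synthesized from the registry itself, so the
# generator and the lint engine share no matching code: agreement between
# the two is a meaningful soundness check.

#' Describe a code fixture
#'
#' @param framework Framework the fixture uses (`"pytorch"`,
#'   `"tensorflow"`, `"xgboost"`).
#' @param violations Rule ids to violate: requirement rules
#'   (seed/flag/env) are violated by *omitting* their satisfying line,
#'   forbidden/discouraged rules by *injecting* a matching call.
#' @param aliases Named character vector of import aliases, e.g.
#'   `c(numpy = "np")`; unaliased modules are imported plainly.
#' @return A `detml_fixture_spec`.
#' @export
fixture_spec <- function(framework, violations = character(0),
                         aliases = character(0)) {
  if (!framework %in% setdiff(.framework_ids, "general")) {
    detml_stop("fixture framework must be a concrete ML framework, got '%s'",
               framework, class = "detml_validation_error")
  }
  structure(list(framework = framework, violations = violations,
                 aliases = aliases),
            class = "detml_fixture_spec")
}

# local (possibly aliased) spelling of a canonical dotted name
.local_name <- function(qualified, aliases) {
  parts <- strsplit(qualified, ".", fixed = TRUE)[[1]]
  root <- parts[1]
  if (root %in% names(aliases)) {
    paste(c(aliases[[root]], parts[-1]), collapse = ".")
  } else {
    qualified
  }
}

# line of code that satisfies a requirement rule, or NULL for none
.satisfier_line <- function(rule, aliases) {
  pat <- rule$patterns[1]
  if (!grepl(".", pat, fixed = TRUE) && toupper(pat) == pat) {
    return(sprintf('os.environ["%s"] = "1"', pat))
  }
  if (!grepl(".", pat, fixed = TRUE)) {           # keyword-argument setting
    required <- rule$required_value %||% TRUE
    val <- if (rule$category == "seed_required") "0"
    else if (required) "True" else "False"
    return(sprintf("run_config = dict_config(%s=%s)", pat, val))
  }
  local <- .local_name(pat, aliases)
  if (rule$category == "seed_required") {
    return(sprintf("%s(0)", local))
  }
  required <- rule$required_value %||% TRUE
  if (!required) {
    return(sprintf("%s = False", local))
  }
  sprintf("%s(True)", local)
}

.injection_line <- function(rule, aliases) {
  pat <- rule$patterns[1]
  sprintf("result = %s(data)", .local_name(pat, aliases))
}

#' Generate a Python source fixture with known expected findings
#'
#' Emits syntactically valid source that imports the spec's framework,
#' satisfies every seed/flag/env requirement of its profile *except* the
#' violated ones, and calls every violated forbidden/discouraged operation
#' at a known line. The expected findings (rule id, line) are produced by
#' construction, independently of the lint engine.
#'
#' @param spec A [fixture_spec()].
#' @param registry A `detml_registry`.
#' @return `list(source, expected)` where `expected` is a data.frame with
#'   columns `rule_id` and `line` (line 1 for omitted requirements, the
#'   call line for injected operations).
#' @export
generate_code_fixture <- function(spec, registry = load_rules()) {
  stopifnot(inherits(spec, "detml_fixture_spec"))
  profile <- rule_profile(registry, spec$framework)
  all_rules <- c(profile$seed_rules, profile$flag_rules, profile$env_rules,
                 profile$forbidden_rules, profile$discouraged_rules)
  ids <- vapply(all_rules, `[[`, "", "id")
  unknown <- setdiff(spec$violations, ids)
  if (length(unknown)) {
    detml_stop("unknown rule id(s) for framework '%s': %s", spec$framework,
               paste(unknown, collapse = ", "),
               class = "detml_validation_error")
  }

  req_rules <- c(profile$seed_rules, profile$flag_rules, profile$env_rules)
  inj_rules <- Filter(function(r) r$id %in% spec$violations,
                      c(profile$forbidden_rules, profile$discouraged_rules))

  # imports: os + every root referenced by emitted lines + the framework
  roots <- unique(c("os", .import_roots[[spec$framework]], unlist(lapply(
    c(Filter(function(r) !(r$id %in% spec$violations), req_rules), inj_rules),
    function(r) {
      pats <- r$patterns[1]
      if (grepl(".", pats, fixed = TRUE)) strsplit(pats, ".", fixed = TRUE)[[1]][1]
    }))))
  roots <- setdiff(roots, "")
  lines <- vapply(roots, function(root) {
    if (root %in% names(spec$aliases)) {
      sprintf("import %s as %s", root, spec$aliases[[root]])
    } else {
      sprintf("import %s", root)
    }
  }, "")
  lines <- c(unname(lines), "")

  expected <- list()
  for (r in req_rules) {
    if (r$id %in% spec$violations) {
      expected[[length(expected) + 1L]] <- list(rule_id = r$id, line = 1L)
    } else {
      lines <- c(lines, .satisfier_line(r, spec$aliases))
    }
  }
  lines <- c(lines, "", "model = build_model()", "data = load_data()")
  for (r in inj_rules) {
    lines <- c(lines, .injection_line(r, spec$aliases))
    expected[[length(expected) + 1L]] <- list(rule_id = r$id,
                                              line = length(lines))
  }
  lines <- c(lines, "train(model, data)")

  expected_df <- if (length(expected)) {
    data.frame(rule_id = vapply(expected, `[[`, "", "rule_id"),
               line = vapply(expected, `[[`, 1L, "line"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(rule_id = character(0), line = integer(0))
  }
  list(source = paste(lines, collapse = "\n"), expected = expected_df)
}

#' Sample a random fixture spec
#'
#' Draws a random subset of violatable rules for the framework (including
#' the empty, fully compliant subset) and random import aliases. Driven by
#' R's RNG so sampling is reproducible under `set.seed()`.
#'
#' @param registry A `detml_registry`.
#' @param framework Framework id; sampled uniformly when `NULL`.
#' @return A [fixture_spec()].
#' @export
sample_fixture_spec <- function(registry = load_rules(), framework = NULL) {
  framework <- framework %||%
    sample(setdiff(.framework_ids, "general"), 1L)
  profile <- rule_profile(registry, framework)
  pool <- vapply(c(profile$seed_rules, profile$flag_rules, profile$env_rules,
                   profile$forbidden_rules, profile$discouraged_rules),
                 `[[`, "", "id")
  k <- sample(0:min(3L, length(pool)), 1L)
  violations <- if (k > 0) sample(pool, k) else character(0)
  aliases <- character(0)
  if (stats::runif(1) < 0.5) aliases["numpy"] <- "np"
  if (stats::runif(1) < 0.3) {
    aliases[.import_roots[[framework]][1]] <-
      paste0("m", sample(99L, 1L))
  }
  fixture_spec(framework, violations, aliases)
}

#' Write a fixture corpus to disk
#'
#' Emits each fixture as a `.py` file plus a JSON sidecar of its expected
#' findings (fields `framework`, `violations`, `expected`).
#'
#' @param specs List of [fixture_spec()] objects.
#' @param dir Output directory (created if needed).
#' @param registry A `detml_registry`.
#' @return Character vector of the `.py` paths, invisibly.
#' @export
write_fixture_corpus <- function(specs, dir, registry = load_rules()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(specs))
  for (i in seq_along(specs)) {
    fx <- generate_code_fixture(specs[[i]], registry)
    py <- file.path(dir, sprintf("fixture_%03d.py", i))
    writeLines(fx$source, py)
    jsonlite::write_json(
      list(framework = specs[[i]]$framework,
           violations = specs[[i]]$violations,
           expected = fx$expected),
      file.path(dir, sprintf("fixture_%03d.expected.json", i)),
      auto_unbox = TRUE, digits = NA)
    paths[i] <- py
  }
  invisible(paths)
}
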