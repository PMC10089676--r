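.rule_categories <- c("seed_required", "flag_required", "env_required",
                      "forbidden_call", "discouraged_pattern")
.rule_severities <- c("error", "warning", "info")
.framework_ids <- c("general", "pytorch", "tensorflow", "xgboost")

# import roots whose presence marks a framework as "in use"
.import_roots <- list(
  general = character(0),
  pytorch = "torch",
  tensorflow = "tensorflow",
  xgboost = "xgboost"
)

#' Path to the packaged default ruleset
#' @return Path of the YAML rules file shipped with the package.
#' @export
default_rules_path <- function() {
  system.file("rules", "default_rules.yml", package = "detml", mustWork = TRUE)
}

#' Load a determinism rule registry
#'
#' Reads a YAML rules document (top-level keys `version` and `rules`) and
#' validates it: rule ids must be unique, categories and severities must come
#' from the known enums, every rule needs at least one pattern, and every
#' `forbidden_call` rule needs a non-empty message. The registry is pure
#' data — swapping the rules file changes lint behavior with no code change.
#'
#' @param path Path to a rules YAML file; `NULL` loads the packaged default.
#' @return A `detml_registry` object (list of validated rules plus `version`).
#' @examples
#' reg <- load_rules()
#' length(reg$rules)
#' @export
load_rules <- function(path = NULL) {
  path <- path %||% default_rules_path()
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    detml_stop("cannot read rules file '%s': %s", path, conditionMessage(e),
               class = "detml_schema_error")
  })
  registry_from_list(doc, where = path)
}

# Build and validate a registry from an already-parsed document.
registry_from_list <- function(doc, where = "<document>") {
  if (!is.list(doc) || is.null(doc$rules) && !identical(doc$rules, list())) {
    if (!is.list(doc) || !("rules" %in% names(doc))) {
      detml_stop("rules document '%s' lacks a top-level 'rules' key", where,
                 class = "detml_schema_error")
    }
  }
  rules <- lapply(doc$rules, .validate_rule, where = where)
  ids <- vapply(rules, `[[`, "", "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    detml_stop("duplicate rule id(s) in '%s': %s", where,
               paste(dup, collapse = ", "), class = "detml_validation_error")
  }
  structure(list(rules = rules,
                 version = as.character(doc$version %||% "unversioned")),
            class = "detml_registry")
}

.validate_rule <- function(r, where) {
  label <- r$id %||% "<missing id>"
  need <- c("id", "framework", "category", "patterns", "severity", "message")
  missing <- setdiff(need, names(r))
  if (length(missing)) {
    detml_stop("rule '%s' in '%s' is missing field(s): %s", label, where,
               paste(missing, collapse = ", "), class = "detml_schema_error")
  }
  if (!r$framework %in% .framework_ids) {
    detml_stop("rule '%s': unknown framework '%s' (known: %s)", label,
               r$framework, paste(.framework_ids, collapse = ", "),
               class = "detml_schema_error")
  }
  if (!r$category %in% .rule_categories) {
    detml_stop("rule '%s': unknown category '%s'", label, r$category,
               class = "detml_schema_error")
  }
  if (!r$severity %in% .rule_severities) {
    detml_stop("rule '%s': unknown severity '%s'", label, r$severity,
               class = "detml_schema_error")
  }
  patterns <- as.character(unlist(r$patterns))
  if (!length(patterns) || any(!nzchar(patterns))) {
    detml_stop("rule '%s': patterns must be non-empty", label,
               class = "detml_schema_error")
  }
  msg <- as.character(r$message)
  if (r$category == "forbidden_call" && (!length(msg) || !nzchar(msg))) {
    detml_stop("rule '%s': forbidden_call rules require a non-empty message",
               label, class = "detml_schema_error")
  }
  list(id = as.character(r$id),
       framework = as.character(r$framework),
       category = as.character(r$category),
       patterns = patterns,
       severity = as.character(r$severity),
       message = msg,
       alternative = if (!is.null(r$alternative)) as.character(r$alternative),
       required_value = if (!is.null(r$required_value)) isTRUE(r$required_value))
}

#' Serialize a registry back to YAML
#'
#' Inverse of [load_rules()]: `load_rules(write_rules(reg, f))` is
#' rule-for-rule identical to `reg`.
#'
#' @param registry A `detml_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(registry, path) {
  stopifnot(inherits(registry, "detml_registry"))
  doc <- list(
    version = registry$version,
    rules = lapply(registry$rules, function(r) Filter(Negate(is.null), r))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Look up a rule by id
#' @param registry A `detml_registry`.
#' @param id Rule id string.
#' @return The rule (a list), or an error if absent.
#' @export
rule_by_id <- function(registry, id) {
  for (r in registry$rules) if (r$id == id) return(r)
  detml_stop("no rule with id '%s' in registry", id,
             class = "detml_validation_error")
}

#' Framework profile: the rules applicable to one framework
#'
#' Partitions the registry's rules for `framework` plus the `general` rules
#' into seed/flag/env/forbidden/discouraged groups. The partitions are
#' pairwise disjoint and jointly cover every applicable rule.
#'
#' @param registry A `detml_registry`.
#' @param framework One of `"general"`, `"pytorch"`, `"tensorflow"`,
#'   `"xgboost"`.
#' @return A `detml_profile` list with `framework`, `import_roots`, and the
#'   five rule partitions.
#' @export
rule_profile <- function(registry, framework) {
  stopifnot(inherits(registry, "detml_registry"))
  if (!framework %in% .framework_ids) {
    detml_stop("unknown framework '%s' (known: %s)", framework,
               paste(.framework_ids, collapse = ", "),
               class = "detml_validation_error")
  }
  applicable <- Filter(function(r) r$framework %in% c("general", framework),
                       registry$rules)
  part <- function(cat) Filter(function(r) r$category == cat, applicable)
  structure(list(
    framework = framework,
    import_roots = .import_roots[[framework]],
    seed_rules = part("seed_required"),
    flag_rules = part("flag_required"),
    env_rules = part("env_required"),
    forbidden_rules = part("forbidden_call"),
    discouraged_rules = part("discouraged_pattern")
  ), class = "detml_profile")
}

#' Deterministic alternatives for a symbol
#'
#' Returns the suggested deterministic replacements from every
#' `forbidden_call` rule whose patterns match `symbol`; rules without a
#' stated alternative contribute an explicit "avoid; no deterministic
#' equivalent" marker.
#'
#' @param registry A `detml_registry`.
#' @param symbol Canonical qualified name (post alias resolution).
#' @return Character vector of suggestion texts (possibly empty).
#' @export
alternatives_for <- function(registry, symbol) {
  stopifnot(inherits(registry, "detml_registry"))
  out <- character(0)
  for (r in registry$rules) {
    if (r$category == "forbidden_call" && symbol %in% r$patterns) {
      out <- c(out, r$alternative %||% "avoid; no deterministic equivalent")
    }
  }
  out
}

#' @export
print.detml_registry <- function(x, ...) {
  cat("<detml rule registry> version ", x$version, ", ",
      length(x$rules), " rules\n", sep = "")
  if (length(x$rules)) {
    fw <- vapply(x$rules, `[[`, "", "framework")
    print(table(framework = fw))
  }
  invisible(x)
}
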