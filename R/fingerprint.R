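.manifest_schema_version <- "1"
.manifest_fields <- c("schema_version", "os_name", "os_version", "cpu_model",
                      "logical_cores", "accelerators", "runtime_version",
                      "packages", "devices_used", "in_container",
                      "container_image", "timestamp", "digest")
.manifest_hw_fields <- c("cpu_model", "logical_cores", "accelerators")
.manifest_sw_fields <- c("os_name", "os_version", "runtime_version", "packages")

#' Fingerprint probe configuration
#'
#' @param packages Package names whose versions are recorded (uninstalled
#'   ones degrade to `"unknown"`, never fail).
#' @param devices_used Caller-supplied annotation of the devices actually
#'   used for the run (visible devices are probed separately, since tools
#'   that log only *available* hardware miss what was actually exercised).
#' @param container_image Optional container image identifier supplied by
#'   configuration; containerization itself is infrastructure, only the
#'   identity is recorded.
#' @return A `detml_fingerprint_config`.
#' @export
fingerprint_config <- function(packages = c("detml", "jsonlite", "yaml"),
                               devices_used = "cpu",
                               container_image = NULL) {
  structure(list(packages = packages, devices_used = devices_used,
                 container_image = container_image),
            class = "detml_fingerprint_config")
}

.probe_cpu_model <- function() {
  out <- tryCatch({
    if (file.exists("/proc/cpuinfo")) {
      ln <- grep("^model name", readLines("/proc/cpuinfo", warn = FALSE),
                 value = TRUE)
      if (length(ln)) trimws(sub("^[^:]*:", "", ln[1])) else "unknown"
    } else "unknown"
  }, error = function(e) "unknown")
  if (!nzchar(out)) "unknown" else out
}

.probe_accelerators <- function() {
  tryCatch({
    smi <- Sys.which("nvidia-smi")
    if (!nzchar(smi)) return(list())
    out <- suppressWarnings(system2(
      smi, c("--query-gpu=name,driver_version", "--format=csv,noheader"),
      stdout = TRUE, stderr = FALSE))
    if (!length(out) || !is.null(attr(out, "status"))) return(list())
    tab <- table(out)
    lapply(names(tab), function(k) {
      parts <- trimws(strsplit(k, ",")[[1]])
      list(model = parts[1], count = as.integer(tab[[k]]),
           driver_version = if (length(parts) > 1) parts[2] else "unknown",
           compute_platform = "unknown")
    })
  }, error = function(e) list())
}

#' Collect a hardware/software provenance manifest
#'
#' Read-only collection of the system state relevant to reproducing a run:
#' OS, CPU model and logical core count, visible accelerators (empty list
#' when none), the R runtime version and configured package versions.
#' Absent probes degrade to `"unknown"` — collection never fails. The
#' digest covers every field except the timestamp (and itself), so
#' collecting twice on one machine yields equal digests.
#'
#' @param config A [fingerprint_config()].
#' @return A `detml_manifest`.
#' @export
collect_manifest <- function(config = fingerprint_config()) {
  si <- Sys.info()
  pkgs <- lapply(stats::setNames(config$packages, config$packages), function(p) {
    tryCatch(as.character(utils::packageVersion(p)),
             error = function(e) "unknown")
  })
  m <- list(
    schema_version = .manifest_schema_version,
    os_name = unname(si[["sysname"]]) %||% "unknown",
    os_version = unname(si[["release"]]) %||% "unknown",
    cpu_model = .probe_cpu_model(),
    logical_cores = tryCatch({
      n <- parallel::detectCores(logical = TRUE)
      if (is.na(n)) "unknown" else as.integer(n)
    }, error = function(e) "unknown"),
    accelerators = .probe_accelerators(),
    runtime_version = R.version.string,
    packages = pkgs,
    devices_used = config$devices_used,
    in_container = file.exists("/.dockerenv") ||
      file.exists("/run/.containerenv"),
    container_image = config$container_image %||% "unknown",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    digest = NA_character_
  )
  m$digest <- manifest_digest(m)
  structure(m, class = "detml_manifest")
}

#' Digest of a manifest's identity fields
#'
#' md5 over the canonical JSON serialization of every field except
#' `timestamp` and `digest`; stable under timestamp change and recomputable
#' from a parsed document.
#'
#' @param manifest A `detml_manifest` (or plain list with the same fields).
#' @return Hex digest string.
#' @export
manifest_digest <- function(manifest) {
  fields <- setdiff(.manifest_fields, c("timestamp", "digest"))
  body <- manifest[fields]
  string_digest(as.character(jsonlite::toJSON(body, auto_unbox = TRUE,
                                              null = "null", digits = NA)))
}

#' Scoped manifest equality
#'
#' `hardware` compares the CPU (model, logical cores) and accelerators
#' only; `software` compares the OS, runtime and package versions; `full`
#' compares both. The diff lists every unequal field in scope.
#'
#' @param a,b Manifests with the same schema version.
#' @param scope `"hardware"`, `"software"` or `"full"`.
#' @return `list(equal = logical, diff = character vector of field names)`.
#' @export
manifests_equal <- function(a, b, scope = c("hardware", "software", "full")) {
  scope <- match.arg(scope)
  if (!identical(a$schema_version, b$schema_version)) {
    detml_stop("manifest schema versions differ ('%s' vs '%s')",
               a$schema_version, b$schema_version,
               class = "detml_schema_error")
  }
  fields <- switch(scope,
                   hardware = .manifest_hw_fields,
                   software = .manifest_sw_fields,
                   full = c(.manifest_hw_fields, .manifest_sw_fields))
  diff <- fields[!vapply(fields, function(f) identical(a[[f]], b[[f]]),
                         logical(1))]
  list(equal = length(diff) == 0L, diff = unname(diff))
}

#' Write a manifest as JSON
#'
#' Serialization has stable key order and round-trips exactly:
#' `read_manifest(write_manifest(m, f))` equals `m` including the digest.
#'
#' @param manifest A `detml_manifest`.
#' @param path Output path (or connection for stdout).
#' @return `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  writeLines(manifest_json(manifest), path)
  invisible(path)
}

#' @rdname write_manifest
#' @return `manifest_json()` returns the JSON text.
#' @export
manifest_json <- function(manifest) {
  as.character(jsonlite::toJSON(manifest[.manifest_fields], auto_unbox = TRUE,
                                null = "null", digits = NA, pretty = TRUE))
}

#' Parse a manifest JSON document
#'
#' Validates that every schema field is present (value `"unknown"` is
#' allowed, absence is not) and that the stored digest matches the
#' recomputed one.
#'
#' @param path Path to a JSON manifest (or JSON text via `text`).
#' @param text JSON text, overrides `path`.
#' @param verify_digest Recompute and compare the digest (default TRUE).
#' @return A `detml_manifest`.
#' @export
read_manifest <- function(path = NULL, text = NULL, verify_digest = TRUE) {
  raw <- text %||% paste(readLines(path, warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(raw, simplifyVector = FALSE)
  missing <- setdiff(.manifest_fields, names(doc))
  if (length(missing)) {
    detml_stop("manifest document missing required field(s): %s",
               paste(missing, collapse = ", "), class = "detml_schema_error")
  }
  m <- doc[.manifest_fields]
  if (is.numeric(m$logical_cores)) m$logical_cores <- as.integer(m$logical_cores)
  m$accelerators <- lapply(m$accelerators, function(acc) {
    if (!is.null(acc$count)) acc$count <- as.integer(acc$count)
    acc
  })
  if (verify_digest && !identical(manifest_digest(m), m$digest)) {
    detml_stop("manifest digest mismatch: document was altered or corrupted",
               class = "detml_schema_error")
  }
  structure(m, class = "detml_manifest")
}

#' @export
print.detml_manifest <- function(x, ...) {
  cat("<detml system manifest>\n")
  cat("  ", x$os_name, x$os_version, "|", x$cpu_model,
      sprintf("(%s cores)", x$logical_cores), "\n")
  cat("  accelerators:", if (length(x$accelerators))
    paste(vapply(x$accelerators, function(a)
      sprintf("%dx %s", a$count, a$model), ""), collapse = ", ")
    else "none", "\n")
  cat("  digest:", x$digest, "\n")
  invisible(x)
}
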