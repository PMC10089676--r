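.run_modes <- c("random", "seeds", "deterministic")

#' Describe one experimental setup
#'
#' The three setups mirror the standard determinism-evaluation protocol:
#' `random` (no seeds set), `seeds` (all library RNG seeds plus the hash
#' seed fixed) and `deterministic` (seeds plus enforced deterministic
#' algorithms, disabled benchmark selection and the required environment
#' variables).
#'
#' @param mode One of `"random"`, `"seeds"`, `"deterministic"`.
#' @param seed Integer seed (ignored for `mode = "random"`, required
#'   otherwise; default 0).
#' @param frameworks Subset of `c("pytorch", "tensorflow", "xgboost")` in
#'   scope for the settings plan.
#' @param device_profile Opaque provenance label; the toy trainer
#'   understands `"cpu"` and `"gpu-sim"` (simulated atomic-add scheduling).
#' @return A `detml_run_setting`.
#' @export
run_setting <- function(mode, seed = 0L, frameworks = character(0),
                        device_profile = "cpu") {
  if (!mode %in% .run_modes) {
    detml_stop("mode must be one of %s", paste(.run_modes, collapse = ", "),
               class = "detml_validation_error")
  }
  unknown <- setdiff(frameworks, setdiff(.framework_ids, "general"))
  if (length(unknown)) {
    detml_stop("unknown framework(s): %s", paste(unknown, collapse = ", "),
               class = "detml_validation_error")
  }
  if (mode != "random" && (is.null(seed) || is.na(seed))) {
    detml_stop("seed required for mode '%s'", mode,
               class = "detml_validation_error")
  }
  structure(list(mode = mode, seed = as.integer(seed),
                 frameworks = sort(unique(frameworks)),
                 device_profile = device_profile),
            class = "detml_run_setting")
}

.plan_action <- function(action, target, value = NULL) {
  list(action = action, target = target, value = value)
}

#' Build the settings plan for a run setting
#'
#' Translates a [run_setting()] into the ordered list of concrete actions a
#' framework adapter would apply before training:
#'
#' * `random`: empty plan — nothing is configured.
#' * `seeds`: `set-seed` actions for Python's random module, NumPy and the
#'   Python hash seed, plus one per framework in scope.
#' * `deterministic`: the seeds plan plus, per framework: the
#'   `TF_DETERMINISTIC_OPS` environment variable (TensorFlow); cuDNN
#'   benchmark off, deterministic algorithms on and
#'   `CUBLAS_WORKSPACE_CONFIG=:4096:8` (PyTorch); the
#'   `single_precision_histogram` option and avoidance of `allreduce`
#'   (XGBoost).
#'
#' The deterministic plan is always a strict superset of the seeds plan for
#' the same seed and frameworks.
#'
#' @param setting A `detml_run_setting`.
#' @return A `detml_settings_plan`: list of actions, each with fields
#'   `action` (`set_seed`, `set_env`, `set_flag`, `avoid`), `target`,
#'   `value`.
#' @export
build_settings_plan <- function(setting) {
  stopifnot(inherits(setting, "detml_run_setting"))
  plan <- list()
  if (setting$mode == "random") {
    return(structure(plan, class = "detml_settings_plan"))
  }
  seed <- setting$seed
  plan <- c(plan, list(
    .plan_action("set_seed", "python.random", seed),
    .plan_action("set_seed", "numpy", seed),
    .plan_action("set_seed", "python.hashseed", seed)
  ))
  for (fw in setting$frameworks) {
    plan <- c(plan, list(.plan_action("set_seed", fw, seed)))
  }
  if (setting$mode == "deterministic") {
    for (fw in setting$frameworks) {
      plan <- c(plan, switch(
        fw,
        tensorflow = list(
          .plan_action("set_env", "TF_DETERMINISTIC_OPS", "1")),
        pytorch = list(
          .plan_action("set_flag", "torch.backends.cudnn.benchmark", FALSE),
          .plan_action("set_flag", "torch.use_deterministic_algorithms", TRUE),
          .plan_action("set_env", "CUBLAS_WORKSPACE_CONFIG", ":4096:8")),
        xgboost = list(
          .plan_action("set_flag", "single_precision_histogram", TRUE),
          .plan_action("avoid", "xgboost.rabit.allreduce"))
      ))
    }
  }
  structure(plan, class = "detml_settings_plan")
}

#' Execute repeated training runs under one setting
#'
#' Builds the settings plan once, then invokes the trainer once per run in
#' run order. The trainer must conform to the training contract:
#' `trainer(plan, setting, epochs)` returning `list(trajectory, params)`
#' with a numeric trajectory of length `epochs` and a numeric (or raw)
#' parameter vector. Fresh state between runs is the trainer's
#' responsibility. Each record carries the digest of the canonical
#' little-endian byte serialization of the parameters and the current
#' system manifest digest.
#'
#' @param trainer A training-contract function (e.g. [make_toy_trainer()]).
#' @param setting A [run_setting()].
#' @param n_runs Number of repetitions (>= 2; default 5).
#' @param epochs Epochs per run.
#' @param manifest Optional [collect_manifest()] result; collected once if
#'   `NULL`.
#' @return List of `detml_run_record` objects.
#' @export
execute_runs <- function(trainer, setting, n_runs = 5L, epochs = 25L,
                         manifest = NULL) {
  stopifnot(is.function(trainer), inherits(setting, "detml_run_setting"))
  if (n_runs < 2L) {
    detml_stop("n_runs must be >= 2: determinism cannot be assessed from one run",
               class = "detml_validation_error")
  }
  plan <- build_settings_plan(setting)
  manifest <- manifest %||% collect_manifest()
  records <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(trainer(plan, setting, epochs), error = function(e) e)
    if (inherits(res, "error")) {
      detml_stop("trainer failed on run %d/%d: %s", i, n_runs,
                 conditionMessage(res), class = "detml_trainer_error")
    }
    if (!is.numeric(res$trajectory) || length(res$trajectory) != epochs) {
      detml_stop("trainer contract violated on run %d: trajectory length %d != epochs %d",
                 i, length(res$trajectory), epochs,
                 class = "detml_trainer_error")
    }
    bytes <- serialize_params(res$params)
    params_num <- if (is.raw(res$params)) {
      readBin(res$params, "double", n = length(res$params) %/% 8L,
              endian = "little")
    } else as.double(res$params)
    records[[i]] <- structure(list(
      run = i,
      setting = setting,
      final_metric = res$trajectory[[epochs]],
      trajectory = res$trajectory,
      param_digest = raw_digest(bytes),
      param_summary = c(mean = mean(params_num),
                        sd = stats::sd(params_num)),
      manifest_digest = manifest$digest,
      wall_time = proc.time()[["elapsed"]] - t0
    ), class = "detml_run_record")
  }
  records
}

#' Classify a set of runs as bit-exact deterministic or not
#'
#' Bit-exactness requires a single distinct parameter digest, exactly zero
#' maximum absolute pairwise difference of the final metric, zero across-run
#' standard deviation at every epoch, and identical trajectories —
#' comparisons are on full-precision values and raw digests, never on
#' rounded displays. The verdict is invariant to the order of the records.
#'
#' @param records List of `detml_run_record` from one setting.
#' @return A `detml_verdict`: `n_runs`, `bit_exact`, `distinct_digests`,
#'   `max_abs_diff`, `per_epoch_std`, `classification`
#'   (`"deterministic"` or `"nondeterministic"`).
#' @export
assess_determinism <- function(records) {
  if (length(records) < 2L) {
    detml_stop("need >= 2 records", class = "detml_validation_error")
  }
  keys <- vapply(records, function(r) {
    paste(r$setting$mode, r$setting$seed, r$setting$device_profile,
          paste(r$setting$frameworks, collapse = "+"))
  }, "")
  if (length(unique(keys)) != 1L) {
    detml_stop("records mix different settings: %s",
               paste(unique(keys), collapse = " | "),
               class = "detml_validation_error")
  }
  finals <- vapply(records, `[[`, 0, "final_metric")
  digests <- vapply(records, `[[`, "", "param_digest")
  trajs <- do.call(rbind, lapply(records, `[[`, "trajectory"))
  max_diff <- max(abs(outer(finals, finals, "-")))
  per_epoch_std <- apply(trajs, 2L, stats::sd)
  trajs_identical <- all(apply(trajs, 2L, function(col) {
    all(col == col[1L])
  }))
  bit_exact <- length(unique(digests)) == 1L && max_diff == 0 &&
    all(per_epoch_std == 0) && trajs_identical
  structure(list(
    n_runs = length(records),
    bit_exact = bit_exact,
    distinct_digests = length(unique(digests)),
    max_abs_diff = max_diff,
    per_epoch_std = per_epoch_std,
    classification = if (bit_exact) "deterministic" else "nondeterministic"
  ), class = "detml_verdict")
}

#' Compare bit-exact results between two systems
#'
#' Both record sets must individually be bit-exact (within-system
#' determinism is a prerequisite for a cross-system statement). The report
#' states whether the two systems produced bit-identical results and
#' whether their manifests are hardware-equal; the expectation (same
#' hardware should reproduce, different hardware may differ) is advisory
#' text, never a hard failure.
#'
#' @param records_a,records_b Bit-exact record sets from the two systems.
#' @param manifest_a,manifest_b The systems' [collect_manifest()] results.
#' @return A `detml_cross_system_report` with `results_equal`,
#'   `hardware_equal`, `hardware_diff`, `status` and `advisory`.
#' @export
compare_systems <- function(records_a, records_b, manifest_a, manifest_b) {
  va <- assess_determinism(records_a)
  vb <- assess_determinism(records_b)
  if (!va$bit_exact || !vb$bit_exact) {
    detml_stop("cross-system comparison requires bit-exact inputs (got %s / %s)",
               va$classification, vb$classification,
               class = "detml_validation_error")
  }
  results_equal <-
    identical(records_a[[1]]$param_digest, records_b[[1]]$param_digest) &&
    identical(records_a[[1]]$trajectory, records_b[[1]]$trajectory)
  hw <- manifests_equal(manifest_a, manifest_b, scope = "hardware")
  status <- if (hw$equal && results_equal) {
    "reproduced on equivalent hardware"
  } else if (!hw$equal && !results_equal) {
    "hardware-attributable difference"
  } else if (hw$equal && !results_equal) {
    "unexplained divergence"
  } else {
    "reproduced across differing hardware"
  }
  advisory <- if (hw$equal) {
    "same hardware: bit-identical results expected"
  } else {
    "different hardware: results may legitimately differ; record both manifests"
  }
  structure(list(results_equal = results_equal, hardware_equal = hw$equal,
                 hardware_diff = hw$diff, status = status,
                 advisory = advisory),
            class = "detml_cross_system_report")
}

#' @export
print.detml_verdict <- function(x, ...) {
  cat(sprintf("<detml verdict> %s over %d runs\n", x$classification, x$n_runs))
  cat(sprintf("  distinct parameter digests: %d\n", x$distinct_digests))
  cat(sprintf("  max |final metric diff|: %.17g\n", x$max_abs_diff))
  invisible(x)
}

#' @export
print.detml_cross_system_report <- function(x, ...) {
  cat("<detml cross-system report>", x$status, "\n  ", x$advisory, "\n")
  invisible(x)
}
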