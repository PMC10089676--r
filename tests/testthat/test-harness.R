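test_that("settings plans encode the three setups", {
  # random: nothing configured
  expect_length(build_settings_plan(run_setting("random",
                                                frameworks = "tensorflow")), 0)

  # seeds with no frameworks: exactly the three general seed actions
  plan <- build_settings_plan(run_setting("seeds", 0))
  expect_length(plan, 3)
  expect_true(all(vapply(plan, `[[`, "", "action") == "set_seed"))
  expect_setequal(vapply(plan, `[[`, "", "target"),
                  c("python.random", "numpy", "python.hashseed"))

  # seeds adds one set-seed per framework in scope
  plan2 <- build_settings_plan(run_setting("seeds", 0, "pytorch"))
  expect_length(plan2, 4)
  expect_true("pytorch" %in% vapply(plan2, `[[`, "", "target"))
})

plan_keys <- function(plan) {
  vapply(plan, function(a) paste(a$action, a$target, a$value), "")
}

test_that("deterministic plans are supersets of seeds plans with the framework actions", {
  for (fw in c("pytorch", "tensorflow", "xgboost")) {
    seeds <- build_settings_plan(run_setting("seeds", 0, fw))
    det <- build_settings_plan(run_setting("deterministic", 0, fw))
    # element-wise superset, and strict
    expect_true(all(plan_keys(seeds) %in% plan_keys(det)), label = fw)
    expect_gt(length(det), length(seeds))
  }
  det_tf <- plan_keys(build_settings_plan(
    run_setting("deterministic", 0, "tensorflow")))
  expect_true("set_env TF_DETERMINISTIC_OPS 1" %in% det_tf)

  det_pt <- plan_keys(build_settings_plan(
    run_setting("deterministic", 0, "pytorch")))
  expect_true("set_flag torch.backends.cudnn.benchmark FALSE" %in% det_pt)
  expect_true("set_env CUBLAS_WORKSPACE_CONFIG :4096:8" %in% det_pt)

  det_xgb <- plan_keys(build_settings_plan(
    run_setting("deterministic", 0, "xgboost")))
  expect_true("set_flag single_precision_histogram TRUE" %in% det_xgb)
  expect_true(any(grepl("^avoid xgboost.rabit.allreduce", det_xgb)))
})

test_that("run settings validate their inputs", {
  expect_error(run_setting("chaotic"), class = "detml_validation_error")
  expect_error(run_setting("seeds", frameworks = "mxnet"),
               class = "detml_validation_error")
  expect_error(run_setting("seeds", seed = NA),
               class = "detml_validation_error")
})

test_that("execute_runs returns ordered records honoring the contract", {
  task <- make_toy_task(50, 3, 0.1, 1)
  tr <- make_toy_trainer(task)
  recs <- execute_runs(tr, run_setting("deterministic", 0), n_runs = 3,
                       epochs = 10)
  expect_length(recs, 3)
  expect_equal(vapply(recs, `[[`, 0L, "run"), 1:3)
  expect_true(all(vapply(recs, function(r) length(r$trajectory), 0L) == 10L))
  digests <- vapply(recs, `[[`, "", "param_digest")
  expect_length(unique(digests), 1)
  expect_length(unique(vapply(recs, `[[`, "", "manifest_digest")), 1)

  expect_error(execute_runs(tr, run_setting("deterministic", 0), n_runs = 1,
                            epochs = 5),
               class = "detml_validation_error")
  broken <- function(plan, setting, epochs) stop("boom")
  expect_error(execute_runs(broken, run_setting("deterministic", 0),
                            n_runs = 2, epochs = 5),
               class = "detml_trainer_error")
})

make_record <- function(final, params, mode = "seeds", traj = NULL) {
  structure(list(
    run = 1L,
    setting = run_setting(mode, 0),
    final_metric = final,
    trajectory = traj %||% c(1, final),
    param_digest = detml:::raw_digest(detml:::serialize_params(params)),
    param_summary = c(mean = mean(params), sd = sd(params)),
    manifest_digest = "m", wall_time = 0
  ), class = "detml_run_record")
}

test_that("verdict logic covers all digest/metric combinations", {
  p <- c(0.1, 0.2)
  # identical records: bit-exact
  v <- assess_determinism(list(make_record(0.5, p), make_record(0.5, p),
                               make_record(0.5, p)))
  expect_true(v$bit_exact)
  expect_identical(v$max_abs_diff, 0)
  expect_equal(v$distinct_digests, 1)
  expect_equal(v$classification, "deterministic")

  # metrics differ in the 7th decimal: not bit-exact
  v2 <- assess_determinism(list(make_record(0.5, p),
                                make_record(0.5000001, p)))
  expect_false(v2$bit_exact)
  expect_equal(v2$max_abs_diff, 1e-7, tolerance = 1e-9)
  expect_equal(v2$classification, "nondeterministic")

  # identical metrics but one parameter byte differs: digests split
  p_perturbed <- p
  p_perturbed[2] <- p_perturbed[2] + 2^-50
  v3 <- assess_determinism(list(
    make_record(0.5, p, traj = c(1, 0.5)),
    make_record(0.5, p_perturbed, traj = c(1, 0.5))))
  expect_false(v3$bit_exact)
  expect_equal(v3$distinct_digests, 2)
  expect_identical(v3$max_abs_diff, 0)

  # metrics and digests differ
  v4 <- assess_determinism(list(make_record(0.4, p),
                                make_record(0.6, p_perturbed)))
  expect_false(v4$bit_exact)
  expect_equal(v4$distinct_digests, 2)
})

test_that("verdicts are invariant to record order and duplication count", {
  p <- c(1, 2, 3)
  recs <- list(make_record(0.3, p), make_record(0.31, p + 1e-9),
               make_record(0.3, p))
  v_fwd <- assess_determinism(recs)
  v_rev <- assess_determinism(rev(recs))
  expect_equal(v_fwd$bit_exact, v_rev$bit_exact)
  expect_equal(v_fwd$distinct_digests, v_rev$distinct_digests)
  expect_identical(v_fwd$max_abs_diff, v_rev$max_abs_diff)

  for (k in c(2, 5, 9)) {
    vk <- assess_determinism(rep(list(make_record(0.5, p)), k))
    expect_true(vk$bit_exact)
    expect_equal(vk$n_runs, k)
  }
})

test_that("mixed settings and single records are rejected", {
  p <- c(1, 2)
  expect_error(assess_determinism(list(make_record(0.5, p))),
               class = "detml_validation_error")
  expect_error(
    assess_determinism(list(make_record(0.5, p, mode = "seeds"),
                            make_record(0.5, p, mode = "random"))),
    class = "detml_validation_error")
})

test_that("per-epoch std agrees with a brute-force two-pass computation", {
  task <- make_toy_task(60, 3, 0.1, 2)
  tr <- make_toy_trainer(task)
  recs <- execute_runs(tr, run_setting("seeds", 0, device_profile = "gpu-sim"),
                       n_runs = 5, epochs = 20)
  v <- assess_determinism(recs)
  trajs <- do.call(rbind, lapply(recs, `[[`, "trajectory"))
  brute <- apply(trajs, 2, function(col) {
    m <- sum(col) / length(col)
    sqrt(sum((col - m)^2) / (length(col) - 1))
  })
  expect_equal(v$per_epoch_std, brute, tolerance = 1e-15)
})

test_that("cross-system comparison distinguishes the hardware/results combinations", {
  task <- make_toy_task(50, 3, 0.1, 1)
  tr <- make_toy_trainer(task)
  s <- run_setting("deterministic", 0)
  m1 <- collect_manifest()
  recs_a <- execute_runs(tr, s, n_runs = 2, epochs = 10, manifest = m1)
  recs_b <- execute_runs(tr, s, n_runs = 2, epochs = 10, manifest = m1)

  # identical results + identical manifests
  rep1 <- compare_systems(recs_a, recs_b, m1, m1)
  expect_true(rep1$results_equal)
  expect_equal(rep1$status, "reproduced on equivalent hardware")

  # differing results + differing hardware manifests
  m2 <- m1
  m2$cpu_model <- "Other CPU Model X"
  m2$digest <- manifest_digest(m2)
  tr2 <- make_toy_trainer(make_toy_task(50, 3, 0.1, 99))
  recs_c <- execute_runs(tr2, s, n_runs = 2, epochs = 10, manifest = m2)
  rep2 <- compare_systems(recs_a, recs_c, m1, m2)
  expect_false(rep2$results_equal)
  expect_equal(rep2$status, "hardware-attributable difference")

  # differing results + identical manifests: unexplained divergence
  rep3 <- compare_systems(recs_a, recs_c, m1, m1)
  expect_equal(rep3$status, "unexplained divergence")

  # non-bit-exact inputs are a precondition error
  noisy <- execute_runs(tr, run_setting("random"), n_runs = 2, epochs = 10,
                        manifest = m1)
  expect_error(compare_systems(noisy, recs_b, m1, m1),
               class = "detml_validation_error")
})
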