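reg <- load_rules()

test_that("framework detection follows import roots", {
  expect_length(detect_frameworks(parse_python_source(""), reg), 0)
  expect_equal(detect_frameworks(parse_python_source("import xgboost"), reg),
               "xgboost")
  both <- detect_frameworks(
    parse_python_source("import torch\nimport tensorflow as tf"), reg)
  expect_setequal(both, c("pytorch", "tensorflow"))
  # importing an unrelated package detects nothing
  expect_length(detect_frameworks(parse_python_source("import pandas"), reg), 0)
})

test_that("seed findings are exactly the unsatisfied seed rules", {
  profile <- rule_profile(reg, "tensorflow")
  compliant <- paste(
    "import os, random",
    "import numpy, tensorflow",
    "random.seed(0)",
    "numpy.random.seed(0)",
    'os.environ["PYTHONHASHSEED"] = "0"',
    "tensorflow.random.set_seed(0)",
    sep = "\n")
  m <- parse_python_source(compliant)
  expect_length(check_seed_requirements(m, profile), 0)

  # only the numpy seed set: set-difference oracle against the rules data
  m2 <- parse_python_source("import numpy, tensorflow\nnumpy.random.seed(0)")
  found <- vapply(check_seed_requirements(m2, profile), `[[`, "", "rule_id")
  all_seed_ids <- vapply(profile$seed_rules, `[[`, "", "id")
  expect_setequal(found, setdiff(all_seed_ids, "SEED-NUMPY"))
  expect_length(found, length(all_seed_ids) - 1L)
})

test_that("hash seed is satisfiable by an environment write in code", {
  rep <- lint_file(text = paste(
    "import os, random, numpy, tensorflow",
    "random.seed(0)",
    "numpy.random.seed(0)",
    'os.environ["PYTHONHASHSEED"] = "0"',
    "tensorflow.random.set_seed(0)",
    'os.environ["TF_DETERMINISTIC_OPS"] = "1"',
    sep = "\n"), registry = reg)
  expect_false("SEED-HASH" %in% findings_df(rep)$rule_id)
  expect_true(rep$passed)
})

test_that("determinism flags: env writes satisfy, truthy benchmark fires at its line", {
  profile <- rule_profile(reg, "tensorflow")
  m <- parse_python_source(
    'import os, tensorflow\nos.environ["TF_DETERMINISTIC_OPS"] = "1"')
  ids <- vapply(check_determinism_enforcement(m, profile), `[[`, "", "rule_id")
  expect_false("FLAG-TF-DETERMINISM" %in% ids)

  pt <- rule_profile(reg, "pytorch")
  m2 <- parse_python_source(paste(
    "import torch",
    "torch.use_deterministic_algorithms(True)",
    "torch.backends.cudnn.benchmark = True",
    sep = "\n"))
  f2 <- check_determinism_enforcement(m2, pt)
  bench <- Filter(function(f) f$rule_id == "FLAG-CUDNN-BENCHMARK", f2)
  expect_length(bench, 1)
  expect_equal(bench[[1]]$line, 3L)
  expect_equal(bench[[1]]$severity, "error")

  # missing workspace-config env var is reported
  expect_true("ENV-CUBLAS-WORKSPACE" %in% vapply(f2, `[[`, "", "rule_id"))
})

test_that("forbidden and discouraged calls yield line-ordered findings", {
  pt <- rule_profile(reg, "pytorch")
  m <- parse_python_source(paste(
    "import torch",
    "a = 1",
    "b = 2",
    "c = 3",
    "y = torch.nn.functional.conv3d(x, w)",
    "d = 4",
    "e = 5",
    "f = 6",
    "z = torch.nn.functional.conv3d(x2, w2)",
    sep = "\n"))
  f <- check_forbidden_calls(m, pt)
  expect_length(f, 2)
  expect_equal(vapply(f, `[[`, 1L, "line"), c(5L, 9L))
  expect_equal(unique(vapply(f, `[[`, "", "rule_id")), "FORBID-CONV3D")

  # a dask cluster in xgboost code draws the multi-worker warning
  xg <- rule_profile(reg, "xgboost")
  m2 <- parse_python_source(paste(
    "import xgboost",
    "import dask.distributed",
    "client = dask.distributed.Client()",
    "out = xgboost.dask.train(client, params, data)",
    sep = "\n"))
  f2 <- check_forbidden_calls(m2, xg)
  ids <- vapply(f2, `[[`, "", "rule_id")
  expect_true("DISC-MULTI-WORKER" %in% ids)
  expect_true("DISC-XGB-MULTI-GPU" %in% ids)
  sev <- vapply(f2, `[[`, "", "severity")
  expect_true(all(sev == "warning"))
})

test_that("lint_file aggregates checks and applies the pass invariant", {
  # no ML imports: vacuous pass, no frameworks
  rep <- lint_file(text = "import os\nprint(os.getcwd())", registry = reg)
  expect_true(rep$passed)
  expect_length(rep$frameworks, 0)
  expect_length(rep$findings, 0)

  # counts sum to findings length; passed iff zero errors
  rep2 <- lint_file(text = "import torch\n", registry = reg)
  expect_equal(sum(rep2$counts), length(rep2$findings))
  expect_false(rep2$passed)
  expect_gt(rep2$counts[["error"]], 0)

  expect_error(lint_file(path = "/no/such/file.py"), class = "detml_io_error")
})

test_that("lint output is deterministic: identical bytes give identical reports", {
  fx <- generate_code_fixture(
    fixture_spec("pytorch", violations = c("SEED-NUMPY", "FORBID-CONV3D")),
    reg)
  r1 <- render_report(lint_file(text = fx$source, registry = reg), "json")
  r2 <- render_report(lint_file(text = fx$source, registry = reg), "json")
  expect_identical(r1, r2)
})

test_that("adding a violation never decreases the finding count", {
  base <- generate_code_fixture(fixture_spec("tensorflow"), reg)$source
  n0 <- length(lint_file(text = base, registry = reg)$findings)
  worse <- paste(base, "y = tensorflow.nn.conv3d(x, w)", sep = "\n")
  n1 <- length(lint_file(text = worse, registry = reg)$findings)
  expect_gte(n1, n0)
  expect_equal(n1, n0 + 1L)
  # removing all content yields zero findings
  expect_length(lint_file(text = "", registry = reg)$findings, 0)
})

test_that("alias choice does not change findings", {
  set.seed(7)
  for (alias in c("np", "xyz", paste0("m", sample(1000, 3)))) {
    plain <- generate_code_fixture(
      fixture_spec("pytorch", violations = "SEED-PYTHON-RANDOM"), reg)
    aliased <- generate_code_fixture(
      fixture_spec("pytorch", violations = "SEED-PYTHON-RANDOM",
                   aliases = c(numpy = alias, torch = "T")), reg)
    fp <- findings_df(lint_file(text = plain$source, registry = reg))
    fa <- findings_df(lint_file(text = aliased$source, registry = reg))
    expect_equal(fa, fp, label = alias)
  }
})

test_that("severity overrides and ignore lists reshape the report", {
  fx <- generate_code_fixture(
    fixture_spec("pytorch", violations = "SEED-NUMPY"), reg)
  cfg <- lint_config(ignore = "SEED-NUMPY")
  expect_true(lint_file(text = fx$source, registry = reg, config = cfg)$passed)

  cfg2 <- lint_config(severity_overrides = c("SEED-NUMPY" = "warning"))
  rep2 <- lint_file(text = fx$source, registry = reg, config = cfg2)
  expect_true(rep2$passed)
  expect_equal(rep2$counts[["warning"]], 1L)
  expect_error(lint_config(severity_overrides = c(X = "fatal")),
               class = "detml_config_error")
})

test_that("lint_project merges per-file reports over include/exclude globs", {
  root <- withr::local_tempdir()
  good <- generate_code_fixture(fixture_spec("tensorflow"), reg)$source
  bad <- generate_code_fixture(
    fixture_spec("tensorflow", violations = "SEED-TENSORFLOW"), reg)$source
  dir.create(file.path(root, "src"))
  writeLines(good, file.path(root, "src", "good.py"))
  writeLines(bad, file.path(root, "src", "bad.py"))
  writeLines("not python", file.path(root, "README.md"))

  rep <- lint_project(root, reg)
  expect_false(rep$passed)
  expect_length(rep$sources, 2)
  expect_equal(findings_df(rep)$rule_id, "SEED-TENSORFLOW")

  rep2 <- lint_project(root, reg, lint_config(exclude = "bad.py"))
  expect_true(rep2$passed)

  empty <- withr::local_tempdir()
  rep3 <- lint_project(empty, reg)
  expect_true(rep3$passed)
  expect_length(rep3$sources, 0)
  expect_match(rep3$notice, "no matching")
})
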