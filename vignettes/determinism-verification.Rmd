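---
title: "Verifying determinism in machine-learning code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying determinism in machine-learning code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detml)
```

## Why bit-exactness, and why seeding is not enough

Deterministic machine learning means that retraining a model on the same
data and the same computational infrastructure reproduces the *bit-exact*
same metrics and parameters. Fixing every random seed is necessary but not
sufficient: the major ML frameworks default to GPU kernels built on atomic
read-modify-write operations, whose scheduling order across parallel
threads is not reproducible. Because floating-point addition is not
associative, a sum reduced in a different order is a different double, and
across thousands of kernel launches these rounding differences accumulate
into visibly different losses, weights and predictions.

`detml` packages the resulting engineering discipline into four verifiable
pieces:

1. a **static analyzer** that checks Python ML sources against a
   data-driven rule set (seeds present, determinism flags enforced, known
   nondeterministic operations avoided);
2. a **runtime harness** that executes a training procedure repeatedly
   under the three canonical setups — *random* (nothing fixed), *seeds*
   (all RNG seeds fixed) and *deterministic* (seeds plus enforced
   deterministic algorithms) — and classifies it as bit-exact or not;
3. a **desk-scale simulator** that reproduces the reduction-order
   mechanism without a GPU;
4. a **system fingerprint** recording the hardware and software that
   produced a run, because even bit-exact pipelines legitimately differ
   across hardware generations.

## The rule set

Rules live in a packaged YAML file (`default_rules_path()`) and are pure
data: id, framework (`general`, `pytorch`, `tensorflow`, `xgboost`),
category (`seed_required`, `flag_required`, `env_required`,
`forbidden_call`, `discouraged_pattern`), patterns, severity, message and
an optional suggested alternative. Severities follow the distinction
between hard requirements and recommendations: missing seeds, missing
determinism flags and forbidden operations are errors; multi-worker or
multi-GPU distribution patterns are warnings; atomic-add notes with
deterministic fallbacks are informational.

The shipped content covers the settings empirically required for
deterministic training: the three general seeds (Python's `random`, NumPy,
`PYTHONHASHSEED`); per-framework seeds; `TF_DETERMINISTIC_OPS` for
TensorFlow; disabled cuDNN benchmark, enforced deterministic algorithms
and `CUBLAS_WORKSPACE_CONFIG=:4096:8` for PyTorch; the
`single_precision_histogram` option and avoidance of `allreduce` and
multi-GPU Dask training for XGBoost; and 3D convolution as a forbidden
operation with no deterministic equivalent. Vendor lists of
nondeterministic operations evolve continuously, so the packaged file is a
versioned snapshot and is deliberately user-extensible: passing `--rules`
(or `load_rules(path)`) replaces the knowledge base with no code change.

One schema note: flag rules may carry `required_value: true|false`, so
"cuDNN benchmark must be `False`" and "deterministic algorithms must be
`True`" are both expressible as data. A flag explicitly set to the
negation of its required value is reported at that line as an error, which
is stronger than merely "not satisfied".

## What the analyzer does — and does not — resolve

The analyzer is purely static and single-file. It tokenizes Python source
(strings, comments and line continuations handled properly), builds an
alias table from `import`/`from ... import ... as` statements, and
resolves every dotted call chain to a canonical qualified name before
matching. Matching is exact qualified-name equality — no regular
expressions — plus two data-driven extensions: ALL-CAPS patterns match
`os.environ` writes, and bare lower-case patterns match keyword arguments
with constant values. The keyword extension exists because XGBoost
configures both its seed and `single_precision_histogram` as parameters
rather than callables; dict-literal configuration keys, by contrast, are a
documented blind spot.

Design choices where the design was genuinely open:

* **Presence, not reachability.** A seed call anywhere in a file satisfies
  its rule; the analyzer does not model control flow or execution order.
  This matches how a CI linter is actually used, and avoids a class of
  false positives at the cost of missing seeds hidden behind dead code.
* **Scoping.** General seed rules fire only when at least one ML framework
  is imported, so non-ML utility scripts lint clean.
* **Locations** are 1-based lines and 0-based columns; missing-requirement
  findings anchor at line 1; findings sort by (source, line, column, rule
  id) so reports are byte-deterministic.
* **Dynamic constructs** (computed attributes, `exec`, `importlib`) are
  never resolved and never produce findings: the analyzer fails quiet, not
  noisy. A file the tokenizer cannot close (unterminated string,
  unbalanced brackets) yields a single `PARSE-ERROR` finding and a failed
  report.
* **Containerization and hardware logging** are requirements of the
  discipline but not statically decidable from model code, so the linter
  does not guess at them; they are handled by the fingerprint module.

```{r lint-example}
report <- lint_file(text = paste(
  "import torch",
  "torch.manual_seed(0)",
  "torch.backends.cudnn.benchmark = True",
  sep = "\n"))
report
```

## The runtime harness

`run_setting(mode, seed, frameworks, device_profile)` describes one
experimental setup; `build_settings_plan()` translates it into the ordered
actions an adapter would apply (`set_seed`, `set_env`, `set_flag`,
`avoid`). The plan contract is testable by inspection: the random plan is
empty, the seeds plan holds the three general seed actions plus one per
framework, and the deterministic plan is a strict superset adding the
framework's flag/env actions.

`execute_runs()` drives any trainer implementing the training contract —
an R function `trainer(plan, setting, epochs)` returning
`list(trajectory, params)`. The full setting is passed alongside the plan
because a trainer needs the device profile to pick its reduction policy;
the harness itself never imports an ML framework, so the toolkit is fully
testable without one. Fresh state between runs is the trainer's
responsibility and is documented as such.

Bit-exactness needs an operational definition; `detml` uses equality of an
md5 digest over the canonical little-endian byte serialization of the
parameters in a fixed traversal order, together with exact equality of the
full metric trajectories. All comparisons are on full-precision doubles
and raw digests, never on rounded displays, and no numerical tolerance
separates "deterministic" from "nondeterministic" — strict bit-exactness
is the classification boundary, with the actual differences exposed for
inspection. Defaults follow the standard protocol: five repetitions,
25 epochs, seed 0.

## The simulator: nondeterminism at desk scale

`ordered_sum(values, order)` is the mechanism in miniature: left-to-right
double-precision summation in an explicit order, with no compensation.
`ordered_sum(c(1e16, 1, -1e16))` is `0` in the identity order (the unit
addend is absorbed at magnitude 1e16) and `1` with the last two elements
swapped.

`make_toy_task()` builds a seeded linear-regression task — 200 samples,
5 features, Gaussian noise with standard deviation 0.1 — sized so that
reduction-order perturbations have enough terms to act on while a
10-run, 100-epoch verification completes in seconds on one CPU.
`toy_train()` runs full-batch gradient descent where every reduction goes
through `ordered_sum()`:

* `deterministic`: fixed sequential order, seeded initialization;
* `seeds` on `cpu`: fixed order, seeded initialization (seeding suffices
  when the accumulation order is fixed, mirroring the observation that
  seeds-only CPU runs reproduce);
* `seeds`/`random` on `gpu-sim`: every reduction draws its own permutation
  from `/dev/urandom` — each GPU kernel launch schedules its atomic adds
  independently, and OS entropy is deliberately outside any seeded RNG
  stream so that `set.seed()` cannot tame it;
* `random` additionally draws its initialization from OS entropy.

What the simulator shows is the *mechanism* — with fixed weights and
shuffled reduction orders, losses across runs differ in the last bits and
the across-run standard deviation is positive at every epoch. What it does
not show is *magnitude*: real GPU models accumulate these errors through
millions of kernel launches and nonlinear layers, producing visible loss
spread, whereas the linear toy model's divergence stays near machine
epsilon. Passing the simulator's tests therefore validates the
classification machinery, not the size of real-world nondeterminism. The
learning rate (0.05) keeps gradient descent well inside its stability
region; convergent linear dynamics actively contract perturbations, which
is why the gpu-sim profile reliably breaks trajectory bit-exactness while
final *weights* may still agree bit-for-bit.

The fixture generator closes the loop on the linter: it synthesizes
Python sources from the rule data itself — satisfying every requirement
except the injected violations — and returns the expected findings by
construction. Generator and lint engine share no matching code, so their
agreement over randomly sampled specs is a genuine soundness check, not a
tautology.

## System fingerprints

`collect_manifest()` records schema version, OS, CPU model and logical
cores, visible accelerators (via `nvidia-smi` when present; an empty list
otherwise), the R runtime, configured package versions, a caller-supplied
"devices used" annotation (tools that log only *available* hardware miss
what was exercised), and a container heuristic plus configured image
identifier. Probes degrade to `"unknown"`, never fail, and collection is
read-only. The digest covers every field except the timestamp, so repeated
collection on one machine is digest-stable, and a stored manifest can be
re-verified after parsing.

Scoped equality answers the cross-system question: `hardware` compares CPU
and accelerators only, `software` compares OS, runtime and packages.
Which fields constitute "same hardware" is a design decision; `detml`
uses CPU model, logical cores and the accelerator list, on the reasoning
that those are the components that partition parallel work and hence
rounding behavior. `compare_systems()` then reports one of four
combinations — reproduced on equivalent hardware, hardware-attributable
difference, unexplained divergence, reproduced across differing hardware —
as advisory text, never a hard failure, because differing hardware
legitimately yields differing bit patterns.

## Configuration and the command line

The `detml` script under `inst/cli/` exposes `lint`, `verify` and
`fingerprint` with the exit-code contract 0 = clean/deterministic,
1 = violations or nondeterminism, 2 = usage or configuration error.
Configuration lives in a YAML file (`detml.yml`); YAML was chosen over
other config formats so that the rules file and the configuration file
share one syntax and one parser. Precedence is flags over file over
defaults, and unknown keys are rejected rather than ignored.

## Numerical and testing notes

* Digests use `tools::md5sum` over exact bytes written to a temporary
  file; the digest choice is an implementation detail behind
  one internal function.
* The across-run standard deviation uses the two-pass sample formula
  (`stats::sd`); tests pin it against an explicit brute-force
  implementation.
* The test suite sizes are deliberate: 100 sampled fixture specs per
  framework and a 200 x 5 x 100-epoch x 10-run harness sweep keep the full
  suite under half a minute on a single CPU while exercising every
  documented property.
* Known limitations: no cross-file analysis, no dict-literal
  configuration keys, no notebook linting, no real-framework adapters in
  the core (they would be optional extras), and the simulator does not
  model per-library differences such as XGBoost versions whose single-GPU
  builds are deterministic while multi-GPU runs are not; the
  `device_profile` label is the hook for representing both regimes.
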