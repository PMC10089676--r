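# detml — determinism verification for machine-learning code

Machine-learning results are routinely irreproducible even with every
random seed fixed, because the major frameworks default to GPU kernels
built on atomic operations: the scheduling order of parallel threads
varies between runs, floating-point addition is not associative, and the
accumulated rounding differences surface as different losses, weights and
predictions. Bit-exact determinism — retraining reproduces the *identical*
bits on the same infrastructure — requires seeds **plus** enforced
deterministic algorithms, disabled runtime kernel auto-selection,
a consistent software stack and documented hardware.

`detml` is an R toolkit for engineers and reviewers who need to *verify*
that discipline rather than trust it:

* **Static analysis** (`lint_file()`, `lint_project()`): checks Python ML
  sources against a data-driven YAML rule set — required seeds (Python
  `random`, NumPy, `PYTHONHASHSEED`, per-framework), determinism flags
  (`TF_DETERMINISTIC_OPS`, cuDNN benchmark off,
  `CUBLAS_WORKSPACE_CONFIG=:4096:8`, `single_precision_histogram`),
  forbidden nondeterministic operations (3D convolution, `allreduce`) and
  discouraged patterns (multi-worker/multi-GPU distribution). Aliased
  imports are resolved; findings carry locations and suggested
  deterministic alternatives.
* **Runtime harness** (`execute_runs()`, `assess_determinism()`): runs a
  training procedure repeatedly under the three canonical setups —
  *random*, *seeds*, *deterministic* — and classifies it as bit-exact
  deterministic or not, via digests over canonical parameter bytes and
  exact trajectory comparison. `compare_systems()` extends the question
  across machines using hardware-scoped manifest equality.
* **Simulator** (`ordered_sum()`, `make_toy_task()`, `toy_train()`): a
  desk-scale reproduction of the reduction-order mechanism — no GPU
  needed — used as the harness's built-in test workload.
* **System fingerprint** (`collect_manifest()`): hardware/software
  provenance manifests with timestamp-invariant digests and scoped
  equality.

## Worked example

Lint a PyTorch snippet that sets its seed but enables cuDNN benchmark:

```r
library(detml)
report <- lint_file(text = paste(
  "import torch",
  "torch.manual_seed(0)",
  "torch.backends.cudnn.benchmark = True",
  sep = "\n"))
report
```

```
detml lint: 1 source(s), frameworks: pytorch
<memory>:1:0 [error] ENV-CUBLAS-WORKSPACE: CUBLAS_WORKSPACE_CONFIG is not set; multi-stream cuBLAS workspace selection is nondeterministic.
    suggestion: os.environ["CUBLAS_WORKSPACE_CONFIG"] = ":4096:8"
<memory>:1:0 [error] FLAG-TORCH-DETERMINISTIC: Deterministic algorithms are not enforced; PyTorch may select nondeterministic kernels.
    suggestion: torch.use_deterministic_algorithms(True)
<memory>:1:0 [error] SEED-HASH: PYTHONHASHSEED is not fixed; hash-based iteration order is randomized per interpreter start.
    suggestion: os.environ["PYTHONHASHSEED"] = "0"
<memory>:1:0 [error] SEED-NUMPY: NumPy RNG seed is not set; array-level randomness will differ between runs.
    suggestion: numpy.random.seed(<seed>)
<memory>:1:0 [error] SEED-PYTHON-RANDOM: Python's random module seed is not set; stdlib RNG draws will differ between runs.
    suggestion: random.seed(<seed>)
<memory>:3:0 [error] FLAG-CUDNN-BENCHMARK: cuDNN benchmark must be disabled: it auto-selects the fastest kernel and can pick nondeterministic functions. (explicitly set to the nondeterministic value here)
    suggestion: torch.backends.cudnn.benchmark = False
errors: 6  warnings: 0  info: 0
FAILED
```

Missing requirements anchor at line 1; the explicitly enabled benchmark is
flagged at its own line (3). Fixing all six findings makes the report
`PASSED`.

Classify the built-in toy trainer (linear regression where every gradient
reduction goes through an explicitly ordered sum) under the three setups
on the simulated-GPU device profile:

```r
trainer <- make_toy_trainer(make_toy_task())
for (mode in c("deterministic", "seeds", "random")) {
  s <- run_setting(mode, seed = 0, device_profile = "gpu-sim")
  print(assess_determinism(execute_runs(trainer, s, n_runs = 5, epochs = 100)))
}
```

```
<detml verdict> deterministic over 5 runs
  distinct parameter digests: 1
  max |final metric diff|: 0
<detml verdict> nondeterministic over 5 runs
  distinct parameter digests: 1
  max |final metric diff|: 3.4694469519536142e-18
<detml verdict> nondeterministic over 5 runs
  distinct parameter digests: 5
  max |final metric diff|: 3.1545213131575767e-07
```

Only the deterministic setup is bit-exact. Seeds alone leave the simulated
atomic-add scheduling free to reorder the reductions — the final losses
differ in their last bits even though the weights happen to agree — and
the random setup diverges outright. On the `cpu` profile, seeds alone *do*
reproduce, which is exactly why GPU nondeterminism goes unnoticed in
CPU-tested code.

The command-line front end wraps the same functions:

```sh
inst/cli/detml lint src/ --format json
inst/cli/detml verify --mode deterministic --mode random --n-runs 5 --epochs 25
inst/cli/detml fingerprint --output manifest.json
```

Exit codes: 0 clean/deterministic, 1 violations or nondeterminism,
2 usage errors.

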