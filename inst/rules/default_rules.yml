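# Default determinism ruleset shipped with detml.
#
# Pure data: the lint engine has no rule knowledge of its own, so editing
# this file (or passing --rules with a replacement) changes lint behavior
# with no code change. Patterns are canonical qualified names matched after
# alias resolution; ALL-CAPS patterns additionally match environment
# variable writes, and bare lower-case patterns match keyword-argument
# names with constant values (used where a framework exposes a setting as
# a parameter rather than a callable).
version: "1.0.0"
rules:
  # ---- general: required for every ML framework ---------------------------
  - id: SEED-PYTHON-RANDOM
    framework: general
    category: seed_required
    patterns: [random.seed]
    severity: error
    message: "Python's random module seed is not set; stdlib RNG draws will differ between runs."
    alternative: "random.seed(<seed>)"
  - id: SEED-NUMPY
    framework: general
    category: seed_required
    patterns: [numpy.random.seed, numpy.random.default_rng]
    severity: error
    message: "NumPy RNG seed is not set; array-level randomness will differ between runs."
    alternative: "numpy.random.seed(<seed>)"
  - id: SEED-HASH
    framework: general
    category: seed_required
    patterns: [PYTHONHASHSEED]
    severity: error
    message: "PYTHONHASHSEED is not fixed; hash-based iteration order is randomized per interpreter start."
    alternative: "os.environ[\"PYTHONHASHSEED\"] = \"0\""
  - id: DISC-MULTI-WORKER
    framework: general
    category: discouraged_pattern
    patterns: [dask.distributed.Client, dask.distributed.LocalCluster, dask_cuda.LocalCUDACluster]
    severity: warning
    message: "Data distribution over multiple worker instances is not deterministic; partitioning across workers does not guarantee a stable order."
    alternative: "train in a single process / on a single device"

  # ---- pytorch ------------------------------------------------------------
  - id: SEED-PYTORCH
    framework: pytorch
    category: seed_required
    patterns: [torch.manual_seed, torch.cuda.manual_seed_all]
    severity: error
    message: "PyTorch RNG seed is not set."
    alternative: "torch.manual_seed(<seed>)"
  - id: FLAG-TORCH-DETERMINISTIC
    framework: pytorch
    category: flag_required
    patterns: [torch.use_deterministic_algorithms, torch.backends.cudnn.deterministic]
    severity: error
    required_value: true
    message: "Deterministic algorithms are not enforced; PyTorch may select nondeterministic kernels."
    alternative: "torch.use_deterministic_algorithms(True)"
  - id: FLAG-CUDNN-BENCHMARK
    framework: pytorch
    category: flag_required
    patterns: [torch.backends.cudnn.benchmark]
    severity: error
    required_value: false
    message: "cuDNN benchmark must be disabled: it auto-selects the fastest kernel and can pick nondeterministic functions."
    alternative: "torch.backends.cudnn.benchmark = False"
  - id: ENV-CUBLAS-WORKSPACE
    framework: pytorch
    category: env_required
    patterns: [CUBLAS_WORKSPACE_CONFIG]
    severity: error
    message: "CUBLAS_WORKSPACE_CONFIG is not set; multi-stream cuBLAS workspace selection is nondeterministic."
    alternative: "os.environ[\"CUBLAS_WORKSPACE_CONFIG\"] = \":4096:8\""
  - id: FORBID-CONV3D
    framework: pytorch
    category: forbidden_call
    patterns: [torch.nn.Conv3d, torch.nn.functional.conv3d]
    severity: error
    message: "3D convolution is implemented nondeterministically based on atomic operations; no deterministic variant is available."
  - id: FORBID-TORCH-INTERPOLATE-NEAREST-EXACT
    framework: pytorch
    category: forbidden_call
    patterns: [torch.nn.functional.interpolate, torch.nn.Upsample]
    severity: error
    message: "Interpolation/upsampling backward passes are labeled nondeterministic by PyTorch on CUDA."
    alternative: "precompute resizing on CPU or use a deterministic pooling layer"
  - id: INFO-ATOMIC-MAXPOOL
    framework: pytorch
    category: discouraged_pattern
    patterns: [torch.nn.MaxPool3d, torch.nn.functional.max_pool3d, torch.nn.AdaptiveMaxPool2d]
    severity: info
    message: "Max-pooling variants are based on atomic add on GPU and accumulate floating-point error nondeterministically; deterministic with enforced deterministic algorithms where supported."

  # ---- tensorflow ---------------------------------------------------------
  - id: SEED-TENSORFLOW
    framework: tensorflow
    category: seed_required
    patterns: [tensorflow.random.set_seed, tensorflow.compat.v1.set_random_seed]
    severity: error
    message: "TensorFlow RNG seed is not set."
    alternative: "tensorflow.random.set_seed(<seed>)"
  - id: FLAG-TF-DETERMINISM
    framework: tensorflow
    category: env_required
    patterns: [TF_DETERMINISTIC_OPS, tensorflow.config.experimental.enable_op_determinism]
    severity: error
    message: "TF_DETERMINISTIC_OPS is not set; TensorFlow defaults to nondeterministic GPU kernels."
    alternative: "os.environ[\"TF_DETERMINISTIC_OPS\"] = \"1\""
  - id: FORBID-TF-CONV3D
    framework: tensorflow
    category: forbidden_call
    patterns: [tensorflow.nn.conv3d, tensorflow.keras.layers.Conv3D]
    severity: error
    message: "3D convolution is implemented nondeterministically based on atomic operations; no deterministic variant is available."

  # ---- xgboost ------------------------------------------------------------
  - id: SEED-XGBOOST
    framework: xgboost
    category: seed_required
    patterns: [seed, random_state]
    severity: error
    message: "XGBoost seed parameter is not set; tree construction will differ between runs."
    alternative: "pass seed=<seed> (or random_state=<seed>) to the booster"
  - id: FLAG-XGB-SINGLE-PRECISION-HISTOGRAM
    framework: xgboost
    category: flag_required
    patterns: [single_precision_histogram]
    severity: error
    required_value: true
    message: "single_precision_histogram is not enabled; GPU histogram construction is nondeterministic without it."
    alternative: "enable single_precision_histogram=True"
  - id: FORBID-ALLREDUCE
    framework: xgboost
    category: forbidden_call
    patterns: [xgboost.rabit.allreduce, xgboost.collective.allreduce]
    severity: error
    message: "XGBoost allreduce operations have not been verified to run deterministically and must be avoided."
    alternative: "train on a single device without distributed reduction"
  - id: DISC-XGB-MULTI-GPU
    framework: xgboost
    category: discouraged_pattern
    patterns: [xgboost.dask.train, xgboost.dask.DaskXGBClassifier, xgboost.dask.DaskXGBRegressor]
    severity: warning
    message: "Multi-GPU XGBoost training is nondeterministic; XGBoost models should be trained on single GPUs."
    alternative: "single-GPU xgboost.train with tree_method=gpu_hist"
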