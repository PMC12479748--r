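# Shared fixtures and oracles. Everything is generated in code; expensive
# artifacts are memoized for the session so acceptance blocks can share them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Central finite differences, the gradient oracle.
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(max(abs(a)), 1e-12)

# A clean 5-beat noise-free record used across modules.
clean_record <- function() {
  memo("clean_record",
       generate_waveform(synthetic_ecg_spec(heart_rate = 60, sampling_rate = 250,
                                            duration = 5, noise_sd = 0,
                                            baseline_wander_amp = 0)))
}

# Small noisy two-class dataset (traces only).
small_dataset <- function() {
  memo("small_dataset", make_ecg_dataset(10, seed = 301, render = FALSE))
}

# Brute-force AUC by enumerating positive-negative pairs (ties count 1/2).
pair_count_auc <- function(scores, labels, positive_class) {
  pos <- scores[labels == positive_class]
  neg <- scores[labels != positive_class]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# The full desk-scale experiment shared by the end-to-end and explainability
# acceptance blocks (trained once per session).
acceptance_pipeline <- function() {
  memo("acceptance_pipeline",
       run_pipeline(pipeline_config(n_per_class = 100, seed = 20260925),
                    progress = FALSE))
}
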