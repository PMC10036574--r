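# Shared fixtures, built in code at test time.

# Small, well-separated dataset: fast to model, fast to select on.
small_spec <- function(seed = 1L, effect_size = 2, n_active = 75L,
                       n_inactive = 75L, n_noise = 10L, n_corr_pairs = 1L) {
  synthetic_spec(
    n_active = n_active, n_inactive = n_inactive,
    n_informative = 5L, effect_size = effect_size,
    n_noise = n_noise, n_corr_pairs = n_corr_pairs,
    seed = seed
  )
}

# Cheap random-forest config for repeated-fit tests.
fast_rf_config <- function(seed = 1L, ntree = 100L) {
  model_config("random_forest", list(ntree = ntree), seed = seed)
}

# Independent bit-loop oracle for the Tanimoto coefficient.
tanimoto_brute <- function(a, b) {
  A <- 0L; B <- 0L; C <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1L) A <- A + 1L
    if (b[i] == 1L) B <- B + 1L
    if (a[i] == 1L && b[i] == 1L) C <- C + 1L
  }
  if (A + B - C == 0L) 0 else C / (A + B - C)
}

# Independent all-pairs Mann-Whitney oracle for the AUC.
auc_brute <- function(y_true, scores) {
  pos <- scores[y_true == "active"]
  neg <- scores[y_true == "inactive"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

random_fingerprints <- function(n, seed, p_on = 0.3) {
  withr::with_seed(seed, {
    fingerprint_set(matrix(rbinom(n * 166, 1, p_on), n, 166),
                    compound_ids = sprintf("FP%04d", seq_len(n)))
  })
}
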