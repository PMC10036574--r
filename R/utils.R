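# Internal helpers shared across modules.

# All randomness in the package flows through this wrapper: Mersenne-Twister
# with Inversion normals and Rejection sampling, seeded locally so the
# caller's RNG state is never touched. Identical seed => identical draws on
# every platform.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

# Binary activity labels are represented as a factor with levels
# c("active", "inactive"); "active" is the positive class everywhere.
activity_levels <- c("active", "inactive")

as_activity_factor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), activity_levels)
  if (length(bad) > 0) {
    stop("labels must be 'active' or 'inactive'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(y, levels = activity_levels)
}

check_both_classes <- function(y) {
  y <- as_activity_factor(y)
  if (any(table(y) == 0)) {
    stop("both classes ('active' and 'inactive') must be present",
         call. = FALSE)
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
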