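#' Specification for a synthetic QSAR dataset
#'
#' Describes a two-class compound set with the statistical structure a
#' descriptor-based QSAR pipeline assumes: class-informative descriptors
#' (standardised mean shift between actives and inactives), pure-noise
#' descriptors, highly correlated descriptor pairs (to exercise redundancy
#' pruning), and structural-key fingerprint bits enriched in actives.
#'
#' Descriptor accounting must be exact: the total descriptor count is
#' `n_informative + n_noise + 2 * n_corr_pairs`.
#'
#' The defaults emulate a curated kinase-inhibitor modelling table: 400
#' balanced compounds over 54 descriptors of which 5 carry signal at a
#' standardised effect size (Cohen's d) of 2, plus 10 fingerprint bits with
#' on-probability 0.8 in actives versus 0.4 in inactives.
#'
#' @param n_active,n_inactive compounds per class.
#' @param n_informative descriptors whose class-conditional means differ.
#' @param effect_size standardised mean shift of informative descriptors.
#' @param n_noise class-independent standard-normal descriptors.
#' @param n_corr_pairs descriptor pairs generated from a shared latent with
#'   target Pearson correlation `rho`.
#' @param rho target correlation within a generated pair (default 0.9).
#' @param n_enriched_bits fingerprint bits with class-specific on-probability.
#' @param p_bit_active,p_bit_inactive on-probability of enriched bits in each
#'   class; must satisfy `0 <= p_bit_inactive <= p_bit_active <= 1`.
#' @param p_bit_background on-probability of all remaining bits (both classes).
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   bit-for-bit (Mersenne-Twister, locally seeded).
#' @return object of class `synthetic_spec`.
#' @seealso [generate_dataset()], [generate_screening_library()]
#' @export
synthetic_spec <- function(n_active = 200L, n_inactive = 200L,
                           n_informative = 5L, effect_size = 2,
                           n_noise = 45L, n_corr_pairs = 2L, rho = 0.9,
                           n_enriched_bits = 10L,
                           p_bit_active = 0.8, p_bit_inactive = 0.4,
                           p_bit_background = 0.3,
                           seed = 42L) {
  spec <- list(
    n_active = as.integer(n_active), n_inactive = as.integer(n_inactive),
    n_informative = as.integer(n_informative), effect_size = effect_size,
    n_noise = as.integer(n_noise), n_corr_pairs = as.integer(n_corr_pairs),
    rho = rho, n_enriched_bits = as.integer(n_enriched_bits),
    p_bit_active = p_bit_active, p_bit_inactive = p_bit_inactive,
    p_bit_background = p_bit_background, seed = as.integer(seed)
  )
  counts <- c(spec$n_active, spec$n_inactive, spec$n_informative,
              spec$n_noise, spec$n_corr_pairs, spec$n_enriched_bits)
  if (any(counts < 0L)) stop("all counts must be >= 0", call. = FALSE)
  spec$n_descriptors <- spec$n_informative + spec$n_noise + 2L * spec$n_corr_pairs
  if (spec$n_descriptors < 1L) {
    stop("inconsistent descriptor accounting: total descriptor count must be >= 1",
         call. = FALSE)
  }
  if (!(p_bit_inactive >= 0 && p_bit_active >= p_bit_inactive && p_bit_active <= 1)) {
    stop("bit probabilities must satisfy 0 <= p_bit_inactive <= p_bit_active <= 1",
         call. = FALSE)
  }
  if (spec$n_enriched_bits > 166L) stop("at most 166 enriched bits", call. = FALSE)
  if (abs(spec$rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  class(spec) <- "synthetic_spec"
  spec
}

descriptor_names_for <- function(spec) {
  c(if (spec$n_informative > 0) sprintf("INF%02d", seq_len(spec$n_informative)),
    if (spec$n_noise > 0) sprintf("NOI%02d", seq_len(spec$n_noise)),
    if (spec$n_corr_pairs > 0)
      as.vector(rbind(sprintf("CORa%02d", seq_len(spec$n_corr_pairs)),
                      sprintf("CORb%02d", seq_len(spec$n_corr_pairs)))))
}

# Draw one block of descriptors + fingerprints for a given label vector.
# Shared by generate_dataset() and generate_screening_library(); must be
# called inside with_seed().
sample_block <- function(spec, labels, ids) {
  n <- length(labels)
  active <- labels == "active"
  cols <- list()
  for (j in seq_len(spec$n_informative)) {
    cols[[length(cols) + 1L]] <- rnorm(n) + spec$effect_size * active
  }
  for (j in seq_len(spec$n_noise)) {
    cols[[length(cols) + 1L]] <- rnorm(n)
  }
  for (j in seq_len(spec$n_corr_pairs)) {
    x1 <- rnorm(n)
    x2 <- spec$rho * x1 + sqrt(1 - spec$rho^2) * rnorm(n)
    cols[[length(cols) + 1L]] <- x1
    cols[[length(cols) + 1L]] <- x2
  }
  X <- do.call(cbind, cols)
  dimnames(X) <- list(ids, descriptor_names_for(spec))

  p_on <- matrix(spec$p_bit_background, n, 166)
  if (spec$n_enriched_bits > 0) {
    enr <- seq_len(spec$n_enriched_bits)
    p_on[active, enr] <- spec$p_bit_active
    p_on[!active, enr] <- spec$p_bit_inactive
  }
  bits <- matrix(rbinom(n * 166, 1L, as.vector(p_on)), n, 166)
  fps <- fingerprint_set(bits, compound_ids = ids)
  list(descriptors = descriptor_matrix(X), fingerprints = fps)
}

#' Generate a labeled synthetic compound dataset
#'
#' Draws a complete two-class dataset from a [synthetic_spec()]: a compound
#' table (id, opaque structure string, IC50 in micromolar consistent with the
#' label), a descriptor matrix, a 166-bit fingerprint set and the label
#' vector. Informative descriptors are standard normal shifted by
#' `effect_size` in actives; noise descriptors are standard normal in both
#' classes; each correlated pair is `x2 = rho * x1 + sqrt(1 - rho^2) * eps`.
#' Enriched fingerprint bits are Bernoulli with class-specific probabilities;
#' all other bits share one background probability. IC50 values are sampled
#' log-uniformly below the 1 micromolar boundary for actives and above it for
#' inactives, so the table round-trips through [assign_labels()] unchanged.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `compounds` (data.frame: compound_id,
#'   structure, ic50_um, label), `descriptors`, `fingerprints`, `labels`.
#'   The enriched bit indices are attached as `attr(fingerprints,
#'   "enriched_bits")`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_active + spec$n_inactive
  if (n < 1L) stop("spec defines zero compounds", call. = FALSE)
  if ((spec$n_informative > 0 || spec$n_enriched_bits > 0) &&
      (spec$n_active == 0L || spec$n_inactive == 0L)) {
    stop("class-conditional sampling requires at least one compound per class",
         call. = FALSE)
  }
  labels <- factor(rep(activity_levels, c(spec$n_active, spec$n_inactive)),
                   levels = activity_levels)
  ids <- sprintf("CPD%05d", seq_len(n))

  with_seed(spec$seed, {
    block <- sample_block(spec, labels, ids)
    # opaque, unique structure strings -- identifiers, not chemistry
    structure_str <- sprintf("SYN[%s-%06d]", ids,
                             sample.int(999999L, n, replace = TRUE))
    ic50 <- numeric(n)
    ic50[labels == "active"] <- 10^runif(spec$n_active, -2, 0)      # 0.01..1
    ic50[labels == "inactive"] <- 10^runif(spec$n_inactive, 0.01, 2) # >1..100
    compounds <- data.frame(
      compound_id = ids, structure = structure_str,
      ic50_um = ic50, label = labels,
      stringsAsFactors = FALSE
    )
    if (spec$n_enriched_bits > 0) {
      attr(block$fingerprints, "enriched_bits") <- seq_len(spec$n_enriched_bits)
    }
    list(compounds = compounds, descriptors = block$descriptors,
         fingerprints = block$fingerprints, labels = labels)
  })
}

#' Generate an unlabeled synthetic screening library
#'
#' Emulates an external compound library to screen: a fraction of compounds
#' is drawn from the training distribution (a latent 50/50 mix of the
#' active- and inactive-conditional distributions of `spec`), and the
#' remaining `frac_shifted` fraction is offset by `shift` standard deviations
#' on every descriptor, placing it outside the training chemical space.
#'
#' @param n library size (must be >= 1).
#' @param frac_shifted fraction in `[0, 1]` of compounds to shift.
#' @param shift standardised offset added to every descriptor of shifted
#'   compounds.
#' @param seed integer RNG seed.
#' @param spec [synthetic_spec()] defining the training distribution.
#' @return list with `descriptors`, `fingerprints`, and a logical
#'   `is_shifted` vector (`round(n * frac_shifted)` entries `TRUE`).
#' @export
generate_screening_library <- function(n, frac_shifted = 0.3, shift = 10,
                                       seed = 1L, spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("screening library must contain at least one compound", call. = FALSE)
  if (frac_shifted < 0 || frac_shifted > 1) {
    stop("frac_shifted must lie in [0, 1]", call. = FALSE)
  }
  n_shift <- as.integer(round(n * frac_shifted))
  ids <- sprintf("LIB%05d", seq_len(n))
  with_seed(seed, {
    latent <- factor(sample(activity_levels, n, replace = TRUE),
                     levels = activity_levels)
    block <- sample_block(spec, latent, ids)
    is_shifted <- rep(FALSE, n)
    if (n_shift > 0) {
      is_shifted[sample.int(n, n_shift)] <- TRUE
      block$descriptors[is_shifted, ] <- block$descriptors[is_shifted, , drop = FALSE] + shift
    }
    list(descriptors = block$descriptors, fingerprints = block$fingerprints,
         is_shifted = is_shifted)
  })
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic QSAR dataset spec\n")
  cat(sprintf("  compounds:   %d active + %d inactive\n", x$n_active, x$n_inactive))
  cat(sprintf("  descriptors: %d (%d informative @ d=%.2g, %d noise, %d corr pairs @ rho=%.2g)\n",
              x$n_descriptors, x$n_informative, x$effect_size,
              x$n_noise, x$n_corr_pairs, x$rho))
  cat(sprintf("  fingerprints: %d enriched bits (p %.2g vs %.2g), background p %.2g\n",
              x$n_enriched_bits, x$p_bit_active, x$p_bit_inactive, x$p_bit_background))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
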