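#' Tanimoto similarity of two structural-key fingerprints
#'
#' For bit vectors with `a` and `b` on-bits sharing `c` on-bits, the
#' Tanimoto coefficient is `Tc = c / (a + b - c)`, the ratio of shared to
#' total distinct substructure keys. Two all-zero fingerprints have an
#' undefined ratio (0/0); they are reported as 0 (maximally dissimilar)
#' with a warning.
#'
#' @param fp_a,fp_b 0/1 vectors of length 166.
#' @return similarity in `[0, 1]`.
#' @examples
#' a <- b <- integer(166); a[1:4] <- 1; b[3:8] <- 1
#' tanimoto(a, b)  # c=2, a=4, b=6 -> 0.25
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != 166L || length(fp_b) != 166L) {
    stop("fingerprints must both have length 166 (got ",
         length(fp_a), " and ", length(fp_b), ")", call. = FALSE)
  }
  if (!all(fp_a %in% c(0, 1)) || !all(fp_b %in% c(0, 1))) {
    stop("fingerprint entries must be 0 or 1", call. = FALSE)
  }
  a <- sum(fp_a)
  b <- sum(fp_b)
  c <- sum(fp_a * fp_b)
  if (a + b == 0) {
    warning("both fingerprints are all-zero; Tanimoto defined as 0", call. = FALSE)
    return(0)
  }
  c / (a + b - c)
}

#' Pairwise Tanimoto similarity matrix
#'
#' Computes `tanimoto()` for every pair across two fingerprint sets in one
#' vectorised pass (shared bits via a cross-product). When both arguments
#' are the same set the result is symmetric with unit diagonal for
#' non-empty fingerprints.
#'
#' @param set_a,set_b fingerprint sets (see [fingerprint_set()]);
#'   `set_b` defaults to `set_a`.
#' @return `nrow(set_a) x nrow(set_b)` matrix with compound ids as dimnames.
#' @export
pairwise_similarity <- function(set_a, set_b = set_a) {
  set_a <- fingerprint_set(set_a)
  set_b <- fingerprint_set(set_b)
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    stop("fingerprint sets must be non-empty", call. = FALSE)
  }
  shared <- set_a %*% t(set_b)
  on_a <- rowSums(set_a)
  on_b <- rowSums(set_b)
  denom <- outer(on_a, on_b, "+") - shared
  if (any(denom == 0)) {
    warning("all-zero fingerprint pair(s); Tanimoto defined as 0", call. = FALSE)
  }
  sim <- ifelse(denom == 0, 0, shared / denom)
  dimnames(sim) <- list(rownames(set_a), rownames(set_b))
  sim
}

#' Per-bit on-frequency within a compound class
#'
#' For each of the 166 bit positions, the percentage of class members with
#' the bit set: `100 * (number of members with bit on) / N`.
#'
#' @param fps fingerprint set.
#' @param member_ids non-empty subset of `rownames(fps)` defining the class.
#' @param class_label optional label ("active"/"inactive"/other) carried in
#'   the result for bookkeeping.
#' @return object of class `bit_frequency_table`: list with `freq`
#'   (named percentage vector, length 166), `n` (class size) and
#'   `class_label`.
#' @export
bit_frequency <- function(fps, member_ids = rownames(fps), class_label = NA_character_) {
  fps <- fingerprint_set(fps)
  if (length(member_ids) == 0) stop("member_ids must be non-empty", call. = FALSE)
  unknown <- setdiff(member_ids, rownames(fps))
  if (length(unknown) > 0) {
    stop("unknown compound id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sub <- fps[member_ids, , drop = FALSE]
  structure(list(
    freq = 100 * colMeans(sub),
    n = length(member_ids),
    class_label = class_label
  ), class = "bit_frequency_table")
}

#' Bits differentially present between two classes
#'
#' Ranks fingerprint bits by the difference in on-frequency between an
#' active-class and an inactive-class [bit_frequency()] table, keeping bits
#' whose active-minus-inactive difference is at least `min_diff` percentage
#' points. What counts as a "reasonable" difference is a judgement call;
#' the default of 10 points is deliberately permissive and configurable.
#'
#' @param freq_active,freq_inactive `bit_frequency_table`s over 166 bits.
#' @param min_diff minimum difference in percentage points (default 10).
#' @return data.frame (bit, freq_active, freq_inactive, diff), sorted by
#'   decreasing difference, ties broken by bit index.
#' @export
differential_bits <- function(freq_active, freq_inactive, min_diff = 10) {
  stopifnot(inherits(freq_active, "bit_frequency_table"),
            inherits(freq_inactive, "bit_frequency_table"))
  fa <- freq_active$freq
  fi <- freq_inactive$freq
  stopifnot(length(fa) == 166L, length(fi) == 166L)
  d <- fa - fi
  idx <- which(d >= min_diff)
  idx <- idx[order(-d[idx], idx)]
  data.frame(
    bit = idx,
    freq_active = unname(fa[idx]),
    freq_inactive = unname(fi[idx]),
    diff = unname(d[idx])
  )
}

#' @export
print.bit_frequency_table <- function(x, ...) {
  cat(sprintf("Bit-frequency table (%s, n = %d): %d/166 bits with freq > 0\n",
              x$class_label, x$n, sum(x$freq > 0)))
  invisible(x)
}
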