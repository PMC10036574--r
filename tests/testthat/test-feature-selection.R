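test_that("correlation filter keeps exactly one of an identical pair", {
  withr::with_seed(1, {
    x <- rnorm(50)
    X <- cbind(a = x, b = x, c = rnorm(50))
  })
  res <- correlation_filter(X, seed = 3)
  expect_equal(ncol(res$X), 2)
  expect_true("c" %in% colnames(res$X))
  expect_equal(nrow(res$drop_log), 1)
  expect_equal(res$drop_log$r, 1)
})

test_that("independent descriptors all survive", {
  withr::with_seed(2, X <- matrix(rnorm(200 * 6), 200, 6,
                                  dimnames = list(NULL, letters[1:6])))
  stopifnot(max(abs(cor(X)[upper.tri(diag(6))])) < 0.5)
  res <- correlation_filter(X, seed = 1)
  expect_equal(colnames(res$X), letters[1:6])
  expect_equal(nrow(res$drop_log), 0)
})

test_that("a generated r = 0.9 pair loses one seeded-random member, logged with its r", {
  d <- generate_dataset(synthetic_spec(n_active = 150, n_inactive = 150,
                                       n_informative = 0, n_noise = 2,
                                       n_corr_pairs = 1, n_enriched_bits = 0,
                                       seed = 5))
  X <- d$descriptors
  # product-moment correlation computed by hand as the oracle
  x <- X[, "CORa01"]; y <- X[, "CORb01"]
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_gt(abs(r_manual), 0.85)

  res <- correlation_filter(X, seed = 11)
  expect_equal(nrow(res$drop_log), 1)
  expect_equal(res$drop_log$r, r_manual, tolerance = 1e-12)
  expect_setequal(c(res$drop_log$kept, res$drop_log$dropped),
                  c("CORa01", "CORb01"))
  # same seed => same member dropped; surviving pairs all below threshold
  res2 <- correlation_filter(X, seed = 11)
  expect_identical(res$drop_log, res2$drop_log)
  cc <- cor(res$X)
  expect_true(all(abs(cc[upper.tri(cc)]) <= 0.85))
})

test_that("zero-variance descriptors are dropped with a warning before correlation", {
  withr::with_seed(3, X <- cbind(const = rep(1, 30), ok = rnorm(30)))
  expect_warning(res <- correlation_filter(X, seed = 1), "zero-variance")
  expect_equal(colnames(res$X), "ok")
  expect_equal(res$dropped_constant, "const")
})

test_that("correlation pruning is invariant to input column order", {
  d <- generate_dataset(small_spec(seed = 9))
  X <- d$descriptors
  perm <- withr::with_seed(4, sample(ncol(X)))
  r1 <- correlation_filter(X, seed = 2)
  r2 <- correlation_filter(X[, perm], seed = 2)
  expect_setequal(colnames(r1$X), colnames(r2$X))
})

test_that("boruta decisions partition the candidates and shadows never leak", {
  d <- generate_dataset(small_spec(seed = 2))
  res <- boruta_select(d$descriptors, d$labels, n_iterations = 25, seed = 7)
  expect_setequal(c(res$confirmed, res$tentative, res$rejected),
                  colnames(d$descriptors))
  expect_equal(length(res$confirmed) + length(res$tentative) +
                 length(res$rejected), ncol(d$descriptors))
  expect_true(all(res$hits >= 0 & res$hits <= res$n_iterations))
  expect_false(any(grepl("shadow", res$kept)))
  expect_true(all(res$kept %in% colnames(d$descriptors)))
})

test_that("boruta recovers planted informative descriptors and is seed-stable", {
  d <- generate_dataset(small_spec(seed = 3, n_active = 150, n_inactive = 150))
  res <- boruta_select(d$descriptors, d$labels, n_iterations = 30, seed = 1)
  expect_true(all(sprintf("INF%02d", 1:5) %in% res$confirmed))
  res2 <- boruta_select(d$descriptors, d$labels, n_iterations = 30, seed = 1)
  expect_identical(res$hits, res2$hits)
})

test_that("shrinking alpha never grows the confirmed set", {
  d <- generate_dataset(small_spec(seed = 4))
  strict <- boruta_select(d$descriptors, d$labels, n_iterations = 25,
                          alpha = 1e-8, seed = 5)
  loose <- boruta_select(d$descriptors, d$labels, n_iterations = 25,
                         alpha = 0.05, seed = 5)
  expect_true(all(strict$confirmed %in% loose$confirmed))
})

test_that("boruta rejects degenerate inputs", {
  d <- generate_dataset(small_spec(seed = 6, n_active = 30, n_inactive = 30))
  expect_error(boruta_select(d$descriptors, rep("active", 60)), "both classes")
  expect_error(boruta_select(d$descriptors, d$labels, n_iterations = 10),
               ">= 20")
})
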