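# End-to-end funnel fixture: well-separated training data, ensemble, AD,
# and a library of training-active replicas plus far-shifted decoys.
funnel <- local({
  spec <- small_spec(seed = 51, effect_size = 3, n_active = 100, n_inactive = 100)
  d <- generate_dataset(spec)
  split <- split_stratified(d$labels, 0.2, seed = 51)
  X_train <- d$descriptors[split$train, ]
  y_train <- d$labels[split$train]
  bundle <- train_ensemble(X_train, y_train, seed = 51)
  ad <- fit_ad(X_train, margin = 0.05)

  act <- which(y_train == "active")[1:20]
  replicas <- X_train[act, ]
  rownames(replicas) <- sprintf("REP%03d", seq_len(nrow(replicas)))
  decoys <- X_train[act, ] + 10
  rownames(decoys) <- sprintf("DEC%03d", seq_len(nrow(decoys)))
  X_lib <- rbind(replicas, decoys)

  fps_lib <- d$fingerprints[rep(rownames(X_train)[act], 2), ]
  rownames(fps_lib) <- rownames(X_lib)
  fps_act <- d$fingerprints[d$labels == "active", ]
  list(d = d, bundle = bundle, ad = ad, X_lib = X_lib,
       fps_lib = fps_lib, fps_act = fps_act)
})

test_that("the final pass is exactly the conjunction of the three filters", {
  rep <- screen_library(funnel$bundle, funnel$ad, funnel$X_lib,
                        fps_lib = funnel$fps_lib,
                        fps_train_active = funnel$fps_act)
  expect_equal(rep$final_pass,
               rep$consensus_active & rep$probability_pass & rep$in_ad)
  expect_lte(sum(rep$final_pass),
             min(sum(rep$consensus_active), sum(rep$probability_pass),
                 sum(rep$in_ad)))
})

test_that("training-active replicas pass and 10-SD decoys fail end to end", {
  rep <- screen_library(funnel$bundle, funnel$ad, funnel$X_lib,
                        fps_lib = funnel$fps_lib,
                        fps_train_active = funnel$fps_act)
  is_rep <- grepl("^REP", rep$compound_id)
  expect_true(all(rep$final_pass[is_rep]))
  expect_false(any(rep$in_ad[!is_rep]))
  expect_false(any(rep$final_pass[!is_rep]))
  # replica fingerprints are copies of training actives: similarity 1, not novel
  expect_equal(rep$max_similarity_to_actives[is_rep], rep(1, sum(is_rep)))
  expect_false(any(rep$novel[is_rep]))
})

test_that("ranks are a permutation of 1..n_pass ordered by mean probability", {
  rep <- screen_library(funnel$bundle, funnel$ad, funnel$X_lib)
  pass <- rep[rep$final_pass, ]
  expect_setequal(pass$rank, seq_len(nrow(pass)))
  expect_true(all(is.na(rep$rank[!rep$final_pass])))
  ord <- pass[order(pass$rank), ]
  expect_true(all(diff(ord$mean_p) <= 0))
})

test_that("raising the probability threshold never grows the passing set", {
  thresholds <- c(0.5, 0.6, 0.7, 0.9, 1.0)
  n_pass <- vapply(thresholds, function(t) {
    sum(screen_library(funnel$bundle, funnel$ad, funnel$X_lib,
                       probability_threshold = t)$final_pass)
  }, numeric(1))
  expect_true(all(diff(n_pass) <= 0))
})

test_that("screening is deterministic and validates inputs", {
  r1 <- screen_library(funnel$bundle, funnel$ad, funnel$X_lib)
  r2 <- screen_library(funnel$bundle, funnel$ad, funnel$X_lib)
  expect_identical(r1, r2)
  expect_error(screen_library(funnel$bundle, funnel$ad,
                              funnel$X_lib[integer(), ]), "empty")
  expect_error(screen_library(funnel$bundle, funnel$ad, funnel$X_lib,
                              probability_threshold = 1.5), "\\[0, 1\\]")
})

test_that("missing library fingerprints are logged, not fatal", {
  rep <- screen_library(funnel$bundle, funnel$ad, funnel$X_lib,
                        fps_lib = funnel$fps_lib[-1, ],
                        fps_train_active = funnel$fps_act)
  expect_true(is.na(rep$max_similarity_to_actives[1]))
  expect_match(attr(rep, "log"), rep$compound_id[1], all = FALSE)
})

test_that("novelty annotation matches the brute-force maximum over actives", {
  hits <- random_fingerprints(50, seed = 52)
  actives <- random_fingerprints(20, seed = 53)
  ann <- novelty_annotation(hits, actives, threshold = 0.5)
  for (i in seq_len(50)) {
    best <- max(vapply(seq_len(20), function(j) {
      tanimoto_brute(hits[i, ], actives[j, ])
    }, numeric(1)))
    expect_equal(ann$max_similarity[i], best)
    expect_equal(ann$novel[i], best <= 0.5)
  }
  # a hit identical to an active is maximally similar, never novel
  self <- novelty_annotation(actives[1, , drop = FALSE], actives)
  expect_equal(self$max_similarity, 1)
  expect_false(self$novel)
  # disjoint bits: similarity 0, novel
  z <- fingerprint_set(matrix(c(rep(1L, 80), rep(0L, 86)), 1), "z")
  w <- fingerprint_set(matrix(c(rep(0L, 80), rep(1L, 86)), 1), "w")
  dis <- novelty_annotation(z, w)
  expect_equal(dis$max_similarity, 0)
  expect_true(dis$novel)
})
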