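test_that("feature table is one row per pair with the pair's own traits", {
  r <- toy_traits(2, "resource", "P")
  c <- toy_traits(3, "consumer", "H", seed = 2)
  idx <- all_pairs(r, c)
  expect_equal(nrow(idx), 6)
  f <- build_features(idx, r, c)
  expect_equal(nrow(f), 6)
  # spot-check a row against the source tables
  row <- f[f$resource_id == "P02" & f$consumer_id == "H01", ]
  expect_equal(row$r_size, r$size[r$species_id == "P02"])
  expect_equal(row$c_shape, c$shape[c$species_id == "H01"])
  # determinism: identical on a second call
  expect_identical(f, build_features(idx, r, c))
  # categorical encoding recorded and reusable
  enc <- attr(f, "encoding")
  expect_true("r_colour" %in% names(enc))
  f2 <- build_features(idx, r, c, encoding = enc)
  expect_identical(as.data.frame(f), as.data.frame(f2))
})

test_that("schema drift and unknown ids are hard errors", {
  r <- toy_traits(2, "resource", "P")
  c <- toy_traits(2, "consumer", "H", seed = 2)
  idx <- all_pairs(r, c)
  enc <- attr(build_features(idx, r, c), "encoding")
  # unseen categorical level at predict time
  r2 <- r
  r2$colour <- c("violet", "violet")
  expect_error(build_features(idx, r2, c, encoding = enc),
               class = "nichewire_schema_error")
  # unresolvable id
  idx2 <- tibble::tibble(resource_id = "P99", consumer_id = "H01")
  expect_error(build_features(idx2, r, c), class = "nichewire_key_error")
})

test_that("metric formulas match direct evaluation on a fixed table", {
  # confusion TP=40, FN=10, FP=10, TN=40
  labels <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  scores <- rep(c(0.9, 0.1, 0.9, 0.1), c(40, 10, 10, 40))
  m <- evaluate_scores(labels, scores, tau = 0.5)
  expect_equal(m$tp, 40)
  expect_equal(m$fn, 10)
  expect_equal(m$fp, 10)
  expect_equal(m$tn, 40)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$kappa, 0.6)
  expect_equal(m$mcc, 0.6)
})

test_that("AUC equals the brute-force pair-ordering statistic", {
  set.seed(7)
  labels <- rbinom(200, 1, 0.4)
  scores <- round(runif(200), 2) # rounding forces ties
  m <- evaluate_scores(labels, scores)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(m$auc, mean(cmp), tolerance = 1e-12)
})

test_that("PR-AUC matches a step-interpolation oracle", {
  set.seed(9)
  labels <- rbinom(150, 1, 0.3)
  scores <- round(runif(150), 2)
  m <- evaluate_scores(labels, scores)
  # oracle: walk thresholds at distinct scores from high to low
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels)
  rec_prev <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / n1
    ap <- ap + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  expect_equal(m$pr_auc, ap, tolerance = 1e-12)
})

test_that("perfect separation yields AUC, PR-AUC and MCC of 1", {
  labels <- rep(c(0, 1), c(30, 20))
  scores <- c(runif(30, 0, 0.2), runif(20, 0.8, 1))
  m <- evaluate_scores(labels, scores, tau = 0.5)
  expect_equal(m$auc, 1)
  expect_equal(m$pr_auc, 1)
  expect_equal(m$mcc, 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  labels <- rbinom(80, 1, 0.5)
  scores <- runif(80)
  a0 <- evaluate_scores(labels, scores)$auc
  expect_equal(evaluate_scores(labels, plogis(5 * scores - 2))$auc, a0)
  expect_equal(evaluate_scores(labels, scores^3)$auc, a0)
})

test_that("one-class labels leave rank metrics undefined but not the rest", {
  expect_warning(m <- evaluate_scores(rep(1, 5), runif(5)), "one class")
  expect_true(is.na(m$auc))
  expect_true(is.na(m$pr_auc))
  expect_equal(m$tp + m$fn, 5)
})

test_that("threshold selection is fixed, optimal, or oracle-equal", {
  expect_equal(choose_threshold(c(0, 1), c(0.2, 0.8), method = "fixed"), 0.4)
  # separated scores 0.1 / 0.9: the smallest grid threshold lying strictly
  # inside the score gap is selected (ties broken downward)
  labels <- rep(c(0, 1), c(10, 10))
  scores <- rep(c(0.1, 0.9), c(10, 10))
  expect_equal(choose_threshold(labels, scores, method = "max_kappa"), 0.11)
  # brute-force grid oracle on a noisy set
  set.seed(15)
  labels <- rbinom(100, 1, 0.4)
  scores <- pmin(pmax(labels * 0.3 + runif(100, 0, 0.7), 0), 1)
  tau_hat <- choose_threshold(labels, scores, method = "max_kappa")
  grid <- seq(0.01, 0.99, by = 0.01)
  kappas <- vapply(grid, function(t) {
    evaluate_scores(labels, scores, tau = t)$kappa
  }, numeric(1))
  expect_equal(tau_hat, grid[which.max(kappas)])
  # youden variant against its own oracle
  tau_y <- choose_threshold(labels, scores, method = "max_youden")
  js <- vapply(grid, function(t) {
    m <- evaluate_scores(labels, scores, tau = t)
    m$tp / (m$tp + m$fn) + m$tn / (m$tn + m$fp) - 1
  }, numeric(1))
  expect_equal(tau_y, grid[which.max(js)])
  expect_error(choose_threshold(labels, scores, method = "best"))
})

test_that("model fitting is reproducible and ranks matching traits first", {
  eco <- simulate_ecosystem(synth_config(seed = 3))
  pairs <- assemble_training_pairs(eco$networks)
  params <- link_params(learning_rate = 0.05, n_trees_max = 600)
  fit <- fit_link_model(pairs, eco$resource, eco$consumer,
                        params = params, seed = 3)
  fit2 <- fit_link_model(pairs, eco$resource, eco$consumer,
                         params = params, seed = 3)
  grid <- all_pairs(eco$resource, eco$consumer)
  p1 <- predict(fit, grid, eco$resource, eco$consumer)$probability
  p2 <- predict(fit2, grid, eco$resource, eco$consumer)$probability
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # the two matching traits carry the signal
  top3 <- head(tidy(fit)$feature, 3)
  expect_true(all(c("r_corolla_length", "c_bill_length") %in% top3))
  # single-class training data cannot be fit
  one <- pairs
  one$label <- 1L
  expect_error(fit_link_model(one, eco$resource, eco$consumer),
               class = "nichewire_data_error")
})

test_that("cross-validation scores each row exactly once out of fold", {
  eco <- simulate_ecosystem(tiny_config(seed = 5))
  pairs <- assemble_training_pairs(eco$networks)
  params <- link_params(learning_rate = 0.1, n_trees_max = 60,
                        early_stopping_rounds = 10)
  cv <- cross_validate(pairs, eco$resource, eco$consumer, k = 5,
                       params = params, seed = 5)
  expect_equal(nrow(cv$scores), nrow(pairs))
  expect_false(any(is.na(cv$scores$score)))
  expect_setequal(unique(cv$scores$fold), 1:5)
  # folds are label-stratified
  by_fold <- table(cv$scores$fold, cv$scores$label)
  expect_lte(diff(range(by_fold[, "1"])), 2)
  # pooled metrics equal metrics recomputed from the saved score vector
  re <- evaluate_scores(cv$scores$label, cv$scores$score, tau = 0.4)
  expect_equal(cv$metrics[1, ], re)
  expect_equal(cv$metrics$threshold, c(0.4, 0.5))
  expect_error(cross_validate(pairs, eco$resource, eco$consumer, k = 1),
               class = "nichewire_config_error")
})

test_that("leave-one-out gives every row its own fold", {
  r <- toy_traits(4, "resource", "P")
  c <- toy_traits(5, "consumer", "H", seed = 2)
  pairs <- all_pairs(r, c)
  pairs$label <- as.integer(
    r$size[match(pairs$resource_id, r$species_id)] > 5
  )
  params <- link_params(learning_rate = 0.3, n_trees_max = 30,
                        early_stopping_rounds = 30)
  cv <- cross_validate(pairs, r, c, k = nrow(pairs), params = params,
                       seed = 8)
  expect_equal(nrow(cv$scores), nrow(pairs))
  # every row sits in its own fold, scored by a model that never saw it
  expect_equal(sort(cv$scores$fold), seq_len(nrow(pairs)))
})

test_that("perfectly separable data cross-validates to AUC 1", {
  r <- toy_traits(10, "resource", "P")
  c <- toy_traits(8, "consumer", "H", seed = 2)
  pairs <- all_pairs(r, c)
  pairs$label <- as.integer(
    r$size[match(pairs$resource_id, r$species_id)] >
      median(r$size)
  )
  params <- link_params(learning_rate = 0.3, n_trees_max = 80,
                        early_stopping_rounds = 80)
  cv <- cross_validate(pairs, r, c, k = 4, params = params, seed = 8)
  expect_equal(cv$metrics$auc[1], 1)
})
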