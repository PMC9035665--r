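test_that("soft cross-entropy matches hand computations", {
  expect_equal(soft_cross_entropy(c(0, 1, 0, 0), c(0, 1, 0, 0)), 0)
  expect_equal(soft_cross_entropy(rep(0.25, 4), c(0.55, 0.45, 0, 0)), log(4))
  # one-hot target reduces to -log(pred) of the true class exactly
  p <- c(0.6, 0.2, 0.15, 0.05)
  expect_equal(soft_cross_entropy(p, c(1, 0, 0, 0)), -log(0.6))
  expect_error(soft_cross_entropy(c(1, 0, 0), c(1, 0, 0, 0)), "length 4")
  expect_error(soft_cross_entropy(c(2, -1, 0, 0), c(1, 0, 0, 0)),
               "nonnegative")
  expect_error(soft_cross_entropy(c(0.5, 0.1, 0.1, 0.1), c(1, 0, 0, 0)),
               "sum to 1")
})

test_that("soft cross-entropy obeys the Gibbs inequality", {
  set.seed(42)
  entropy <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  for (i in 1:50) {
    pred <- as.vector(stats::rgamma(4, 1)); pred <- pred / sum(pred)
    targ <- as.vector(stats::rgamma(4, 1)); targ <- targ / sum(targ)
    expect_gte(soft_cross_entropy(pred, targ) + 1e-12, entropy(targ))
  }
  q <- c(0.55, 0.45, 0, 0)
  expect_equal(soft_cross_entropy(q, q), entropy(q), tolerance = 1e-9)
})

test_that("training separates a clean synthetic cohort", {
  spec <- tiny_spec(noise_sd = 0)
  train <- generate_cohort(spec, balanced_counts(4, disease_labels()),
                           seed = 31)
  test <- generate_cohort(spec, balanced_counts(2, disease_labels()),
                          seed = 32, start_identity = 20000L)
  model <- train_classifier(train, clf_config(pool = 8, hidden = 8,
                                              maxit = 200), seed = 1)
  expect_lt(model$final_loss, model$initial_loss)
  pr <- predict(model, test)
  expect_true(all(abs(rowSums(as.matrix(pr[, 1:4])) - 1) < 1e-6))
  expect_gte(mean(pr$label == test$disease), 0.95)
})

test_that("training is deterministic given one seed", {
  fx <- fixture_cohort()
  m1 <- train_classifier(fx$study, clf_config(hidden = 6, maxit = 50),
                         seed = 9)
  m2 <- train_classifier(fx$study, clf_config(hidden = 6, maxit = 50),
                         seed = 9)
  expect_identical(m1$fit$wts, m2$fit$wts)
})

test_that("a single-class manifest yields a constant predictor", {
  spec <- tiny_spec()
  train <- generate_cohort(spec, tibble::tibble(disease = "22q",
                                                age = age_brackets(),
                                                n = 3L), seed = 5)
  model <- train_classifier(train, clf_config(hidden = 4, maxit = 100),
                            seed = 1)
  pr <- predict(model, train)
  expect_true(all(pr$label == "22q"))
  expect_true(all(pr$p_22q > 0.9))
})

test_that("soft-label rows influence the fit", {
  fx <- fixture_cohort()
  study <- fx$study
  blend <- study[study$disease == "WS", ][1:5, ]
  blend$p_ws <- 0.55
  blend$p_22q <- 0.45
  with_blend <- dplyr::bind_rows(study, blend)
  cfg <- clf_config(hidden = 6, maxit = 60)
  m_base <- train_classifier(study, cfg, seed = 3)
  m_blend <- train_classifier(with_blend, cfg, seed = 3)
  expect_false(isTRUE(all.equal(m_base$fit$wts, m_blend$fit$wts)))
})

test_that("penultimate features reproduce the network's own forward pass", {
  fx <- fixture_cohort()
  model <- train_classifier(fx$study, clf_config(hidden = 6, maxit = 60),
                            seed = 2)
  imgs <- fx$study$image[1:4]
  h <- classifier_features(model, imgs)
  expect_equal(dim(h), c(4, 6))
  # reconstruct the output layer from the hidden activations
  n <- model$fit$n
  wts <- model$fit$wts
  w2 <- matrix(wts[-(seq_len((n[1] + 1) * n[2]))], nrow = n[2] + 1)
  logits <- cbind(1, h) %*% w2
  probs <- exp(logits) / rowSums(exp(logits))
  expect_equal(unname(as.matrix(predict(model, imgs)[, 1:4])),
               unname(probs), tolerance = 1e-8)
})

test_that("the confidence filter averages only confident members", {
  a <- c(0.9, 0.1, 0, 0)
  b <- c(0.4, 0.3, 0.2, 0.1)
  out <- ensemble_average(rbind(a, b))
  expect_equal(out$probabilities, a, ignore_attr = TRUE)
  expect_equal(out$n_used, 1)
  # two qualifying members: elementwise mean, still on the simplex
  c2 <- c(0.2, 0.6, 0.1, 0.1)
  out2 <- ensemble_average(rbind(a, c2))
  expect_equal(out2$probabilities, (a + c2) / 2, ignore_attr = TRUE)
  expect_equal(sum(out2$probabilities), 1)
  # nobody qualifies: fall back to averaging everyone
  w <- c(0.3, 0.3, 0.2, 0.2)
  out3 <- ensemble_average(rbind(b, w))
  expect_equal(out3$n_used, 2)
  expect_equal(out3$probabilities, (b + w) / 2, ignore_attr = TRUE)
})

test_that("ensemble predictions live on the 4-simplex", {
  fx <- fixture_cohort()
  ens <- fixture_ensemble()
  pr <- ensemble_predict(ens, fx$test[1:10, ])
  expect_true(all(abs(rowSums(as.matrix(pr[, 1:4])) - 1) < 1e-8))
  expect_true(all(pr$n_members_used >= 1 & pr$n_members_used <= 5))
  single <- face_ensemble(ens$models[1])
  pr1 <- ensemble_predict(single, fx$test[1:5, ])
  direct <- predict(ens$models[[1]], fx$test[1:5, ])
  expect_equal(as.matrix(pr1[, 1:4]), as.matrix(direct[, 1:4]),
               tolerance = 1e-12)
})

test_that("forced binary choice restricts the argmax to a pair", {
  expect_equal(forced_binary(c(0.1, 0.2, 0.3, 0.4), c("WS", "control")),
               "control")
  expect_equal(forced_binary(c(0.5, 0, 0.5, 0), c("WS", "control")), "WS")
  expect_error(forced_binary(c(0.5, 0.5, 0, 0), c("WS", "WS")), "distinct")
  expect_error(forced_binary(c(0.5, 0.5, 0, 0), c("WS", "nope")), "invalid")
})

test_that("forced binary never scores below pair-mapped 4-way argmax", {
  # brute force over a probability grid: whenever the global argmax equals
  # the truth, the pair-restricted argmax must too
  grid <- seq(0, 1, by = 0.2)
  pair <- c("WS", "control")
  for (p1 in grid) for (p2 in grid) for (p3 in grid) {
    if (p1 + p2 + p3 > 1) next
    p <- c(p1, p2, p3, 1 - p1 - p2 - p3)
    for (truth in pair) {
      four_way <- disease_labels()[which.max(p)]
      if (four_way == truth) {
        expect_equal(forced_binary(p, pair), truth)
      }
    }
  }
})

test_that("confusion matrices are row-normalised percentages", {
  truths <- c(rep("WS", 10), rep("22q", 5))
  preds <- c(rep("WS", 7), rep("22q", 3), rep("22q", 5))
  m <- confusion_matrix(preds, truths)
  expect_equal(unname(m["WS", ]), c(70, 30, 0, 0))
  expect_equal(unname(m["22q", ]), c(0, 100, 0, 0))
  perfect <- confusion_matrix(disease_labels(), disease_labels())
  expect_equal(unname(diag(perfect)), rep(100, 4))
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix("WS", "plague"), "cover")
})

test_that("confusion matrix agrees with an independent tally", {
  set.seed(7)
  truths <- sample(disease_labels(), 200, replace = TRUE)
  preds <- sample(disease_labels(), 200, replace = TRUE)
  m <- confusion_matrix(preds, truths)
  for (t in disease_labels()) {
    for (p in disease_labels()) {
      manual <- 100 * sum(truths == t & preds == p) / sum(truths == t)
      expect_equal(m[t, p], manual, tolerance = 1e-8)
    }
  }
  expect_true(all(abs(rowSums(m) - 100) < 1e-8))
})
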