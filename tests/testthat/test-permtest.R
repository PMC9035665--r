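test_that("map embeddings are deterministic and sized as configured", {
  emb <- map_embedder("projection", dim = 32, seed = 5)
  maps <- random_maps(2, g = 7, seed = 1)
  e1 <- embed_map(emb, maps[[1]])
  e2 <- embed_map(emb, maps[[1]])
  expect_identical(e1, e2)
  expect_length(e1, 32)
  expect_equal(sqrt(sum((e1 - embed_map(emb, maps[[1]]))^2)), 0)
  bad <- maps[[2]]; bad$grid[1] <- NA
  expect_error(embed_map(emb, bad), "non-finite")
})

test_that("random projection approximately preserves map distances", {
  # Johnson-Lindenstrauss: embedding distance ~ raw distance over many pairs
  emb <- map_embedder("projection", dim = 64, seed = 2)
  set.seed(11)
  ratios <- replicate(100, {
    m1 <- make_map(matrix(rnorm(49), 7, 7))
    m2 <- make_map(matrix(rnorm(49), 7, 7))
    raw <- sqrt(sum((m1$grid - m2$grid)^2))
    emb_d <- sqrt(sum((embed_map(emb, m1) - embed_map(emb, m2))^2))
    emb_d / raw
  })
  expect_gt(mean(ratios), 0.8)
  expect_lt(mean(ratios), 1.2)
  expect_lt(stats::sd(ratios), 0.25)
})

test_that("classifier embedder returns penultimate features of the map image", {
  fx <- fixture_cohort()
  model <- fixture_ensemble()$models[[1]]
  emb <- map_embedder("classifier", model = model)
  maps <- random_maps(1, g = 7, seed = 3)
  e <- embed_map(emb, maps[[1]])
  expect_length(e, model$config$hidden)
  expect_identical(e, embed_map(emb, maps[[1]]))
  expect_error(map_embedder("classifier"), "trained")
})

test_that("identical groups give zero distance and a null rank", {
  emb <- map_embedder("projection", dim = 32, seed = 1)
  maps <- random_maps(10, g = 7, seed = 4)
  res <- age_permutation_test(maps, maps, emb, n_perm = 100, seed = 9)
  expect_equal(res$observed, 0)
  expect_equal(res$rank_fraction, 0)
  expect_false(res$different)
  expect_length(res$null, 100)
})

test_that("rank fractions count strictly smaller null values", {
  expect_equal(rank_fraction(1, c(rep(0, 43), rep(2, 57))), 0.43)
  expect_equal(rank_fraction(10, rep(0, 100)), 1)
  expect_equal(rank_fraction(0, rep(1, 100)), 0)
  # ties sit above the observed unless mid-ranked
  expect_equal(rank_fraction(1, c(0, 1, 1, 2)), 0.25)
  expect_equal(rank_fraction(1, c(0, 1, 1, 2), mid_rank = TRUE), 0.5)
})

test_that("the observed statistic ignores within-group map order", {
  emb <- map_embedder("projection", dim = 32, seed = 1)
  a <- random_maps(10, g = 7, seed = 5)
  b <- random_maps(10, g = 7, seed = 6, shift = 0.5)
  r1 <- age_permutation_test(a, b, emb, n_perm = 10, seed = 1)
  r2 <- age_permutation_test(sample(a), sample(b), emb, n_perm = 10,
                             seed = 1)
  expect_equal(r1$observed, r2$observed, tolerance = 1e-12)
})

test_that("group size mismatches require an explicit override", {
  emb <- map_embedder("projection", dim = 16, seed = 1)
  a <- random_maps(10, g = 5, seed = 1)
  b <- random_maps(8, g = 5, seed = 2)
  expect_error(age_permutation_test(a, b, emb), "sizes differ")
  res <- age_permutation_test(a, b, emb, n_perm = 20, seed = 1,
                              allow_unequal = TRUE)
  expect_length(res$null, 20)
})

test_that("strong group separation is detected with rank near one", {
  emb <- map_embedder("projection", dim = 32, seed = 1)
  a <- random_maps(10, g = 7, seed = 7, shift = 0)
  b <- random_maps(10, g = 7, seed = 8, shift = 3)
  res <- age_permutation_test(a, b, emb, n_perm = 100, seed = 2)
  expect_gte(res$rank_fraction, 0.95)
  expect_true(res$different)
})

test_that("exchangeable maps give approximately uniform rank fractions", {
  emb <- map_embedder("projection", dim = 16, seed = 3)
  set.seed(21)
  fracs <- replicate(60, {
    pool <- lapply(1:20, function(i) make_map(matrix(rnorm(25), 5, 5)))
    res <- age_permutation_test(pool[1:10], pool[11:20], emb, n_perm = 50,
                                seed = sample.int(1e6, 1))
    res$rank_fraction
  })
  ks <- suppressWarnings(stats::ks.test(fracs, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("pairwise age comparisons return one row per bracket pair", {
  emb <- map_embedder("projection", dim = 16, seed = 1)
  maps_by_age <- lapply(seq_along(age_brackets()), function(i) {
    random_maps(5, g = 5, seed = 30 + i)
  })
  names(maps_by_age) <- age_brackets()
  pr <- pairwise_age_ranks(maps_by_age, emb, n_perm = 20, seed = 4)
  expect_equal(nrow(pr), choose(5, 2))
  expect_true(all(pr$rank_fraction >= 0 & pr$rank_fraction <= 1))
  expect_named(pr, c("age_a", "age_b", "rank_fraction", "observed",
                     "different"))
})

test_that("permutation results tidy, glance and plot", {
  emb <- map_embedder("projection", dim = 16, seed = 1)
  a <- random_maps(6, g = 5, seed = 1)
  b <- random_maps(6, g = 5, seed = 2)
  res <- age_permutation_test(a, b, emb, n_perm = 30, seed = 3)
  expect_equal(nrow(tidy(res)), 30)
  g <- glance(res)
  expect_named(g, c("observed", "rank_fraction", "n_perm", "alpha",
                    "different"))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
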