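test_that("factorized conditions concatenate age and disease rows", {
  tab <- embedding_table(256, 256, seed = 1)
  v <- make_condition(tab, c(1, 0, 0, 0, 0), c(1, 0, 0, 0))
  expect_length(v, 512)
  expect_equal(v, c(tab$age["infant", ], tab$disease["WS", ]),
               ignore_attr = TRUE)
  # midpoint of two age rows
  tab2 <- embedding_table(8, 8, seed = 2)
  mid <- make_condition(tab2, c(0.5, 0, 0, 0, 0.5), c(0, 1, 0, 0))
  expect_equal(mid[1:8],
               (tab2$age["infant", ] + tab2$age["older_adult", ]) / 2,
               ignore_attr = TRUE)
})

test_that("condition construction is exactly linear in the coefficients", {
  tab <- embedding_table(16, 16, seed = 3)
  set.seed(4)
  for (i in 1:10) {
    w1 <- as.vector(stats::rgamma(5, 1)); w1 <- w1 / sum(w1)
    w2 <- as.vector(stats::rgamma(5, 1)); w2 <- w2 / sum(w2)
    d1 <- as.vector(stats::rgamma(4, 1)); d1 <- d1 / sum(d1)
    d2 <- as.vector(stats::rgamma(4, 1)); d2 <- d2 / sum(d2)
    al <- runif(1)
    lhs <- make_condition(tab, al * w1 + (1 - al) * w2,
                          al * d1 + (1 - al) * d2)
    rhs <- al * make_condition(tab, w1, d1) +
      (1 - al) * make_condition(tab, w2, d2)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_error(make_condition(tab, c(0.5, 0.5, 0.1, 0, 0), c(1, 0, 0, 0)),
               "sum to 1")
  expect_error(make_condition(tab, c(1, 0, 0, 0, 0), c(2, -1, 0, 0)),
               "nonnegative")
})

test_that("type-1 counts follow the per-disease bracket mean", {
  spec <- tiny_spec()
  counts <- tibble::tibble(
    disease = rep("WS", 5), age = age_brackets(),
    n = c(10L, 20L, 30L, 20L, 20L))
  m <- generate_cohort(spec, counts, seed = 1, render = FALSE)
  t1 <- type1_counts(m)
  expect_equal(unique(t1$n), 20)
  expect_equal(sum(t1$n), 100)   # matches the study count of the disease
  # rare-bracket upsampling with round-half-even: mean 7.8 -> 8
  counts2 <- tibble::tibble(
    disease = rep("22q", 5), age = age_brackets(),
    n = c(1L, 1L, 1L, 1L, 35L))
  m2 <- generate_cohort(spec, counts2, seed = 1, render = FALSE)
  t2 <- type1_counts(m2)
  expect_equal(unique(t2$n), 8)
})

test_that("type-1 generation emits fresh latents and one-hot labels", {
  gan <- fixture_gan_raw()
  fx <- fixture_cohort()
  small <- fx$study[fx$study$disease == "WS", ][1:10, ]
  g1 <- generate_type1(gan, small, seed = 5)
  expect_equal(nrow(g1), sum(type1_counts(small)$n))
  expect_true(all(g1$provenance == "generated"))
  expect_true(all(g1$p_ws == 1))
  expect_false(any(duplicated(g1$path)))
  # images from different latents differ
  expect_false(identical(g1$image[[1]], g1$image[[2]]))
  # generator contract: shape and range
  expect_equal(dim(g1$image[[1]]), c(32, 32, 3))
  expect_true(all(g1$image[[1]] >= 0 & g1$image[[1]] <= 1))
})

test_that("type-2 sets share a latent across the five brackets", {
  gan <- fixture_gan_raw()
  g2 <- generate_type2(gan, "22q", seed = 8)
  expect_equal(nrow(g2), 5)
  expect_setequal(g2$age, age_brackets())
  expect_true(all(g2$p_22q == 1))
  # definitional identity with direct generation
  z <- gan_latent(gan, 1, seed = 8)[, 1]
  direct <- gan_generate(gan, one_hot_vec("child", age_brackets()),
                         one_hot_vec("22q", disease_labels()), z)[[1]]
  expect_identical(g2$image[[which(g2$age == "child")]], direct)
})

test_that("type-3 interpolates three equally spaced interior age vectors", {
  gan <- fixture_gan_raw()
  g3 <- generate_type3(gan, "WS", seed = 9)
  expect_equal(nrow(g3), 5)
  expect_equal(g3$infant_weight, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(diff(g3$infant_weight), rep(-0.25, 4))
  expect_equal(g3$age, age_brackets())
  # endpoints coincide with type-2 outputs at infant / older adult
  g2 <- generate_type2(gan, "WS", seed = 9)
  expect_identical(g3$image[[1]], g2$image[[1]])
  expect_identical(g3$image[[5]], g2$image[[5]])
  # condition-space distance from the infant endpoint strictly increases
  cond <- lapply(g3$infant_weight, function(w) {
    ac <- numeric(5); ac[1] <- w; ac[5] <- 1 - w
    make_condition(gan$table, ac, one_hot_vec("WS", disease_labels()))
  })
  d0 <- vapply(cond, function(v) sqrt(sum((v - cond[[1]])^2)), numeric(1))
  expect_true(all(diff(d0) > 0))
})

test_that("type-4 blends carry the matching soft labels", {
  gan <- fixture_gan_raw()
  g4 <- generate_type4(gan, "child", c_main = 0.55, main = "WS", seed = 10)
  expect_equal(nrow(g4), 3)
  expect_setequal(g4$partner, c("22q", "control", "unaffected"))
  row_22q <- g4[g4$partner == "22q", ]
  expect_equal(as.numeric(row_22q[, c("p_ws", "p_22q", "p_control",
                                      "p_unaffected")]),
               c(0.55, 0.45, 0, 0))
  expect_true(all(abs(g4$p_ws + g4$p_22q + g4$p_control +
                        g4$p_unaffected - 1) < 1e-9))
  g4b <- generate_type4(gan, "child", c_main = 0.75, main = "22q", seed = 10)
  expect_equal(as.numeric(
    g4b[g4b$partner == "WS", c("p_ws", "p_22q")]), c(0.25, 0.75))
  expect_error(generate_type4(gan, "child", c_main = 1), "inside")
  expect_error(generate_type4(gan, "child", c_main = 0), "inside")
  # the blend condition converges to the pure main condition as c -> 1
  z <- gan_latent(gan, 1, seed = 1)[, 1]
  pure <- gan_generate(gan, one_hot_vec("child", age_brackets()),
                       one_hot_vec("WS", disease_labels()), z)[[1]]
  near <- generate_type4(gan, "child", z = z, c_main = 0.999)
  img_near <- near$image[[which(near$partner == "22q")]]
  expect_lt(mean(abs(img_near - pure)), 0.005)
})

test_that("generation is reproducible from the seed", {
  gan <- fixture_gan_raw()
  a <- generate_type3(gan, "control", seed = 77)
  b <- generate_type3(gan, "control", seed = 77)
  expect_identical(a$image, b$image)
})

test_that("training keeps batches balanced and audits embedding gradients", {
  gan <- fixture_gan()
  expect_true(all(gan$batch_affected_fraction == 0.5))
  # every (age, disease) cell present in the data pushed gradient into its
  # age-embedding row: the shared age matrix is trained by all diseases
  expect_true(all(gan$age_grad_audit > 0))
  expect_equal(dim(gan$age_grad_audit), c(5, 4))
})

test_that("discriminator separation emerges and then narrows", {
  gan <- fixture_gan()
  gap <- gan$trace$d_real - gan$trace$d_fake
  early_max <- max(gap[seq_len(length(gap) / 2)])
  late <- mean(abs(utils::tail(gap, 50)))
  expect_gt(early_max, 0.1)   # the discriminator learned to separate
  expect_lt(late, early_max)  # and the generator closed most of the gap
  expect_true(all(is.finite(gan$trace$g_loss)))
})

test_that("type-2 sets persist latent-specific appearance", {
  # images within one set differ only by age; images from two different
  # latents differ by identity as well, so the mean within-set pairwise
  # distance must fall below the mean set-to-set distance
  gan <- fixture_gan()
  within <- between <- numeric(0)
  for (r in 1:20) {
    s1 <- generate_type2(gan, "WS", seed = r)
    s2 <- generate_type2(gan, "WS", seed = 1000 + r)
    m1 <- sapply(s1$image, as.vector)
    m2 <- sapply(s2$image, as.vector)
    within <- c(within, mean(dist(t(m1))))
    db <- 0
    for (i in 1:5) for (j in 1:5) db <- db + sqrt(sum((m1[, i] - m2[, j])^2))
    between <- c(between, db / 25)
  }
  expect_lt(mean(within), mean(between))
})

test_that("training is reproducible from the seed", {
  fx <- fixture_cohort()
  cfg <- gan_config(iters = 5, hidden_g = 16, hidden_d = 8, batch = 8)
  g1 <- train_gan(fx$study, fx$aux, config = cfg, seed = 55)
  g2 <- train_gan(fx$study, fx$aux, config = cfg, seed = 55)
  expect_identical(g1$G, g2$G)
  expect_identical(g1$table$age, g2$table$age)
  expect_identical(g1$trace, g2$trace)
})

test_that("degenerate GAN inputs are rejected", {
  fx <- fixture_cohort()
  only_aff <- fx$study
  expect_error(train_gan(only_aff[0, ], fx$aux), "no affected")
  expect_error(train_gan(only_aff, fx$aux[0, ]), "no unaffected")
  wrong_size <- fx$study
  expect_error(train_gan(wrong_size, fx$aux,
                         config = gan_config(image_size = 64, iters = 2)),
               "image_size")
})
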