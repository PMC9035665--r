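test_that("rendering is deterministic and bounded", {
  spec <- tiny_spec()
  a <- render_image(spec, "WS", "child", identity = 3, seed = 11)
  b <- render_image(spec, "WS", "child", identity = 3, seed = 11)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(dim(a), c(32, 32, 3))
  d <- render_image(spec, "WS", "child", identity = 3, seed = 12)
  expect_false(identical(a, d))
  expect_error(render_image(spec, "WSX", "child"), "unknown disease")
  expect_error(render_image(spec, "WS", "toddler"), "unknown age")
})

test_that("unaffected images are the bare baseline template", {
  spec <- tiny_spec(noise_sd = 0)
  u1 <- render_image(spec, "unaffected", "child", identity = 1, seed = 1)
  u2 <- render_image(spec, "unaffected", "child", identity = 99, seed = 42)
  # no features and no noise: identity and seed cannot matter
  expect_identical(u1, u2)
  # a WS render differs from the baseline only inside WS feature regions
  w <- render_image(spec, "WS", "child", identity = 1, seed = 1)
  diff <- abs(w - u1)
  regions <- lapply(default_features()$WS, function(f) f$region)
  outside <- array(TRUE, dim = dim(diff))
  for (r in regions) {
    rows <- (round(r[1] * 31) + 1):(round(r[2] * 31) + 1)
    cols <- (round(r[3] * 31) + 1):(round(r[4] * 31) + 1)
    outside[rows, cols, ] <- FALSE
  }
  expect_equal(max(diff[outside]), 0)
  expect_gt(max(diff[!outside]), 0.1)
})

test_that("age-specific features fade according to their age profile", {
  spec <- tiny_spec(noise_sd = 0)
  # the WS mouth feature has profile (1, 1, 1, 0.3, 0.2)
  young <- render_image(spec, "WS", "infant", identity = 1, seed = 1)
  old <- render_image(spec, "WS", "older_adult", identity = 1, seed = 1)
  f <- default_features()$WS[[2]]
  rows <- (round(f$region[1] * 31) + 1):(round(f$region[2] * 31) + 1)
  cols <- (round(f$region[3] * 31) + 1):(round(f$region[4] * 31) + 1)
  inside <- mean(abs(young - old)[rows, cols, ])
  mask <- array(TRUE, dim = dim(young))
  mask[rows, cols, ] <- FALSE
  outside <- mean(abs(young - old)[mask])
  expect_gt(inside, outside)
  expect_gt(inside, (f$age_profile[1] - f$age_profile[5]) * f$intensity / 2)
})

test_that("age-constant specs render identically across brackets", {
  spec <- spec_age_constant(tiny_spec(noise_sd = 0))
  imgs <- lapply(age_brackets(), function(a) {
    render_image(spec, "22q", a, identity = 1, seed = 1)
  })
  for (i in 2:5) expect_identical(imgs[[1]], imgs[[i]])
})

test_that("cohort generation honours per-cell counts and conservation", {
  spec <- tiny_spec()
  counts <- tibble::tibble(
    disease = c("WS", "22q"), age = "older_adult", n = c(39L, 35L))
  m <- generate_cohort(spec, counts, seed = 1, render = FALSE)
  tal <- table(m$disease)
  expect_equal(unname(tal[["WS"]]), 39)
  expect_equal(unname(tal[["22q"]]), 35)
  expect_equal(nrow(m), sum(counts$n))
  expect_false(any(duplicated(m$identity)))
  expect_false(any(duplicated(m$path)))
  # soft labels are consistent one-hots
  expect_true(all(abs(m$p_ws + m$p_22q + m$p_control + m$p_unaffected - 1)
                  < 1e-9))
  expect_true(all(m$p_ws[m$disease == "WS"] == 1))

  empty <- generate_cohort(spec, dplyr::mutate(counts, n = 0L), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(generate_cohort(spec, dplyr::mutate(counts, n = -1L)),
               "nonnegative")
})

test_that("cohorts are reproducible byte-for-byte under a fixed seed", {
  spec <- tiny_spec()
  counts <- tibble::tibble(disease = "control", age = "child", n = 4L)
  m1 <- generate_cohort(spec, counts, seed = 7)
  m2 <- generate_cohort(spec, counts, seed = 7)
  expect_identical(m1$image, m2$image)
  expect_identical(m1$path, m2$path)
})

test_that("auxiliary pools are all-unaffected with requested age tallies", {
  spec <- tiny_spec()
  pool <- generate_auxiliary_pool(spec, rep(6L, 5), seed = 3, render = FALSE)
  expect_equal(nrow(pool), 30)
  expect_true(all(pool$disease == "unaffected"))
  expect_equal(unname(table(pool$age)[age_brackets()]), rep(6L, 5),
               ignore_attr = TRUE)
  expect_true(all(pool$provenance == "auxiliary"))
})

test_that("with zero noise a nearest-centroid oracle attains 100% accuracy", {
  spec <- tiny_spec(noise_sd = 0)
  train <- generate_cohort(spec, balanced_counts(3, disease_labels()),
                           seed = 21)
  test <- generate_cohort(spec, balanced_counts(2, disease_labels()),
                          seed = 22, start_identity = 10000L)
  cents <- sapply(disease_labels(), function(d) {
    rowMeans(sapply(train$image[train$disease == d], as.vector))
  })
  pred <- vapply(test$image, function(img) {
    disease_labels()[which.min(colSums((cents - as.vector(img))^2))]
  }, character(1))
  expect_equal(mean(pred == test$disease), 1)
})

test_that("grayscale rendering replicates one channel", {
  spec <- phenotype_spec(image_size = 32, noise_sd = 0.05,
                         grayscale_fraction = 1)
  img <- render_image(spec, "WS", "child", identity = 1, seed = 5)
  expect_identical(img[, , 1], img[, , 2])
  expect_identical(img[, , 2], img[, , 3])
})

test_that("manifests round-trip through re-rendering and CSV", {
  spec <- tiny_spec()
  counts <- tibble::tibble(disease = "WS", age = "infant", n = 3L)
  full <- generate_cohort(spec, counts, seed = 9)
  slim <- generate_cohort(spec, counts, seed = 9, render = FALSE)
  rerendered <- render_manifest(slim, spec, seed = 9)
  expect_identical(rerendered$image, full$image)

  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_manifest(full, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(nrow(back), 3)
  expect_named(back, c("path", "disease", "age", "identity", "provenance",
                       "p_ws", "p_22q", "p_control", "p_unaffected"))
})

test_that("invalid phenotype specs are rejected", {
  expect_error(phenotype_spec(image_size = 16), "image_size")
  expect_error(phenotype_spec(noise_sd = -1), "noise_sd")
  bad <- default_features()
  bad$unaffected <- bad$WS
  expect_error(phenotype_spec(features = bad), "unaffected")
  bad2 <- default_features()
  bad2$WS[[1]]$age_profile <- c(2, 1, 1, 1, 1)
  expect_error(phenotype_spec(features = bad2), "age_profile")
})
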