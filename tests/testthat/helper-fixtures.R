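# Shared fixtures, built once per test run and memoised.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

one_hot_vec <- function(label, levels) as.numeric(levels == label)

tiny_spec <- function(noise_sd = 0.04) {
  phenotype_spec(image_size = 32, noise_sd = noise_sd,
                 grayscale_fraction = 0, identity_jitter_sd = 0)
}

balanced_counts <- function(n = 6, diseases = c("WS", "22q", "control")) {
  tidyr::crossing(disease = diseases, age = age_brackets()) |>
    dplyr::mutate(n = n)
}

# small study cohort (undersampled older brackets, as in the study design),
# auxiliary pool, and a held-out test set
fixture_cohort <- function() {
  memo("cohort", {
    spec <- tiny_spec()
    counts <- tibble::tibble(
      disease = rep(c("WS", "22q", "control"), each = 5),
      age = rep(age_brackets(), 3),
      n = c(8L, 9L, 8L, 6L, 5L,
            7L, 9L, 8L, 6L, 5L,
            7L, 7L, 7L, 7L, 7L))
    study <- generate_cohort(spec, counts, seed = 101)
    aux <- generate_auxiliary_pool(spec, rep(12, 5), seed = 102)
    test <- generate_cohort(
      spec,
      dplyr::bind_rows(balanced_counts(3),
                       tibble::tibble(disease = "unaffected",
                                      age = age_brackets(), n = 3)),
      seed = 103, start_identity = 50000L)
    list(spec = spec, study = study, aux = aux, test = test)
  })
}

fixture_ensemble <- function() {
  memo("ensemble", {
    fx <- fixture_cohort()
    folds <- make_cv_folds(fx$study, k = 5, seed = 104)
    train_cv_ensemble(fx$study, folds, aux = fx$aux,
                      config = clf_config(pool = 8, hidden = 12, maxit = 200),
                      seed = 105)
  })
}

# one trained desk GAN shared by every test that needs trained behaviour
fixture_gan <- function() {
  memo("gan", {
    fx <- fixture_cohort()
    train_gan(fx$study, fx$aux, config = gan_config(iters = 3000),
              seed = 106)
  })
}

# an essentially untrained GAN for structural generation tests
fixture_gan_raw <- function() {
  memo("gan_raw", {
    fx <- fixture_cohort()
    train_gan(fx$study, fx$aux,
              config = gan_config(iters = 3, batch = 8,
                                  hidden_g = 16, hidden_d = 8),
              seed = 107)
  })
}

# deterministic mock classifier whose predictions are a fixed function of
# the image; used to probe occlusion attribution independently of training
patch_model <- function(rows, cols, resolution = 32) {
  structure(list(rows = rows, cols = cols, resolution = resolution),
            class = c("patch_model"))
}

predict.patch_model <- function(object, newdata, ...) {
  images <- if (is.list(newdata) && !is.data.frame(newdata)) newdata
            else list(newdata)
  p <- vapply(images, function(img) {
    mean(img[object$rows, object$cols, ])
  }, numeric(1))
  p <- pmin(pmax(p, 0), 1)
  tibble::tibble(p_ws = p, p_22q = (1 - p) / 3, p_control = (1 - p) / 3,
                 p_unaffected = (1 - p) / 3)
}

constant_model <- function() structure(list(), class = "constant_model")

predict.constant_model <- function(object, newdata, ...) {
  n <- if (is.list(newdata) && !is.data.frame(newdata)) length(newdata) else 1
  tibble::tibble(p_ws = rep(0.4, n), p_22q = 0.3, p_control = 0.2,
                 p_unaffected = 0.1)
}

# synthetic saliency map with a given grid
make_map <- function(grid, target = "WS", window = 8L, stride = 4L,
                     image_size = 32L) {
  structure(list(grid = grid, window = window, stride = stride,
                 target = target, image_size = image_size, n = 1L),
            class = "saliency_map")
}

random_maps <- function(n, g = 7, seed = 1, shift = 0) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    make_map(matrix(rnorm(g * g, mean = shift), g, g))
  })
}

registerS3method("predict", "patch_model", predict.patch_model,
                 envir = asNamespace("stats"))
registerS3method("predict", "constant_model", predict.constant_model,
                 envir = asNamespace("stats"))
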