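#' Experiment configuration
#'
#' Bundles every stage's settings with a single master seed. The `desk`
#' preset runs the full pipeline in minutes on one CPU (64 px classifier
#' images, 32 px GAN, small imbalanced cohort); `full_scale` mirrors the
#' reference design's dimensions (448 px classifier input, 256 px GAN,
#' 256/256 embeddings, 500 auxiliary images per bracket) and is intended for
#' heavyweight runs, not for routine testing.
#'
#' @param preset `"desk"` or `"full_scale"`.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory (created; default a tempdir subdirectory).
#' @param use_gan Train the GAN and augmentation variants (`TRUE`) or skip
#'   the augmentation stage entirely.
#' @param gan_types Which fake-image schemes to train augmentation variants
#'   for (subset of 1:4).
#' @param ... Overrides for individual fields of the preset.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("desk", "full_scale"), seed = 1L,
                              out_dir = NULL, use_gan = TRUE,
                              gan_types = c(1L, 3L), ...) {
  preset <- match.arg(preset)
  base <- list(
    seed = as.integer(seed),
    out_dir = out_dir %||% file.path(tempdir(),
                                     sprintf("agefaces-exp-%d", seed)),
    use_gan = use_gan,
    gan_types = gan_types,
    image_size = 64L,
    gan_image_size = 32L,
    noise_sd = 0.04,
    train_counts = desk_train_counts(),
    test_per_cell = 10L,
    aux_per_bracket = 30L,
    k_folds = 5L,
    clf = clf_config(pool = 8L, hidden = 16L, maxit = 250L),
    gan = gan_config(image_size = 32L, iters = 3000L),
    window = 16L,
    stride = 8L,
    n_perm = 100L,
    n_raters = 15L,
    rater_difficulty = desk_rater_difficulty(),
    c_blend = 0.55
  )
  if (preset == "full_scale") {
    base$image_size <- 448L
    base$gan_image_size <- 256L
    base$clf <- clf_config(pool = 16L, hidden = 64L, maxit = 500L)
    base$gan <- gan_config(image_size = 256L, e_d = 256L, e_a = 256L,
                           iters = 20000L, aux_per_bracket = 500L)
    base$aux_per_bracket <- 600L
    base$window <- 20L
    base$stride <- 10L
  }
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  structure(base, class = "experiment_config")
}

# Small imbalanced study cohort: rarer older brackets, WS/22q/control only
# (unaffected training images come from the auxiliary pool).
desk_train_counts <- function() {
  tibble::tibble(
    disease = rep(c("WS", "22q", "control"), each = 5),
    age = rep(age_brackets(), 3),
    n = c(8, 10, 8, 5, 4,
          7, 10, 8, 5, 4,
          8, 8, 8, 8, 8)
  )
}

# Human rater difficulty per cell, echoing the qualitative pattern of a
# panel study: harder on infants and older adults, easier on adolescents.
desk_rater_difficulty <- function() {
  tibble::tibble(
    disease = rep(c("WS", "22q", "control"), each = 5),
    age = rep(age_brackets(), 3),
    accuracy = c(0.67, 0.71, 0.81, 0.74, 0.71,
                 0.54, 0.53, 0.67, 0.61, 0.51,
                 0.75, 0.60, 0.52, 0.60, 0.59)
  )
}

#' Run the full pipeline end to end
#'
#' Executes synthetic-cohort generation, auxiliary split, stratified folds,
#' ensemble training, (optionally) GAN training with the requested
#' augmentation variants, test-set evaluation with confusion matrices and
#' the augmentation comparison table, per-cell composite saliency with the
#' pairwise age permutation tests, and the simulated-survey human-vs-model
#' statistics. Every artifact (manifests, predictions, tables, JSON results)
#' is written under `config$out_dir`, together with a `run.json` manifest of
#' stage seeds and files; the same master seed reproduces the same outputs.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, a list with the main results (`test_predictions`,
#'   `confusion`, `augmentation` (or `NULL` when the GAN stage is skipped),
#'   `age_ranks`, `survey`, `out_dir`).
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_lines <- character()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[agefaces] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  # --- data ---
  spec <- phenotype_spec(image_size = config$image_size,
                         noise_sd = config$noise_sd)
  study <- generate_cohort(spec, config$train_counts,
                           seed = derive_seed(seed, 1))
  test_counts <- dplyr::bind_rows(
    dplyr::mutate(config$train_counts, n = config$test_per_cell),
    tibble::tibble(disease = "unaffected", age = age_brackets(),
                   n = config$test_per_cell)
  )
  test <- generate_cohort(spec, test_counts, seed = derive_seed(seed, 2),
                          start_identity = 50000L)
  aux <- generate_auxiliary_pool(spec, rep(config$aux_per_bracket, 5),
                                 seed = derive_seed(seed, 3))
  write_manifest(study, file.path(config$out_dir, "study_manifest.csv"))
  write_manifest(test, file.path(config$out_dir, "test_manifest.csv"))
  note("cohort: %d study, %d test, %d auxiliary images",
       nrow(study), nrow(test), nrow(aux))

  split <- split_auxiliary(aux, seed = derive_seed(seed, 4))
  folds <- make_cv_folds(study, k = config$k_folds,
                         seed = derive_seed(seed, 5))
  write_partition_json(folds, file.path(config$out_dir, "folds.json"))

  # --- classifier ensemble on real images ---
  aux_train <- aux[split$train, ]
  ensemble <- train_cv_ensemble(study, folds, aux = aux_train,
                                config = config$clf,
                                seed = derive_seed(seed, 6))
  preds <- ensemble_predict(ensemble, test)
  preds$path <- test$path
  preds$truth <- test$disease
  preds$age <- test$age
  utils::write.csv(
    as.data.frame(preds[, c("path", "p_ws", "p_22q", "p_control",
                            "p_unaffected", "label", "truth", "age")]),
    file.path(config$out_dir, "test_predictions_real.csv"),
    row.names = FALSE)
  conf <- confusion_matrix(preds$label, test$disease)
  utils::write.csv(as.data.frame(conf),
                   file.path(config$out_dir, "confusion_real.csv"))
  note("ensemble (real images): overall test accuracy %.1f%%",
       100 * mean(preds$label == test$disease))

  # --- GAN augmentation variants ---
  augmentation <- NULL
  if (isTRUE(config$use_gan)) {
    gspec <- phenotype_spec(image_size = config$gan_image_size,
                            noise_sd = config$noise_sd)
    gstudy <- generate_cohort(gspec, config$train_counts,
                              seed = derive_seed(seed, 1))
    gaux <- generate_auxiliary_pool(gspec, rep(config$aux_per_bracket, 5),
                                    seed = derive_seed(seed, 3))
    gan <- train_gan(gstudy, gaux, config = config$gan,
                     seed = derive_seed(seed, 7))
    note("GAN trained: %d iterations, final D(real) %.2f / D(fake) %.2f",
         config$gan$iters,
         mean(utils::tail(gan$trace$d_real, 10)),
         mean(utils::tail(gan$trace$d_fake, 10)))

    variants <- list(real = preds$label)
    type_names <- c("unrelated", "age_related", "age_prog", "blended")
    for (ty in config$gan_types) {
      gen <- generate_augmentation(gan, gstudy, type = ty,
                                   c_main = config$c_blend,
                                   seed = derive_seed(seed, 8 + ty))
      # re-render generated images at classifier resolution via nearest
      # neighbour so all training tensors share one shape
      gen$image <- lapply(gen$image, resize_nn, config$image_size)
      ens_aug <- train_cv_ensemble(study, folds, aux = aux_train,
                                   generated = gen, config = config$clf,
                                   seed = derive_seed(seed, 20 + ty))
      pa <- ensemble_predict(ens_aug, test)
      nm <- type_names[ty]
      variants[[nm]] <- pa$label
      note("augmentation +%s: overall test accuracy %.1f%%", nm,
           100 * mean(pa$label == test$disease))
    }
    augmentation <- augmentation_comparison(variants, test$disease)
    utils::write.csv(as.data.frame(augmentation),
                     file.path(config$out_dir, "augmentation_comparison.csv"),
                     row.names = FALSE)
  } else {
    note("GAN stage disabled: augmentation comparison skipped")
  }

  # --- saliency + permutation tests ---
  embedder <- map_embedder("projection", dim = 64L,
                           seed = derive_seed(seed, 30))
  age_ranks <- list()
  for (d in c("WS", "22q")) {
    maps_by_age <- lapply(age_brackets(), function(a) {
      rows <- which(test$disease == d & test$age == a)
      lapply(rows, function(i) {
        ensemble_saliency(ensemble, test$image[[i]], target = d,
                          window = config$window, stride = config$stride)
      })
    })
    names(maps_by_age) <- age_brackets()
    for (a in age_brackets()) {
      comp <- composite_saliency(maps_by_age[[a]], disease = d, age = a)
      utils::write.csv(comp$grid,
                       file.path(config$out_dir,
                                 sprintf("composite_saliency_%s_%s.csv", d, a)),
                       row.names = FALSE)
    }
    pr <- pairwise_age_ranks(maps_by_age, embedder, n_perm = config$n_perm,
                             seed = derive_seed(seed, 31))
    pr$disease <- d
    age_ranks[[d]] <- pr
  }
  age_ranks <- dplyr::bind_rows(age_ranks)
  utils::write.csv(as.data.frame(age_ranks),
                   file.path(config$out_dir, "age_rank_fractions.csv"),
                   row.names = FALSE)
  note("permutation tests: %d age-pair comparisons per disease",
       choose(5, 2))

  # --- simulated survey vs model ---
  raters <- simulate_raters(config$rater_difficulty,
                            n_raters = config$n_raters,
                            n_images = config$test_per_cell,
                            seed = derive_seed(seed, 40))
  human_cells <- per_cell_accuracy(raters)
  model_rows <- preds[preds$truth != "unaffected", ]
  pair_for <- function(d) if (d == "22q") c("22q", "control") else
    c("WS", "control")
  model_correct <- vapply(seq_len(nrow(model_rows)), function(i) {
    pr4 <- as.numeric(model_rows[i, c("p_ws", "p_22q", "p_control",
                                      "p_unaffected")])
    pick <- forced_binary(pr4, pair_for(model_rows$truth[i]))
    as.integer(pick == model_rows$truth[i])
  }, integer(1))
  model_tbl <- tibble::tibble(
    disease = model_rows$truth, age = model_rows$age,
    image = stats::ave(seq_len(nrow(model_rows)),
                       paste(model_rows$truth, model_rows$age),
                       FUN = seq_along),
    correct = model_correct)
  model_cells <- per_cell_accuracy(model_tbl)
  survey <- dplyr::left_join(
    dplyr::rename(human_cells, human = "accuracy"),
    dplyr::rename(model_cells[, c("disease", "age", "accuracy")],
                  model = "accuracy"),
    by = c("disease", "age"))
  survey$p_perm <- vapply(seq_len(nrow(survey)), function(i) {
    cell <- raters[raters$disease == survey$disease[i] &
                     raters$age == survey$age[i], ]
    block <- matrix(cell$correct[order(cell$image, cell$rater)],
                    nrow = config$n_raters)
    mc <- model_tbl$correct[model_tbl$disease == survey$disease[i] &
                              model_tbl$age == survey$age[i]]
    cell_permutation_pvalue(block, mc, n_perm = 1000L,
                            seed = derive_seed(seed, 50 + i))$p_value
  }, numeric(1))
  utils::write.csv(as.data.frame(survey),
                   file.path(config$out_dir, "survey_vs_model.csv"),
                   row.names = FALSE)

  per_image_human <- raters |>
    dplyr::group_by(.data$disease, .data$age, .data$image) |>
    dplyr::summarise(human = mean(.data$correct), .groups = "drop")
  joined <- dplyr::inner_join(per_image_human, model_tbl,
                              by = c("disease", "age", "image"))
  tt <- lapply(c("WS", "22q"), function(d) {
    sub <- joined[joined$disease == d, ]
    res <- paired_t_test(sub$correct, sub$human)
    tibble::tibble(disease = d, tidy(res))
  })
  tt <- dplyr::bind_rows(tt)
  utils::write.csv(as.data.frame(tt),
                   file.path(config$out_dir, "paired_t.csv"),
                   row.names = FALSE)

  jsonlite::write_json(
    list(seed = seed, preset_image_size = config$image_size,
         use_gan = isTRUE(config$use_gan), log = log_lines,
         files = list.files(config$out_dir)),
    file.path(config$out_dir, "run.json"), auto_unbox = TRUE)

  invisible(list(test_predictions = preds, confusion = conf,
                 augmentation = augmentation, age_ranks = age_ranks,
                 survey = survey, paired_t = tt, out_dir = config$out_dir))
}

# Nearest-neighbour resize of an RGB array to side n.
resize_nn <- function(img, n) {
  m <- dim(img)[1]
  idx <- pmin(m, pmax(1, ceiling(seq_len(n) / n * m)))
  img[idx, idx, , drop = FALSE]
}
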