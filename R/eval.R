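#' Simulate survey rater responses
#'
#' Stands in for a panel study in which every test image of each
#' (disease-vs-control cohort, age bracket) cell is viewed by a fixed number
#' of raters: each rater's correctness on each image is an independent
#' Bernoulli draw at the cell's difficulty (probability of a correct call).
#'
#' @param difficulty A data frame with columns `disease`, `age` and
#'   `accuracy` (per-cell probability of a correct human call).
#' @param n_raters Raters per image (default 15).
#' @param n_images Test images per cell (default 10).
#' @param seed Integer seed.
#' @return A tibble with columns `disease`, `age`, `image`, `rater`,
#'   `correct` (0/1).
#' @export
simulate_raters <- function(difficulty, n_raters = 15L, n_images = 10L,
                            seed = 1L) {
  difficulty <- tibble::as_tibble(difficulty)
  stopifnot(all(c("disease", "age", "accuracy") %in% names(difficulty)))
  with_local_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(nrow(difficulty)), function(i) {
      tibble::tibble(
        disease = difficulty$disease[i],
        age = difficulty$age[i],
        image = rep(seq_len(n_images), each = n_raters),
        rater = rep(seq_len(n_raters), n_images),
        correct = as.integer(runif(n_images * n_raters) <
                               difficulty$accuracy[i])
      )
    }))
  })
}

#' Per-cell accuracy table
#'
#' Mean correctness over (images x raters) within each (disease, age) cell.
#' Works for human rater blocks and for per-image model correctness alike
#' (a model is a single "rater").
#'
#' @param responses A data frame with columns `disease`, `age`, `image`,
#'   `correct` (and optionally `rater`).
#' @return A tibble with `disease`, `age`, `n_images`, `accuracy`.
#' @export
per_cell_accuracy <- function(responses) {
  responses <- tibble::as_tibble(responses)
  stopifnot(all(c("disease", "age", "image", "correct") %in%
                  names(responses)))
  out <- responses |>
    dplyr::group_by(.data$disease, .data$age) |>
    dplyr::summarise(n_images = dplyr::n_distinct(.data$image),
                     accuracy = mean(.data$correct), .groups = "drop")
  if (any(out$n_images == 0)) stop("empty cell", call. = FALSE)
  out
}

#' Paired t-test from the closed form
#'
#' Standard paired t on per-image differences between two raters (e.g. mean
#' human accuracy per image vs model correctness per image):
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p-value. A zero-variance difference vector is flagged as
#' degenerate (`t` is `NA` unless the mean is also 0, in which case `t = 0`,
#' `p = 1`).
#'
#' @param x,y Equal-length numeric vectors (length >= 2), paired by image.
#' @return An object of class `paired_t` with `estimate` (mean difference),
#'   `statistic`, `df`, `p_value`, `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  d <- x - y
  n <- length(d)
  s <- sd(d)
  degenerate <- s == 0
  if (degenerate) {
    statistic <- if (mean(d) == 0) 0 else NA_real_
    p <- if (mean(d) == 0) 1 else NA_real_
  } else {
    statistic <- mean(d) / (s / sqrt(n))
    p <- 2 * pt(-abs(statistic), df = n - 1)
  }
  structure(list(estimate = mean(d), statistic = statistic, df = n - 1,
                 p_value = p, degenerate = degenerate, n = n),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  if (x$degenerate && is.na(x$statistic)) {
    cat(sprintf("<paired_t> degenerate: zero-variance differences (mean %.4f)\n",
                x$estimate))
  } else {
    cat(sprintf("<paired_t> mean diff %.4f, t = %.3f (df %d), p = %.3g%s\n",
                x$estimate, x$statistic, x$df, x$p_value,
                if (x$degenerate) " [degenerate]" else ""))
  }
  invisible(x)
}

#' @export
tidy.paired_t <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, statistic = x$statistic, df = x$df,
                 p_value = x$p_value, degenerate = x$degenerate)
}

#' Per-cell permutation p-value, model versus human raters
#'
#' Observed statistic: model accuracy minus mean human accuracy over the
#' cell's images. Null: in each permutation round and for each image, the
#' model's correctness is swapped with the response of one uniformly drawn
#' rater, and the statistic is recomputed on the swapped data. The p-value
#' is one-sided (model better), with the add-one convention
#' `p = (1 + #(null >= observed)) / (n_perm + 1)` so p never reaches 0.
#'
#' @param human_block An `n_raters x n_images` 0/1 matrix of rater
#'   correctness.
#' @param model_correct Length-`n_images` 0/1 vector of model correctness.
#' @param n_perm Permutation rounds (default 1000).
#' @param seed Integer seed.
#' @param two_sided Compare `abs(null)` against `abs(observed)` instead.
#' @return A list with `observed`, `p_value`, `n_perm`.
#' @export
cell_permutation_pvalue <- function(human_block, model_correct,
                                    n_perm = 1000L, seed = 1L,
                                    two_sided = FALSE) {
  human_block <- as.matrix(human_block)
  n_images <- ncol(human_block)
  n_raters <- nrow(human_block)
  if (length(model_correct) != n_images) {
    stop("model_correct length must match the block's image count",
         call. = FALSE)
  }
  if (any(is.na(human_block))) stop("incomplete rater block", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  observed <- mean(model_correct) - mean(human_block)
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      hb <- human_block
      mc <- model_correct
      for (i in seq_len(n_images)) {
        r <- sample.int(n_raters, 1)
        tmp <- hb[r, i]
        hb[r, i] <- mc[i]
        mc[i] <- tmp
      }
      mean(mc) - mean(hb)
    }, numeric(1))
  })
  exceed <- if (two_sided) sum(abs(null) >= abs(observed)) else
    sum(null >= observed)
  list(observed = observed,
       p_value = (1 + exceed) / (n_perm + 1),
       n_perm = as.integer(n_perm))
}

#' Compare classifiers trained with different augmentation sets
#'
#' Per-class accuracy (and their macro average) for each prediction variant
#' on a shared test set, in the fixed column layout used for
#' augmentation-type comparisons: the base variant first, then one column
#' per augmentation scheme.
#'
#' @param predictions Named list of character vectors of predicted labels,
#'   one element per variant (e.g. `real`, `unrelated`, `age_related`,
#'   `age_prog`, `blended_55_45`, `blended_75_25`); all on the same test
#'   images.
#' @param truths Character vector of true labels.
#' @param labels Class order, default [disease_labels()].
#' @return A tibble with a `class` column (four classes then `"average"`)
#'   and one accuracy column (percent) per variant.
#' @export
augmentation_comparison <- function(predictions, truths,
                                    labels = disease_labels()) {
  stopifnot(length(predictions) >= 1)
  lens <- vapply(predictions, length, 1L)
  if (any(lens != length(truths))) {
    stop("all variants must predict the same test set", call. = FALSE)
  }
  present <- labels[labels %in% truths]
  cols <- lapply(predictions, function(pred) {
    acc <- vapply(present, function(cl) {
      100 * mean(pred[truths == cl] == cl)
    }, numeric(1))
    c(acc, average = mean(acc))
  })
  out <- tibble::tibble(class = c(present, "average"))
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  out
}
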