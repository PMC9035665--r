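#' Split an auxiliary pool into train and test by age bracket
#'
#' Within each age bracket, `floor(fraction * n_bracket)` rows are chosen
#' uniformly at random as test rows; the rest are train rows. With the
#' default one-sixth fraction and bracket counts divisible by 6 the split is
#' an exact sixth (e.g. a pool of 62,088 with divisible brackets yields
#' 10,348 test and 51,740 train rows).
#'
#' @param manifest An auxiliary cohort manifest (all rows `unaffected`).
#' @param fraction Test fraction in (0, 1); default `1/6`.
#' @param seed Integer seed; the split is reproducible and, up to relabelling,
#'   invariant to row order (indices are shuffled before selection).
#' @return An object of class `aux_split` with integer elements `train` and
#'   `test` indexing into `manifest`.
#' @export
#' @examples
#' spec <- phenotype_spec(image_size = 32)
#' pool <- generate_auxiliary_pool(spec, rep(6, 5), seed = 1, render = FALSE)
#' s <- split_auxiliary(pool, seed = 1)
#' lengths(list(s$train, s$test))
split_auxiliary <- function(manifest, fraction = 1 / 6, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!all(manifest$disease == "unaffected")) {
    stop("auxiliary manifest must contain only unaffected rows", call. = FALSE)
  }
  for (a in unique(manifest$age)) match_label(a, age_brackets(), "age bracket")
  test <- integer(0)
  with_local_seed(seed, {
    for (a in age_brackets()) {
      idx <- which(manifest$age == a)
      if (!length(idx)) next
      k <- floor(fraction * length(idx))
      if (k > 0) test <- c(test, sort(sample(idx, k)))
    }
  })
  test <- sort(test)
  structure(
    list(train = setdiff(seq_len(nrow(manifest)), test), test = test,
         fraction = fraction, n = nrow(manifest)),
    class = "aux_split"
  )
}

#' @export
print.aux_split <- function(x, ...) {
  cat(sprintf("<aux_split> %d train / %d test (fraction %.4f)\n",
              length(x$train), length(x$test), x$fraction))
  invisible(x)
}

#' Stratified k-fold cross-validation partition
#'
#' Assigns study rows to `k` validation folds, stratified by the
#' (disease, age bracket) cell: within each cell, shuffled rows are dealt
#' cyclically to folds starting at a random offset, so per-cell fold sizes
#' differ by at most one. If `k` exceeds the smallest cell size the function
#' warns and falls back to disease-only stratification.
#'
#' @param manifest A study cohort manifest.
#' @param k Number of folds (>= 2), default 5.
#' @param seed Integer seed.
#' @return An object of class `fold_partition`: a list with `k` and `folds`,
#'   where `folds[[i]]` has integer `train` and `validation` indices.
#'   Validation sets are pairwise disjoint and their union is every row.
#' @export
make_cv_folds <- function(manifest, k = 5L, seed = 1L) {
  n <- nrow(manifest)
  if (n == 0) stop("manifest is empty", call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  strata <- paste(manifest$disease, manifest$age, sep = "|")
  cell_sizes <- table(strata)
  if (min(cell_sizes) < k) {
    warning(sprintf(
      "k = %d exceeds the smallest (disease, age) cell (%d rows); %s",
      k, min(cell_sizes), "falling back to disease-only stratification"
    ), call. = FALSE)
    strata <- manifest$disease
  }
  assignment <- integer(n)
  with_local_seed(seed, {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      offset <- sample.int(k, 1) - 1L
      assignment[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    }
  })
  folds <- lapply(seq_len(k), function(i) {
    list(train = which(assignment != i), validation = which(assignment == i))
  })
  structure(list(k = as.integer(k), folds = folds, n = n),
            class = "fold_partition")
}

#' @export
print.fold_partition <- function(x, ...) {
  cat(sprintf("<fold_partition> %d folds over %d rows (validation sizes: %s)\n",
              x$k, x$n,
              paste(vapply(x$folds, function(f) length(f$validation), 1L),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname make_cv_folds
#' @param x A `fold_partition` or `aux_split`.
#' @param path Output JSON path.
#' @export
write_partition_json <- function(x, path) {
  if (inherits(x, "fold_partition")) {
    obj <- list(k = x$k,
                folds = lapply(x$folds, function(f)
                  list(train = f$train, validation = f$validation)))
  } else if (inherits(x, "aux_split")) {
    obj <- list(train = x$train, test = x$test)
  } else {
    stop("unsupported partition object", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @export
tidy.fold_partition <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(x$k), function(i) {
    tibble::tibble(fold = i,
                   n_train = length(x$folds[[i]]$train),
                   n_validation = length(x$folds[[i]]$validation))
  }))
}

#' @export
tidy.aux_split <- function(x, ...) {
  tibble::tibble(split = c("train", "test"),
                 n = c(length(x$train), length(x$test)))
}
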