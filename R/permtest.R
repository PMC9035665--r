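#' Saliency-map embedders
#'
#' Builds the function that turns a composite saliency map into a
#' fixed-length feature vector for the age permutation test.
#'
#' Two embedders are provided. `"projection"` is a seeded Gaussian random
#' projection of the flattened attribution grid to `dim` coordinates
#' (scaled by `1/sqrt(dim)`, so by the Johnson--Lindenstrauss property
#' pairwise embedding distances approximate raw map distances); it is fully
#' deterministic and model-free. `"classifier"` renders the map as a
#' 3-channel image (nearest-neighbour upsampling, linear rescale to
#' `[0, 1]`) and takes the penultimate-layer activations of a trained
#' [train_classifier()] model, the desk-scale analogue of embedding maps
#' with a pretrained image backbone.
#'
#' @param method `"projection"` or `"classifier"`.
#' @param dim Output dimension of the projection embedder.
#' @param seed Seed fixing the projection matrix.
#' @param model A `face_classifier`, required for `method = "classifier"`.
#' @return An object of class `map_embedder`.
#' @export
map_embedder <- function(method = c("projection", "classifier"),
                         dim = 64L, seed = 1L, model = NULL) {
  method <- match.arg(method)
  if (method == "classifier" && !inherits(model, "face_classifier")) {
    stop("classifier embedder needs a trained face_classifier", call. = FALSE)
  }
  structure(list(method = method, dim = as.integer(dim),
                 seed = as.integer(seed), model = model,
                 cache = new.env(parent = emptyenv())),
            class = "map_embedder")
}

projection_matrix <- function(embedder, p) {
  key <- as.character(p)
  if (is.null(embedder$cache[[key]])) {
    embedder$cache[[key]] <- with_local_seed(
      derive_seed(embedder$seed, p),
      matrix(rnorm(p * embedder$dim), p, embedder$dim) / sqrt(embedder$dim)
    )
  }
  embedder$cache[[key]]
}

#' Embed a saliency map
#'
#' @param embedder A [map_embedder()].
#' @param map A `saliency_map` (typically a composite) with finite values.
#' @return A numeric feature vector (length `dim` for the projection
#'   embedder; the classifier's hidden width otherwise). Deterministic:
#'   identical maps give identical embeddings.
#' @export
embed_map <- function(embedder, map) {
  stopifnot(inherits(embedder, "map_embedder"),
            inherits(map, "saliency_map"))
  if (!all(is.finite(map$grid))) {
    stop("saliency map contains non-finite values", call. = FALSE)
  }
  if (embedder$method == "projection") {
    v <- as.vector(map$grid)
    as.vector(v %*% projection_matrix(embedder, length(v)))
  } else {
    res <- embedder$model$resolution
    up <- upsample_map(map, res)
    rng <- range(up)
    scaled <- if (diff(rng) > 0) (up - rng[1]) / diff(rng) else up * 0 + 0.5
    img <- array(rep(scaled, 3), dim = c(res, res, 3))
    as.vector(classifier_features(embedder$model, list(img)))
  }
}

mean_map <- function(maps) composite_saliency(maps)

#' Rank fraction of an observed statistic against a permutation null
#'
#' The share of null values strictly below the observed value (ties sit
#' above the observed by this convention; `mid_rank = TRUE` counts half of
#' any exact ties instead).
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of permutation-null values.
#' @param mid_rank Count exact ties as half.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' rank_fraction(1, c(rep(0, 43), rep(2, 57))) # 0.43
rank_fraction <- function(observed, null, mid_rank = FALSE) {
  below <- sum(null < observed)
  if (mid_rank) below <- below + sum(null == observed) / 2
  below / length(null)
}

#' Permutation test for age differences in salient features
#'
#' Tests whether the classifier-salient features of one disease differ
#' between two age groups. The observed statistic is the Euclidean distance
#' between the embeddings of the two groups' composite (mean) saliency maps.
#' The null is built by pooling the `2m` maps, redrawing a random `m / m`
#' split `n_perm` times and recomputing the same statistic. The rank
#' fraction is the share of null distances strictly below the observed
#' distance; the groups are declared different when it exceeds
#' `1 - alpha` (equivalently, not different when the observed distance is
#' smaller than the `alpha` tail of the permutation values).
#'
#' @param maps_a,maps_b Lists of `saliency_map` objects (equal sizes; the
#'   reference design uses 10 + 10), grid shapes consistent.
#' @param embedder A [map_embedder()].
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed for the permutation draws.
#' @param alpha Significance threshold (default 0.05).
#' @param allow_unequal Permit unequal group sizes (permutation then draws
#'   `length(maps_a)` of the pool).
#' @return An object of class `permutation_result`: `observed`, `null`
#'   (length `n_perm`), `rank_fraction`, `different`, plus bookkeeping.
#' @export
age_permutation_test <- function(maps_a, maps_b, embedder, n_perm = 100L,
                                 seed = 1L, alpha = 0.05,
                                 allow_unequal = FALSE) {
  m <- length(maps_a)
  if (!allow_unequal && length(maps_b) != m) {
    stop("group sizes differ; set allow_unequal = TRUE to override",
         call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  pool <- c(maps_a, maps_b)
  stat <- function(idx_a) {
    ea <- embed_map(embedder, mean_map(pool[idx_a]))
    eb <- embed_map(embedder, mean_map(pool[-idx_a]))
    sqrt(sum((ea - eb)^2))
  }
  observed <- stat(seq_len(m))
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(length(pool), m)),
           numeric(1))
  })
  rank_fraction <- rank_fraction(observed, null)
  structure(
    list(observed = observed, null = null,
         rank_fraction = rank_fraction,
         different = rank_fraction > 1 - alpha,
         alpha = alpha, n_perm = as.integer(n_perm),
         group_sizes = c(m, length(maps_b))),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed %.4f, rank fraction %.2f over %d permutations -> %s\n",
    x$observed, x$rank_fraction, x$n_perm,
    if (x$different) "age groups differ" else "not statistically different"))
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm), distance = x$null)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, rank_fraction = x$rank_fraction,
                 n_perm = x$n_perm, alpha = x$alpha,
                 different = x$different)
}

#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "#b2182b",
                        linewidth = 1) +
    ggplot2::labs(
      title = sprintf("Permutation null vs observed (rank fraction %.2f)",
                      object$rank_fraction),
      x = "embedding distance", y = "permutations") +
    ggplot2::theme_minimal()
}

#' Pairwise age-group rank fractions for one disease
#'
#' Runs [age_permutation_test()] for every pair of age brackets and returns
#' the rank-fraction matrix in tidy form — the quantitative summary of how
#' salient features drift with age.
#'
#' @param maps_by_age Named list (names from [age_brackets()]) of lists of
#'   `saliency_map` objects.
#' @param embedder A [map_embedder()].
#' @inheritParams age_permutation_test
#' @return A tibble with columns `age_a`, `age_b`, `rank_fraction`,
#'   `observed`, `different`.
#' @export
pairwise_age_ranks <- function(maps_by_age, embedder, n_perm = 100L,
                               seed = 1L, alpha = 0.05) {
  ages <- names(maps_by_age)
  out <- list()
  k <- 0L
  for (i in seq_along(ages)) {
    for (j in seq_along(ages)) {
      if (j <= i) next
      k <- k + 1L
      res <- age_permutation_test(maps_by_age[[i]], maps_by_age[[j]],
                                  embedder, n_perm = n_perm,
                                  seed = derive_seed(seed, k), alpha = alpha)
      out[[k]] <- tibble::tibble(
        age_a = ages[i], age_b = ages[j],
        rank_fraction = res$rank_fraction, observed = res$observed,
        different = res$different)
    }
  }
  dplyr::bind_rows(out)
}
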