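#' Classifier configuration
#'
#' Desk-scale backbone settings for the four-label classifier: a single
#' hidden-layer softmax network (fit with [nnet::nnet()]) on block-averaged
#' pixel features. The pooling grid and hidden width keep the parameter count
#' small enough for CPU-only cross-validation while remaining a configurable
#' stand-in for a heavier convolutional backbone at full scale.
#'
#' @param pool Side of the average-pooling grid applied to the
#'   channel-averaged image (features per image = `pool^2`). Must divide the
#'   image resolution.
#' @param hidden Hidden units.
#' @param maxit Optimiser iterations for [nnet::nnet()].
#' @param decay Weight decay.
#' @param resolution Expected input image side; `NULL` accepts any size
#'   divisible by `pool`.
#' @return A list of class `clf_config`.
#' @export
clf_config <- function(pool = 8L, hidden = 16L, maxit = 300L,
                       decay = 1e-3, resolution = NULL) {
  structure(list(pool = as.integer(pool), hidden = as.integer(hidden),
                 maxit = as.integer(maxit), decay = decay,
                 resolution = resolution),
            class = "clf_config")
}

# Channel-average then block-average an image to a pool x pool feature vector.
image_features <- function(img, pool) {
  n <- dim(img)[1]
  if (n %% pool != 0) {
    stop(sprintf("image side %d not divisible by pooling grid %d", n, pool),
         call. = FALSE)
  }
  g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  b <- n %/% pool
  # block means via two matrix multiplications
  agg <- matrix(0, pool, n)
  for (i in seq_len(pool)) agg[i, ((i - 1) * b + 1):(i * b)] <- 1 / b
  as.vector(agg %*% g %*% t(agg))
}

feature_matrix <- function(images, pool) {
  t(vapply(images, image_features, numeric(pool^2), pool = pool))
}

soft_label_matrix <- function(manifest) {
  as.matrix(manifest[, c("p_ws", "p_22q", "p_control", "p_unaffected")])
}

#' Soft-label cross-entropy
#'
#' `-sum(target * log(pred))` for length-4 probability vectors, the training
#' loss used for both one-hot and blended soft labels. Predictions are
#' clipped away from zero at `eps` before taking logs. On a one-hot target
#' this reduces exactly to standard cross-entropy.
#'
#' @param pred Predicted probability 4-vector (nonnegative, sums to 1).
#' @param target Target soft-label 4-vector (nonnegative, sums to 1).
#' @param eps Clipping floor for predicted probabilities.
#' @return A nonnegative scalar.
#' @export
#' @examples
#' soft_cross_entropy(rep(0.25, 4), c(0.55, 0.45, 0, 0)) # log(4)
soft_cross_entropy <- function(pred, target, eps = 1e-12) {
  if (length(pred) != 4 || length(target) != 4) {
    stop("pred and target must have length 4", call. = FALSE)
  }
  if (any(pred < 0) || any(target < 0)) {
    stop("probabilities must be nonnegative", call. = FALSE)
  }
  if (abs(sum(pred) - 1) > 1e-6 || abs(sum(target) - 1) > 1e-6) {
    stop("pred and target must each sum to 1", call. = FALSE)
  }
  -sum(target * log(pmax(pred, eps)))
}

#' Train the four-label classifier
#'
#' Fits the configured softmax network on every row of the manifest (study,
#' auxiliary and generated rows alike), using each row's soft-label 4-vector
#' as the target, i.e. maximising `sum_i sum_k target_ik log p_ik`. One-hot
#' rows give ordinary cross-entropy training; blended rows contribute soft
#' targets directly.
#'
#' @param manifest A cohort manifest with an `image` list-column (see
#'   [render_manifest()] / [read_manifest_images()] if images are not in
#'   memory).
#' @param config A [clf_config()].
#' @param seed Integer seed (controls the random weight initialisation).
#' @return An object of class `face_classifier`.
#' @export
train_classifier <- function(manifest, config = clf_config(), seed = 1L) {
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  if (is.null(manifest$image)) {
    stop("manifest has no 'image' column; render or read images first",
         call. = FALSE)
  }
  for (d in unique(manifest$disease)) {
    match_label(d, disease_labels(), "disease label")
  }
  x <- feature_matrix(manifest$image, config$pool)
  y <- soft_label_matrix(manifest)
  p <- ncol(x)
  max_wts <- (p + 1) * config$hidden + (config$hidden + 1) * 4 + 10
  fit <- with_local_seed(seed, {
    nnet::nnet(x, y, size = config$hidden, softmax = TRUE,
               maxit = config$maxit, decay = config$decay,
               MaxNWts = max_wts, trace = FALSE)
  })
  structure(
    list(fit = fit, config = config, seed = as.integer(seed),
         labels = disease_labels(),
         resolution = dim(manifest$image[[1]])[1],
         initial_loss = initial_softmax_loss(y),
         final_loss = fit$value),
    class = "face_classifier"
  )
}

# Expected loss of an untrained (near-uniform) softmax on targets y.
initial_softmax_loss <- function(y) nrow(y) * log(4)

#' @export
print.face_classifier <- function(x, ...) {
  cat(sprintf(
    "<face_classifier> %d->%d->4 softmax net, resolution %d, final loss %.3f\n",
    x$config$pool^2, x$config$hidden, x$resolution, x$final_loss))
  invisible(x)
}

#' @export
glance.face_classifier <- function(x, ...) {
  tibble::tibble(hidden = x$config$hidden, pool = x$config$pool,
                 resolution = x$resolution,
                 initial_loss = x$initial_loss, final_loss = x$final_loss)
}

images_from <- function(newdata) {
  if (is.data.frame(newdata)) {
    if (is.null(newdata$image)) stop("manifest has no 'image' column",
                                     call. = FALSE)
    newdata$image
  } else if (is.array(newdata)) {
    list(newdata)
  } else {
    newdata
  }
}

#' Predict label probabilities
#'
#' @param object A `face_classifier`.
#' @param newdata A manifest with an `image` column, a list of image arrays,
#'   or a single image array.
#' @param ... Unused.
#' @return A tibble with columns `p_ws, p_22q, p_control, p_unaffected` (rows
#'   sum to 1) and `label` (argmax).
#' @export
predict.face_classifier <- function(object, newdata, ...) {
  images <- images_from(newdata)
  x <- feature_matrix(images, object$config$pool)
  pr <- predict(object$fit, x)
  pr <- pr / rowSums(pr)
  out <- tibble::as_tibble(as.data.frame(pr))
  names(out) <- c("p_ws", "p_22q", "p_control", "p_unaffected")
  out$label <- object$labels[max.col(pr, ties.method = "first")]
  out
}

#' Penultimate-layer features of a trained classifier
#'
#' Reconstructs the hidden-layer (logistic) activations from the fitted
#' network weights; used as the default saliency-map embedder at desk scale.
#'
#' @param model A `face_classifier`.
#' @param images A list of image arrays (or a manifest / single array).
#' @return A numeric matrix, one row per image, `hidden` columns.
#' @export
classifier_features <- function(model, images) {
  images <- images_from(images)
  x <- feature_matrix(images, model$config$pool)
  n <- model$fit$n # c(inputs, hidden, outputs)
  p <- n[1]; h <- n[2]
  wts <- model$fit$wts
  w1 <- matrix(wts[seq_len((p + 1) * h)], nrow = p + 1)
  act <- cbind(1, x) %*% w1
  1 / (1 + exp(-act))
}

#' Confidence-filtered ensemble of fold classifiers
#'
#' Bundles one classifier per cross-validation fold. Prediction averages the
#' member probability vectors, restricted per image to the members whose
#' maximum predicted probability is at least `threshold`; when no member
#' qualifies, all members are averaged (the filter never abstains).
#'
#' @param models A list of `face_classifier` objects.
#' @param threshold Confidence threshold on the members' maximum predicted
#'   probability, default 0.5.
#' @return An object of class `face_ensemble`.
#' @export
face_ensemble <- function(models, threshold = 0.5) {
  stopifnot(length(models) >= 1)
  for (m in models) stopifnot(inherits(m, "face_classifier"))
  structure(list(models = models, threshold = threshold),
            class = "face_ensemble")
}

#' @export
print.face_ensemble <- function(x, ...) {
  cat(sprintf("<face_ensemble> %d members, confidence threshold %.2f\n",
              length(x$models), x$threshold))
  invisible(x)
}

#' Train the k-fold ensemble
#'
#' Trains one classifier per fold on that fold's training rows joined with
#' the (optional) auxiliary training rows and (optional) generated
#' augmentation rows, then bundles them into a [face_ensemble()].
#'
#' @param study Study manifest with images.
#' @param partition A [make_cv_folds()] partition of `study`.
#' @param aux Optional auxiliary manifest rows (already restricted to the
#'   auxiliary train split) with images.
#' @param generated Optional generated manifest with images (soft labels
#'   allowed).
#' @param config A [clf_config()].
#' @param seed Integer seed; member `i` trains with seed `seed + i`.
#' @return A `face_ensemble`.
#' @export
train_cv_ensemble <- function(study, partition, aux = NULL, generated = NULL,
                              config = clf_config(), seed = 1L) {
  stopifnot(inherits(partition, "fold_partition"))
  models <- lapply(seq_len(partition$k), function(i) {
    tr <- study[partition$folds[[i]]$train, ]
    if (!is.null(aux)) tr <- dplyr::bind_rows(tr, aux)
    if (!is.null(generated)) tr <- dplyr::bind_rows(tr, generated)
    train_classifier(tr, config = config, seed = seed + i)
  })
  face_ensemble(models)
}

#' Confidence-filtered average of member probability vectors
#'
#' The ensemble combination rule in isolation: given one probability
#' 4-vector per member, average only the members whose maximum entry
#' reaches `threshold`; when none qualifies, average all members.
#'
#' @param member_probs A `k x 4` matrix (or list of 4-vectors), one row per
#'   ensemble member.
#' @param threshold Confidence threshold (default 0.5).
#' @return A list with `probabilities` (length-4 vector summing to 1) and
#'   `n_used` (number of members that passed the filter).
#' @export
#' @examples
#' ensemble_average(rbind(c(0.9, 0.1, 0, 0), c(0.4, 0.3, 0.2, 0.1)))
ensemble_average <- function(member_probs, threshold = 0.5) {
  if (is.list(member_probs)) member_probs <- do.call(rbind, member_probs)
  stopifnot(ncol(member_probs) == 4)
  qual <- which(apply(member_probs, 1, max) >= threshold)
  if (!length(qual)) qual <- seq_len(nrow(member_probs))
  list(probabilities = colMeans(member_probs[qual, , drop = FALSE]),
       n_used = length(qual))
}

#' Ensemble prediction with the confidence filter
#'
#' Applies [ensemble_average()] per image to the member predictions.
#'
#' @param ensemble A [face_ensemble()].
#' @param newdata Manifest, list of images, or single image array.
#' @return A tibble like [predict.face_classifier()], plus `n_members_used`.
#' @export
ensemble_predict <- function(ensemble, newdata) {
  stopifnot(inherits(ensemble, "face_ensemble"))
  images <- images_from(newdata)
  member_probs <- lapply(ensemble$models, function(m) {
    as.matrix(predict(m, images)[, 1:4])
  })
  n <- length(images)
  out <- matrix(0, n, 4)
  used <- integer(n)
  for (i in seq_len(n)) {
    pm <- t(vapply(member_probs, function(p) p[i, ], numeric(4)))
    avg <- ensemble_average(pm, ensemble$threshold)
    out[i, ] <- avg$probabilities
    used[i] <- avg$n_used
  }
  res <- tibble::as_tibble(as.data.frame(out))
  names(res) <- c("p_ws", "p_22q", "p_control", "p_unaffected")
  res$label <- disease_labels()[max.col(out, ties.method = "first")]
  res$n_members_used <- used
  res
}

#' Forced two-label choice from a four-label probability vector
#'
#' Restricts a probability 4-vector to a pair of labels and returns the
#' higher-probability member, emulating a binary survey question answered by
#' a four-label model. Ties break toward the first element of `pair`.
#'
#' @param probabilities Length-4 probability vector in [disease_labels()]
#'   order.
#' @param pair Character vector of two distinct labels.
#' @return One of `pair`.
#' @export
#' @examples
#' forced_binary(c(0.1, 0.2, 0.3, 0.4), c("WS", "control"))
forced_binary <- function(probabilities, pair) {
  if (length(pair) != 2 || pair[1] == pair[2]) {
    stop("pair must be two distinct labels", call. = FALSE)
  }
  i <- match(pair, disease_labels())
  if (any(is.na(i))) stop("invalid label in pair", call. = FALSE)
  if (length(probabilities) != 4) {
    stop("probabilities must have length 4", call. = FALSE)
  }
  if (probabilities[i[2]] > probabilities[i[1]]) pair[2] else pair[1]
}

#' Row-normalised percentage confusion matrix
#'
#' Rows are true labels, columns predicted labels; entries are percentages of
#' each row's images, so every row sums to 100. Values are exact; round for
#' integer-percent display.
#'
#' @param predictions Character vector of predicted labels.
#' @param truths Character vector of true labels (same length).
#' @param labels Label order; defaults to [disease_labels()].
#' @return A numeric `length(labels) x length(labels)` matrix (percent).
#' @export
confusion_matrix <- function(predictions, truths, labels = disease_labels()) {
  if (!length(truths)) stop("empty input", call. = FALSE)
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length", call. = FALSE)
  }
  if (!all(truths %in% labels)) stop("labels must cover all truths",
                                     call. = FALSE)
  tab <- table(factor(truths, levels = labels),
               factor(predictions, levels = labels))
  m <- 100 * sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
  dimnames(m) <- list(truth = labels, prediction = labels)
  m
}
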