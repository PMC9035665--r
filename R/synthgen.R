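#' Define a synthetic facial-phenotype specification
#'
#' Describes how synthetic study images are rendered: a smooth oval "face"
#' template shared by everyone, plus localised rectangular feature patches per
#' disease whose strength is modulated by a five-entry age profile (one entry
#' per age bracket). Some features are age-stable (constant profile), others
#' age-specific, which is what gives the cohort an age-by-disease interaction
#' for the saliency permutation test to detect.
#'
#' Each feature is a list with elements `region` (relative coordinates
#' `c(row0, row1, col0, col1)` in `[0, 1]`), `intensity` (additive pixel
#' strength), `age_profile` (5-vector in `[0, 1]`, ordered as
#' [age_brackets()]) and `tint` (length-3 RGB weights). The `unaffected`
#' label always carries an empty feature set: those images are the baseline
#' template only.
#'
#' Independently of the disease features, the baseline template itself drifts
#' with age: a band of the face oval darkens linearly by `age_drift` from the
#' infant to the older-adult bracket, so even unaffected images carry an age
#' signal (needed for the GAN's age embedding to have something to learn from
#' the auxiliary pool).
#'
#' @param image_size Pixels per side of the square image (>= 32).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise (>= 0).
#' @param grayscale_fraction Fraction of images rendered single-channel and
#'   replicated to 3 channels (emulating mixed colour / black-and-white
#'   collections).
#' @param identity_jitter_sd Standard deviation, in pixels, of the per-identity
#'   translation applied to all feature patches; the same identity is rendered
#'   with the same jitter at every age bracket ("the same person" across ages).
#' @param age_drift Strength of the age-linked darkening of the baseline
#'   template, in pixel-intensity units.
#' @param features Named list (names from [disease_labels()]) of lists of
#'   feature descriptors; defaults to a built-in phenotype set with age-stable
#'   and age-specific features for each affected label.
#'
#' @return An object of class `phenotype_spec`.
#' @export
#' @examples
#' spec <- phenotype_spec(image_size = 32, noise_sd = 0)
#' img <- render_image(spec, "WS", "infant", identity = 1, seed = 7)
#' dim(img)
phenotype_spec <- function(image_size = 64,
                           noise_sd = 0.05,
                           grayscale_fraction = 0.2,
                           identity_jitter_sd = 1,
                           age_drift = 0.15,
                           features = default_features()) {
  stopifnot(image_size >= 32, noise_sd >= 0, identity_jitter_sd >= 0,
            grayscale_fraction >= 0, grayscale_fraction <= 1)
  stopifnot(is.list(features))
  missing <- setdiff(setdiff(disease_labels(), "unaffected"), names(features))
  for (d in missing) features[[d]] <- list()
  if (length(features[["unaffected"]] %||% list()) > 0) {
    stop("'unaffected' must have an empty feature set", call. = FALSE)
  }
  features[["unaffected"]] <- list()
  for (d in names(features)) {
    for (f in features[[d]]) {
      stopifnot(length(f$region) == 4, length(f$age_profile) == 5)
      if (any(f$age_profile < 0 | f$age_profile > 1)) {
        stop("age_profile entries must lie in [0, 1]", call. = FALSE)
      }
    }
  }
  structure(
    list(
      image_size = as.integer(image_size),
      noise_sd = noise_sd,
      grayscale_fraction = grayscale_fraction,
      identity_jitter_sd = identity_jitter_sd,
      age_drift = age_drift,
      features = features
    ),
    class = "phenotype_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname phenotype_spec
#' @export
default_features <- function() {
  list(
    WS = list(
      list(name = "periorbital", region = c(0.25, 0.40, 0.15, 0.45),
           intensity = 0.35, age_profile = c(1, 1, 1, 1, 1),
           tint = c(1, 0.85, 0.7)),
      list(name = "mouth", region = c(0.65, 0.78, 0.35, 0.65),
           intensity = 0.30, age_profile = c(1, 1, 1, 0.3, 0.2),
           tint = c(1, 0.7, 0.7))
    ),
    `22q` = list(
      list(name = "nasal_bridge", region = c(0.45, 0.60, 0.42, 0.58),
           intensity = 0.25, age_profile = c(0.3, 0.5, 0.7, 0.9, 1),
           tint = c(0.75, 0.9, 1)),
      list(name = "mandible", region = c(0.80, 0.92, 0.25, 0.75),
           intensity = 0.20, age_profile = c(1, 0.8, 0.6, 0.4, 0.3),
           tint = c(0.8, 1, 0.8))
    ),
    control = list(
      list(name = "forehead", region = c(0.08, 0.20, 0.30, 0.70),
           intensity = 0.28, age_profile = c(1, 1, 1, 1, 1),
           tint = c(0.9, 0.9, 1))
    ),
    unaffected = list()
  )
}

#' Remove all age signal from a phenotype specification
#'
#' Returns a copy of `spec` in which every feature's age profile is replaced
#' by its own mean (constant across brackets) and the baseline age drift is
#' zeroed. Under the resulting spec, images of a given disease are
#' exchangeable across age brackets, which is the null condition used to
#' calibrate the age permutation test's type-I error.
#'
#' @param spec A [phenotype_spec()].
#' @return A `phenotype_spec` with age-constant phenotypes.
#' @export
spec_age_constant <- function(spec) {
  stopifnot(inherits(spec, "phenotype_spec"))
  spec$age_drift <- 0
  spec$features <- lapply(spec$features, function(fs) {
    lapply(fs, function(f) {
      f$age_profile <- rep(mean(f$age_profile), 5)
      f
    })
  })
  spec
}

# Baseline oval face template (h x w matrix in [0,1]), before age drift.
base_template <- function(n) {
  rc <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  r2 <- outer(rc^2 / 0.9, rc^2 / 0.55, `+`)
  0.25 + 0.55 * exp(-1.6 * r2)
}

# Ring mask used for the age-linked darkening (band of the oval, cheek-level).
age_band <- function(n) {
  rows <- seq_len(n) / n
  band <- exp(-((rows - 0.62) / 0.12)^2)
  matrix(band, n, n)
}

region_px <- function(region, n, dr = 0L, dc = 0L) {
  r0 <- max(1L, min(n, round(region[1] * (n - 1)) + 1L + dr))
  r1 <- max(1L, min(n, round(region[2] * (n - 1)) + 1L + dr))
  c0 <- max(1L, min(n, round(region[3] * (n - 1)) + 1L + dc))
  c1 <- max(1L, min(n, round(region[4] * (n - 1)) + 1L + dc))
  list(rows = r0:r1, cols = c0:c1)
}

identity_jitter <- function(spec, identity) {
  if (spec$identity_jitter_sd == 0) return(c(0L, 0L))
  with_local_seed(derive_seed(7919, identity), {
    as.integer(round(rnorm(2, 0, spec$identity_jitter_sd)))
  })
}

#' Render one synthetic labelled image
#'
#' Deterministically renders the square RGB image for a (disease, age bracket,
#' identity) triple under a [phenotype_spec()]. The disease's feature patches
#' are added to the baseline face template with intensity scaled by the
#' feature's age-profile entry for the requested bracket; the identity
#' controls a reproducible translation of the patches so the same identity is
#' renderable consistently at all five brackets; pixel noise and the
#' grayscale decision come from a seed derived from `seed` and the identity.
#'
#' @param spec A [phenotype_spec()].
#' @param disease One of [disease_labels()].
#' @param age One of [age_brackets()].
#' @param identity Integer identity tag (drives the geometric jitter).
#' @param seed Integer seed; the same `(spec, disease, age, identity, seed)`
#'   always yields a bit-identical image.
#' @return A numeric array `image_size x image_size x 3` with values in
#'   `[0, 1]`.
#' @export
render_image <- function(spec, disease, age, identity = 1L, seed = 1L) {
  stopifnot(inherits(spec, "phenotype_spec"))
  disease <- match_label(disease, disease_labels(), "disease label")
  age <- match_label(age, age_brackets(), "age bracket")
  n <- spec$image_size
  ai <- match(age, age_brackets())

  base <- base_template(n)
  base <- base - spec$age_drift * (ai - 1) / 4 * age_band(n)
  img <- array(rep(base, 3), dim = c(n, n, 3))

  jit <- identity_jitter(spec, identity)
  for (f in spec$features[[disease]]) {
    s <- f$intensity * f$age_profile[ai]
    if (s == 0) next
    px <- region_px(f$region, n, jit[1], jit[2])
    tint <- f$tint %||% c(1, 1, 1)
    for (ch in 1:3) {
      img[px$rows, px$cols, ch] <- img[px$rows, px$cols, ch] + s * tint[ch]
    }
  }

  rs <- derive_seed(seed, identity * 7L + ai)
  with_local_seed(rs, {
    gray <- runif(1) < spec$grayscale_fraction
    if (spec$noise_sd > 0) {
      img <- img + array(rnorm(n * n * 3, 0, spec$noise_sd), dim = c(n, n, 3))
    }
    if (gray) {
      lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
      img <- array(rep(lum, 3), dim = c(n, n, 3))
    }
  })
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

one_hot_label <- function(disease) {
  p <- as.numeric(disease_labels() == disease)
  names(p) <- c("p_ws", "p_22q", "p_control", "p_unaffected")
  p
}

manifest_row <- function(path, disease, age, identity, provenance, soft,
                         image = NULL) {
  tibble::tibble(
    path = path, disease = disease, age = age,
    identity = as.integer(identity), provenance = provenance,
    p_ws = soft[1], p_22q = soft[2], p_control = soft[3],
    p_unaffected = soft[4],
    image = if (is.null(image)) list(NULL) else list(image)
  )
}

#' Generate a synthetic study cohort
#'
#' Renders `counts$n` images for each (disease, age bracket) cell, each with a
#' fresh identity, and returns a cohort manifest: one row per image with the
#' disease label, age bracket, identity, provenance and a one-hot soft-label
#' 4-vector (`p_ws, p_22q, p_control, p_unaffected`). With `render = TRUE`
#' the pixel arrays are kept in the `image` list-column; with a non-`NULL`
#' `dir` each image is additionally written as an 8-bit RGB PNG.
#'
#' @param spec A [phenotype_spec()].
#' @param counts A data frame with columns `disease`, `age`, `n` (nonnegative
#'   integer counts per cell); omitted cells count 0.
#' @param seed Integer master seed; per-image seeds are derived by a fixed
#'   counter scheme so cohorts are reproducible byte-for-byte.
#' @param dir Optional directory to write PNGs into.
#' @param render Keep rendered pixel arrays in the manifest (`TRUE`, default).
#'   With `render = FALSE` only the bookkeeping columns are produced; pixels
#'   can be re-materialised later with [render_manifest()].
#' @param provenance Provenance tag for the rows (default `"study"`).
#' @param start_identity First identity number to assign.
#' @return A tibble manifest (class `cohort_manifest`).
#' @export
#' @examples
#' spec <- phenotype_spec(image_size = 32)
#' counts <- tibble::tibble(disease = "WS", age = "infant", n = 3)
#' m <- generate_cohort(spec, counts, seed = 1)
#' nrow(m)
generate_cohort <- function(spec, counts, seed = 1L, dir = NULL,
                            render = TRUE, provenance = "study",
                            start_identity = 1L) {
  stopifnot(inherits(spec, "phenotype_spec"))
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("disease", "age", "n") %in% names(counts)))
  if (any(counts$n < 0)) stop("counts must be nonnegative", call. = FALSE)
  for (d in counts$disease) match_label(d, disease_labels(), "disease label")
  for (a in counts$age) match_label(a, age_brackets(), "age bracket")

  counts <- counts[counts$n > 0, , drop = FALSE]
  total <- sum(counts$n)
  disease <- rep(counts$disease, counts$n)
  age <- rep(counts$age, counts$n)
  identity <- as.integer(start_identity) + seq_len(total) - 1L
  counter <- seq_len(total) - 1L
  lab <- vapply(disease, one_hot_label, numeric(4))
  out <- tibble::tibble(
    path = sprintf("%s/%s_%s_%06d.png", provenance, disease, age, identity),
    disease = disease, age = age, identity = identity,
    provenance = provenance,
    p_ws = if (total) lab[1, ] else numeric(0),
    p_22q = if (total) lab[2, ] else numeric(0),
    p_control = if (total) lab[3, ] else numeric(0),
    p_unaffected = if (total) lab[4, ] else numeric(0)
  )
  if (render || !is.null(dir)) {
    out$image <- purrr::pmap(
      list(disease, age, identity, counter),
      function(d, a, id, ct) {
        render_image(spec, d, a, identity = id, seed = derive_seed(seed, ct))
      })
    if (!is.null(dir)) {
      full <- file.path(dir, out$path)
      for (i in seq_len(total)) {
        dir.create(dirname(full[i]), recursive = TRUE, showWarnings = FALSE)
        png::writePNG(out$image[[i]], full[i])
      }
      out$path <- full
    }
    if (!render) out$image <- NULL
  }
  class(out) <- c("cohort_manifest", class(out))
  out
}

#' Generate a large auxiliary pool of unaffected images
#'
#' Emulates the role of a large labelled-by-age pool of unaffected faces used
#' for joint training: every row carries the `unaffected` label and one of the
#' five age brackets, with `per_age_counts` rows per bracket.
#'
#' @param spec A [phenotype_spec()].
#' @param per_age_counts Integer vector of length 5 (counts per age bracket,
#'   in [age_brackets()] order).
#' @inheritParams generate_cohort
#' @return A tibble manifest (class `cohort_manifest`) of unaffected rows.
#' @export
generate_auxiliary_pool <- function(spec, per_age_counts, seed = 1L,
                                    dir = NULL, render = TRUE,
                                    start_identity = 100000L) {
  stopifnot(length(per_age_counts) == 5, all(per_age_counts >= 0))
  counts <- tibble::tibble(
    disease = "unaffected",
    age = age_brackets(),
    n = as.integer(per_age_counts)
  )
  generate_cohort(spec, counts, seed = seed, dir = dir, render = render,
                  provenance = "auxiliary", start_identity = start_identity)
}

#' Re-render the pixel arrays for manifest rows
#'
#' Rendering is deterministic given the manifest bookkeeping, so manifests
#' generated with `render = FALSE` (or subsets of them) can have their pixels
#' materialised on demand.
#'
#' @param manifest A cohort manifest produced by [generate_cohort()] or
#'   [generate_auxiliary_pool()] with `render = FALSE`; rows must retain the
#'   original `identity` values.
#' @param spec The [phenotype_spec()] the manifest was generated under.
#' @param seed The master seed used at generation time.
#' @param counters Integer vector of the per-row generation counters; defaults
#'   to `identity - min(identity)` which matches generation order for
#'   manifests produced in one call.
#' @return The manifest with an `image` list-column.
#' @export
render_manifest <- function(manifest, spec, seed,
                            counters = manifest$identity - min(manifest$identity)) {
  stopifnot(nrow(manifest) == length(counters))
  manifest$image <- purrr::pmap(
    list(manifest$disease, manifest$age, manifest$identity, counters),
    function(d, a, id, ct) {
      render_image(spec, d, a, identity = id, seed = derive_seed(seed, ct))
    }
  )
  manifest
}

#' Read manifest images from disk
#'
#' @param manifest A cohort manifest whose `path` column points at PNG files.
#' @return The manifest with an `image` list-column of pixel arrays.
#' @export
read_manifest_images <- function(manifest) {
  manifest$image <- purrr::map(manifest$path, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  manifest
}

#' Write a manifest to CSV
#'
#' Writes the bookkeeping columns (never the pixel arrays) with the fixed
#' header `path,disease,age,identity,provenance,p_ws,p_22q,p_control,
#' p_unaffected`.
#'
#' @param manifest A cohort manifest.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("path", "disease", "age", "identity", "provenance",
            "p_ws", "p_22q", "p_control", "p_unaffected")
  utils::write.csv(as.data.frame(manifest)[, cols], path, row.names = FALSE)
  invisible(path)
}
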