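#' Per-cell counts for type-1 generation
#'
#' For each affected disease, the number of fake images generated per
#' (disease, age bracket) cell equals the mean study count of that disease
#' over all five brackets, rounded half-to-even. Rare brackets are therefore
#' upsampled relative to their real share, and the total per disease stays
#' close to that disease's study count.
#'
#' @param manifest Study cohort manifest (tallies are taken from its
#'   `study`-provenance rows).
#' @return A tibble with columns `disease`, `age`, `n`.
#' @export
#' @examples
#' # bracket counts (1,1,1,1,35) -> mean 7.8 -> 8 per cell
type1_counts <- function(manifest) {
  study <- manifest[manifest$provenance == "study" &
                      manifest$disease != "unaffected", ]
  diseases <- intersect(disease_labels(), unique(study$disease))
  out <- list()
  for (d in diseases) {
    per_bracket <- vapply(age_brackets(), function(a) {
      sum(study$disease == d & study$age == a)
    }, 0)
    k <- round(mean(per_bracket)) # round-half-even
    out[[d]] <- tibble::tibble(disease = d, age = age_brackets(), n = k)
  }
  if (!length(out)) {
    return(tibble::tibble(disease = character(), age = character(),
                          n = integer()))
  }
  dplyr::bind_rows(out)
}

generated_manifest <- function(images, diseases, ages, softs, ids) {
  if (!length(images)) {
    out <- manifest_row("x", "WS", "infant", 1L, "generated",
                        one_hot_label("WS"))[0, ]
    class(out) <- c("cohort_manifest", class(out))
    return(out)
  }
  rows <- lapply(seq_along(images), function(i) {
    manifest_row(
      sprintf("generated/%s_%s_%06d.png", diseases[i], ages[i], ids[i]),
      diseases[i], ages[i], ids[i], "generated", softs[[i]],
      image = images[[i]]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cohort_manifest", class(out))
  out
}

#' Type 1: unrelated fake faces per (disease, age) cell
#'
#' Each image gets its own fresh latent, so all images are (in principle)
#' unique; per-cell counts follow [type1_counts()]; labels are one-hot.
#'
#' @param gan A trained [train_gan()] model.
#' @param manifest Study manifest the tallies come from.
#' @param seed Integer seed for the latents.
#' @param start_identity First identity tag for generated rows.
#' @return A generated cohort manifest with images.
#' @export
generate_type1 <- function(gan, manifest, seed = 1L,
                           start_identity = 900000L) {
  counts <- type1_counts(manifest)
  counts <- counts[counts$n > 0, ]
  total <- sum(counts$n)
  if (total == 0) {
    return(generated_manifest(list(), character(), character(), list(),
                              integer()))
  }
  z <- gan_latent(gan, total, seed = seed)
  images <- vector("list", total)
  diseases <- ages <- character(total)
  softs <- vector("list", total)
  pos <- 0L
  for (i in seq_len(nrow(counts))) {
    d <- counts$disease[i]; a <- counts$age[i]; k <- counts$n[i]
    imgs <- gan_generate(gan, one_hot(a, age_brackets()),
                         one_hot(d, disease_labels()),
                         z[, pos + seq_len(k), drop = FALSE])
    for (j in seq_len(k)) {
      images[[pos + j]] <- imgs[[j]]
      diseases[pos + j] <- d
      ages[pos + j] <- a
      softs[[pos + j]] <- one_hot_label(d)
    }
    pos <- pos + k
  }
  generated_manifest(images, diseases, ages, softs,
                     start_identity + seq_len(total) - 1L)
}

#' Type 2: similar faces across the five age brackets
#'
#' Five images of one disease sharing a single latent and disease embedding,
#' with the age embedding stepped through the five brackets; age-stable
#' characteristics of the latent persist across the set.
#'
#' @inheritParams generate_type1
#' @param disease Affected disease label.
#' @param z Optional latent vector; drawn from `seed` if missing.
#' @return A generated manifest of 5 rows (one per bracket), one-hot labels.
#' @export
generate_type2 <- function(gan, disease, z = NULL, seed = 1L,
                           start_identity = 910000L) {
  disease <- match_label(disease, disease_labels(), "disease label")
  if (is.null(z)) z <- gan_latent(gan, 1, seed = seed)[, 1]
  images <- lapply(age_brackets(), function(a) {
    gan_generate(gan, one_hot(a, age_brackets()),
                 one_hot(disease, disease_labels()), z)[[1]]
  })
  generated_manifest(images, rep(disease, 5), age_brackets(),
                     rep(list(one_hot_label(disease)), 5),
                     rep(start_identity, 5))
}

#' Type 3: age progression of the same synthetic person
#'
#' Holds the latent and disease embedding fixed and moves the age condition
#' along the segment from the infant embedding to the older-adult embedding:
#' weights (1, 0), (0.75, 0.25), (0.5, 0.5), (0.25, 0.75), (0, 1) on
#' (infant, older-adult) — the three interior vectors are equally spaced
#' interpolations. The five images are labelled with the five brackets in
#' order (interior images map to child / adolescent / young-adult).
#'
#' @inheritParams generate_type2
#' @return A generated manifest of 5 rows with one-hot disease labels and a
#'   `infant_weight` column recording the interpolation coefficients.
#' @export
generate_type3 <- function(gan, disease, z = NULL, seed = 1L,
                           start_identity = 920000L) {
  disease <- match_label(disease, disease_labels(), "disease label")
  if (is.null(z)) z <- gan_latent(gan, 1, seed = seed)[, 1]
  w_inf <- c(1, 0.75, 0.5, 0.25, 0)
  images <- lapply(w_inf, function(w) {
    ac <- numeric(5)
    ac[1] <- w
    ac[5] <- 1 - w
    gan_generate(gan, ac, one_hot(disease, disease_labels()), z)[[1]]
  })
  out <- generated_manifest(images, rep(disease, 5), age_brackets(),
                            rep(list(one_hot_label(disease)), 5),
                            rep(start_identity, 5))
  out$infant_weight <- w_inf
  out
}

#' Type 4: blended-disease faces with soft labels
#'
#' Fixes a latent and an age bracket and blends the main disease's embedding
#' with each of the other three labels' embeddings:
#' `c * e_main + (1 - c) * e_partner`. Each image carries the soft label
#' placing `c` on the main disease and `1 - c` on the partner (e.g.
#' `(0.55, 0.45, 0, 0)` for a WS-main / 22q-partner blend at the default
#' `c = 0.55`); the 75/25 preset used in augmentation comparisons is
#' `c = 0.75`.
#'
#' @inheritParams generate_type2
#' @param age Age bracket of the blends.
#' @param c_main Blend fraction in (0, 1) carried by the main disease.
#' @param main Main disease, `"WS"` or `"22q"`.
#' @return A generated manifest of 3 rows with soft labels and a `partner`
#'   column.
#' @export
generate_type4 <- function(gan, age, z = NULL, c_main = 0.55, main = "WS",
                           seed = 1L, start_identity = 930000L) {
  age <- match_label(age, age_brackets(), "age bracket")
  main <- match_label(main, c("WS", "22q"), "main disease")
  if (!(c_main > 0 && c_main < 1)) {
    stop("c_main must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.null(z)) z <- gan_latent(gan, 1, seed = seed)[, 1]
  partners <- setdiff(disease_labels(), main)
  ac <- one_hot(age, age_brackets())
  images <- list(); softs <- list()
  for (p in partners) {
    dc <- c_main * one_hot(main, disease_labels()) +
      (1 - c_main) * one_hot(p, disease_labels())
    images[[p]] <- gan_generate(gan, ac, dc, z)[[1]]
    soft <- numeric(4)
    soft[match(main, disease_labels())] <- c_main
    soft[match(p, disease_labels())] <- 1 - c_main
    names(soft) <- c("p_ws", "p_22q", "p_control", "p_unaffected")
    softs[[p]] <- soft
  }
  out <- generated_manifest(images, rep(main, 3), rep(age, 3), softs,
                            rep(start_identity, 3))
  out$partner <- partners
  out
}

#' Bulk generation of an augmentation set
#'
#' Convenience wrapper producing a full augmentation manifest of one scheme,
#' sized by the type-1 count rule so every scheme contributes about as many
#' images as there are affected study individuals.
#'
#' @param gan A trained GAN.
#' @param manifest Study manifest (drives the count rule).
#' @param type Scheme 1, 2, 3 or 4.
#' @param c_main Blend fraction for type 4.
#' @param seed Integer seed.
#' @return A generated cohort manifest.
#' @export
generate_augmentation <- function(gan, manifest, type = 3L, c_main = 0.55,
                                  seed = 1L) {
  counts <- type1_counts(manifest)
  if (type == 1) return(generate_type1(gan, manifest, seed = seed))
  per_disease <- stats::aggregate(n ~ disease, data = counts, sum)
  sets <- list()
  sid <- 900000L + type * 10000L
  ctr <- 0L
  if (type %in% c(2, 3)) {
    fun <- if (type == 2) generate_type2 else generate_type3
    for (i in seq_len(nrow(per_disease))) {
      d <- per_disease$disease[i]
      n_sets <- max(1L, round(per_disease$n[i] / 5))
      for (s in seq_len(n_sets)) {
        sets[[length(sets) + 1L]] <-
          fun(gan, d, seed = derive_seed(seed, ctr),
              start_identity = sid + ctr * 10L)
        ctr <- ctr + 1L
      }
    }
  } else if (type == 4) {
    total <- sum(per_disease$n)
    n_sets <- max(1L, round(total / 6))
    mains <- c("WS", "22q")
    for (s in seq_len(n_sets)) {
      for (m in mains) {
        a <- age_brackets()[(ctr %% 5) + 1]
        sets[[length(sets) + 1L]] <-
          generate_type4(gan, a, c_main = c_main, main = m,
                         seed = derive_seed(seed, ctr),
                         start_identity = sid + ctr * 10L)
        ctr <- ctr + 1L
      }
    }
  } else {
    stop("type must be 1, 2, 3 or 4", call. = FALSE)
  }
  out <- dplyr::bind_rows(sets)
  class(out) <- c("cohort_manifest", class(out))
  out
}
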