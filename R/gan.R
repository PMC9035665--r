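#' GAN configuration
#'
#' Desk-scale settings for the conditional GAN. The generator is a dense
#' network with one tanh hidden layer plus a linear skip path from its input
#' (latent vector and condition) straight to the pixel logits; its output
#' bias is initialised to the logit of the training-set mean image so
#' training starts from the data mean. Conditioning enters the generator as
#' the concatenated (age embedding, disease embedding) vector built by
#' [make_condition()] from the trainable [embedding_table()] — the
#' factorized embedding is the point: one age row per bracket is shared by,
#' and trained from, images of every disease. The discriminator is a
#' projection discriminator: a tanh feature layer on the image with an
#' unconditional score head plus an inner product between the features and a
#' learned additive (age row + disease row) label projection.
#'
#' Training combines four terms, all standard stabilisers for small
#' conditional GANs: the least-squares adversarial objective; matching-aware
#' negatives (real images paired with permuted labels are scored as fakes,
#' which penalises label-image mismatch); a paired conditional
#' reconstruction anchor (the fake generated under image j's labels is
#' pulled toward image j, anchoring the generator to the conditional mean);
#' and a diversity hinge (two fakes sharing a condition are pushed apart
#' until their mean squared difference reaches a margin, so the latent keeps
#' carrying within-condition "identity" variation instead of collapsing).
#'
#' @param image_size Generated image side (images are RGB), default 32.
#' @param latent_dim Latent vector dimension.
#' @param e_d,e_a Disease / age embedding dimensions (desk default 32 each;
#'   the full-scale preset is 256/256, giving a 512-length condition vector).
#' @param hidden_g,hidden_d Hidden widths of generator / discriminator.
#' @param iters Training iterations (one discriminator and one generator
#'   step each).
#' @param batch Batch size; every batch holds `batch/2` affected and
#'   `batch/2` unaffected images.
#' @param lr Adam learning rate for generator and discriminator.
#' @param lr_embed Adam learning rate for the embedding table (smaller, so
#'   the condition space the generator is conditioned on drifts slowly).
#' @param embed_init_sd Standard deviation of the embedding initialisation
#'   (unit scale, comparable to the latent input).
#' @param embed_freeze_frac Fraction of training during which the embedding
#'   table is updated; 1 trains it throughout.
#' @param mismatch_weight Weight of the matching-aware negative term in the
#'   discriminator loss.
#' @param latent_skip_sd Initialisation scale of the latent block of the
#'   generator skip path (larger keeps the latent influential from the
#'   start).
#' @param recon_weight Weight of the paired conditional reconstruction
#'   anchor in the generator loss.
#' @param diversity_weight,diversity_margin Weight and mean-squared-pixel
#'   margin of the diversity hinge.
#' @param aux_per_bracket Cap on unaffected auxiliary images per age bracket
#'   used for training (full-scale preset 500).
#' @return A list of class `gan_config`.
#' @export
gan_config <- function(image_size = 32L, latent_dim = 16L,
                       e_d = 32L, e_a = 32L,
                       hidden_g = 128L, hidden_d = 64L,
                       iters = 3000L, batch = 16L, lr = 2e-3,
                       lr_embed = 2e-4, embed_init_sd = 1,
                       embed_freeze_frac = 1, mismatch_weight = 1,
                       latent_skip_sd = 0.05, recon_weight = 50,
                       diversity_weight = 50, diversity_margin = 0.005,
                       aux_per_bracket = 500L) {
  stopifnot(batch %% 2 == 0)
  structure(list(image_size = as.integer(image_size),
                 latent_dim = as.integer(latent_dim),
                 e_d = as.integer(e_d), e_a = as.integer(e_a),
                 hidden_g = as.integer(hidden_g),
                 hidden_d = as.integer(hidden_d),
                 iters = as.integer(iters), batch = as.integer(batch),
                 lr = lr, lr_embed = lr_embed,
                 embed_init_sd = embed_init_sd,
                 embed_freeze_frac = embed_freeze_frac,
                 mismatch_weight = mismatch_weight,
                 latent_skip_sd = latent_skip_sd,
                 recon_weight = recon_weight,
                 diversity_weight = diversity_weight,
                 diversity_margin = diversity_margin,
                 aux_per_bracket = as.integer(aux_per_bracket)),
            class = "gan_config")
}

#' Factorized disease / age embedding table
#'
#' Two trainable matrices — disease `4 x e_d` and age `5 x e_a` — replace a
#' single per-(disease, age)-cell label embedding. A condition vector is the
#' concatenation of a convex combination of age rows with a convex
#' combination of disease rows, so its length is `e_a + e_d` (512 at the
#' full-scale 256/256 preset). Because every image, whatever its disease,
#' contributes gradient to its age bracket's row, rare (disease, age) cells
#' still get a well-trained age representation.
#'
#' @param e_d,e_a Embedding dimensions.
#' @param seed Seed for the random initialisation.
#' @param init_sd Standard deviation of the initial entries.
#' @return An object of class `embedding_table` with matrices `disease`
#'   (rows named by [disease_labels()]) and `age` (rows named by
#'   [age_brackets()]).
#' @export
#' @examples
#' tab <- embedding_table(256, 256)
#' length(make_condition(tab, c(1, 0, 0, 0, 0), c(1, 0, 0, 0)))
embedding_table <- function(e_d = 32L, e_a = 32L, seed = 1L, init_sd = 1) {
  with_local_seed(seed, {
    dis <- matrix(rnorm(4 * e_d, 0, init_sd), 4, e_d,
                  dimnames = list(disease_labels(), NULL))
    age <- matrix(rnorm(5 * e_a, 0, init_sd), 5, e_a,
                  dimnames = list(age_brackets(), NULL))
    structure(list(disease = dis, age = age, e_d = as.integer(e_d),
                   e_a = as.integer(e_a)),
              class = "embedding_table")
  })
}

#' Build a condition vector from embedding coefficients
#'
#' Returns `c(sum_a w_a * ageRow_a, sum_d v_d * diseaseRow_d)`: the convex
#' combination of age rows concatenated with the convex combination of
#' disease rows. Exactly linear in both coefficient sets; one-hot
#' coefficients select single rows.
#'
#' @param table An [embedding_table()].
#' @param age_coeffs Length-5 nonnegative weights summing to 1 (order of
#'   [age_brackets()]).
#' @param disease_coeffs Length-4 nonnegative weights summing to 1 (order of
#'   [disease_labels()]).
#' @return Numeric vector of length `e_a + e_d`.
#' @export
make_condition <- function(table, age_coeffs, disease_coeffs) {
  stopifnot(inherits(table, "embedding_table"))
  if (length(age_coeffs) != 5 || length(disease_coeffs) != 4) {
    stop("age_coeffs must have length 5 and disease_coeffs length 4",
         call. = FALSE)
  }
  if (any(age_coeffs < 0) || any(disease_coeffs < 0)) {
    stop("coefficients must be nonnegative", call. = FALSE)
  }
  if (abs(sum(age_coeffs) - 1) > 1e-9 || abs(sum(disease_coeffs) - 1) > 1e-9) {
    stop("coefficient sets must each sum to 1 (within 1e-9)", call. = FALSE)
  }
  c(as.vector(age_coeffs %*% table$age),
    as.vector(disease_coeffs %*% table$disease))
}

one_hot <- function(label, levels) as.numeric(levels == label)

condition_for <- function(table, disease, age) {
  make_condition(table, one_hot(age, age_brackets()),
                 one_hot(disease, disease_labels()))
}

# ---- numerics ------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# keep generated pixels off exact 0/1 so logs and gradients stay finite
clamp01 <- function(x) pmin(pmax(x, 1e-7), 1 - 1e-7)

init_layer <- function(n_out, n_in, sd = NULL) {
  list(W = matrix(rnorm(n_out * n_in, 0, sd %||% sqrt(2 / n_in)),
                  n_out, n_in),
       b = numeric(n_out))
}

# generator forward pass (mirrors the compiled training core exactly):
# tanh hidden layer plus a linear skip from [latent; condition] to the
# pixel logits, sigmoid output clamped off exact 0/1
g_forward <- function(G, z, C) {
  inp <- rbind(z, C)
  a <- tanh(G$W1 %*% inp + G$b1)
  x <- clamp01(sigmoid(G$W2 %*% a + G$b2 + G$Ws %*% inp))
  list(inp = inp, a = a, x = x)
}

flatten_image <- function(img) as.vector(img)

#' Train the conditional GAN
#'
#' Adversarially trains the generator, the projection discriminator and the
#' factorized embedding table on study affected images plus an unaffected
#' auxiliary subsample (capped per age bracket). Every training batch
#' contains an equal number of affected and unaffected images. The
#' discriminator sees three kinds of pairs per step: real images with their
#' labels (target "real"), generated images with the conditioning labels
#' (target "fake"), and real images with within-batch permuted labels
#' (also "fake") so that label-image mismatch is penalised and the generator
#' is pushed toward conditional fidelity, not just marginal realism. The
#' generator loss adds the conditional reconstruction anchor and the
#' diversity hinge described in [gan_config()].
#'
#' The embedding table is generator-side: it receives gradient through the
#' generator objective only, at the smaller `lr_embed`. Because the age
#' matrix rows are shared across diseases, every image in a batch — whatever
#' its disease — contributes gradient to its age bracket's row; the
#' accumulated magnitude is recorded per (age bracket, disease of the
#' contributing image) in `age_grad_audit`.
#'
#' @param study Study cohort manifest with images at `config$image_size`
#'   (affected rows are those with a disease other than `unaffected`).
#' @param aux Auxiliary unaffected manifest with images (subsampled to
#'   `config$aux_per_bracket` per bracket).
#' @param config A [gan_config()].
#' @param seed Integer seed.
#' @return An object of class `face_gan`: generator `G`, discriminator `D`,
#'   `table` (the trained [embedding_table()]), a per-iteration `trace`
#'   tibble with mean discriminator scores on real and fake batches,
#'   `batch_affected_fraction`, and the 5 x 4 `age_grad_audit` matrix.
#' @export
train_gan <- function(study, aux, config = gan_config(), seed = 1L) {
  affected <- study[study$disease != "unaffected", ]
  if (nrow(affected) == 0) stop("no affected images", call. = FALSE)
  if (nrow(aux) == 0) stop("no unaffected images", call. = FALSE)
  npx <- config$image_size^2 * 3
  chk <- dim(affected$image[[1]])
  if (chk[1] != config$image_size) {
    stop(sprintf("images are %dpx but config$image_size is %d",
                 chk[1], config$image_size), call. = FALSE)
  }

  with_local_seed(seed, {
    keep <- unlist(lapply(age_brackets(), function(a) {
      idx <- which(aux$age == a)
      if (length(idx) > config$aux_per_bracket) {
        sample(idx, config$aux_per_bracket)
      } else {
        idx
      }
    }))
    pool <- dplyr::bind_rows(affected, aux[keep, ])
    x_all <- vapply(pool$image, flatten_image, numeric(npx))
    is_aff <- pool$disease != "unaffected"
    age_idx <- match(pool$age, age_brackets())
    dis_idx <- match(pool$disease, disease_labels())

    tab <- embedding_table(config$e_d, config$e_a,
                           seed = derive_seed(seed, 1L),
                           init_sd = config$embed_init_sd)
    cdim <- config$e_a + config$e_d

    G <- c(stats::setNames(init_layer(config$hidden_g,
                                      config$latent_dim + cdim),
                           c("W1", "b1")),
           stats::setNames(init_layer(npx, config$hidden_g), c("W2", "b2")))
    G$Ws <- init_layer(npx, config$latent_dim + cdim, sd = 0.01)$W
    # the latent block of the skip starts stronger so the generator keeps
    # using z for within-condition diversity
    G$Ws[, seq_len(config$latent_dim)] <-
      matrix(rnorm(npx * config$latent_dim, 0, config$latent_skip_sd), npx)
    G$b2 <- logit(pmin(pmax(rowMeans(x_all), 0.02), 0.98))
    D <- list(W1 = init_layer(config$hidden_d, npx)$W,
              b1 = numeric(config$hidden_d),
              w0 = matrix(rnorm(config$hidden_d, 0,
                                sqrt(1 / config$hidden_d)), 1),
              b0 = 0,
              V = matrix(rnorm(9 * config$hidden_d, 0,
                               sqrt(1 / config$hidden_d)), 9))

    fit <- .gan_train_cpp(
      x_all, as.integer(age_idx), as.integer(dis_idx),
      which(is_aff), which(!is_aff), G, D,
      tab$age, tab$disease,
      config$iters, config$batch, config$latent_dim,
      config$lr, config$lr_embed,
      as.integer(round(config$embed_freeze_frac * config$iters)),
      config$mismatch_weight, config$recon_weight,
      config$diversity_weight, config$diversity_margin)

    tab$age <- fit$age_emb
    tab$disease <- fit$dis_emb
    dimnames(tab$age) <- list(age_brackets(), NULL)
    dimnames(tab$disease) <- list(disease_labels(), NULL)
    audit <- fit$audit
    dimnames(audit) <- list(age_brackets(), disease_labels())
    G <- fit$G
    G$b1 <- as.vector(G$b1); G$b2 <- as.vector(G$b2)
    D <- fit$D
    D$b1 <- as.vector(D$b1)
    structure(
      list(G = G, D = D, table = tab, config = config,
           seed = as.integer(seed),
           trace = tibble::tibble(iter = seq_len(config$iters),
                                  d_real = as.vector(fit$trace_real),
                                  d_fake = as.vector(fit$trace_fake),
                                  g_loss = as.vector(fit$g_loss)),
           batch_affected_fraction = as.vector(fit$aff_frac),
           age_grad_audit = audit,
           n_affected = sum(is_aff), n_unaffected = sum(!is_aff)),
      class = "face_gan"
    )
  })
}

#' @export
print.face_gan <- function(x, ...) {
  cat(sprintf(
    "<face_gan> %dpx, condition %d (e_a=%d + e_d=%d), %d iters on %d affected + %d unaffected\n",
    x$config$image_size, x$config$e_a + x$config$e_d, x$config$e_a,
    x$config$e_d, x$config$iters, x$n_affected, x$n_unaffected))
  invisible(x)
}

#' Generate images from the trained generator
#'
#' @param gan A `face_gan`.
#' @param age_coeffs,disease_coeffs Coefficients for [make_condition()].
#' @param z Latent matrix (`latent_dim x n`) or vector; see [gan_latent()].
#' @return A list of `image_size x image_size x 3` arrays in `[0, 1]`.
#' @export
gan_generate <- function(gan, age_coeffs, disease_coeffs, z) {
  stopifnot(inherits(gan, "face_gan"))
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  stopifnot(nrow(z) == gan$config$latent_dim)
  cond <- make_condition(gan$table, age_coeffs, disease_coeffs)
  C <- matrix(cond, length(cond), ncol(z))
  x <- g_forward(gan$G, z, C)$x
  n <- gan$config$image_size
  lapply(seq_len(ncol(x)), function(i) array(x[, i], dim = c(n, n, 3)))
}

#' Draw latent vectors
#'
#' Standard-normal latents of the generator's configured dimension.
#'
#' @param gan A `face_gan`.
#' @param n Number of latents.
#' @param seed Integer seed.
#' @return A `latent_dim x n` matrix.
#' @export
gan_latent <- function(gan, n = 1L, seed = 1L) {
  with_local_seed(seed, {
    matrix(rnorm(gan$config$latent_dim * n), gan$config$latent_dim, n)
  })
}
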