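#' Configuration for the expression VAE
#'
#' The generative model is a variational autoencoder: a multilayer
#' perceptron encoder mapping a cell's expression vector to the mean and
#' (log-)variance of a diagonal-Gaussian approximate posterior over a
#' latent space, and an MLP decoder mapping latent vectors back to
#' expression. Every layer is followed by a ReLU except the encoder's
#' final (Gaussian-parameter) layer; the decoder's final ReLU guarantees
#' non-negative output. Defaults follow the reference architecture:
#' encoder widths 2048/1024/512/256, decoder widths 512/1024/2048 (plus
#' the gene-count output layer), latent dimension 128. For small training
#' sets the widths can be reduced substantially without hurting recovery.
#'
#' @param latent_dim Latent space dimensionality.
#' @param encoder_widths Hidden-layer widths of the encoder MLP.
#' @param decoder_widths Hidden-layer widths of the decoder MLP (the final
#'   layer to the gene count is appended automatically).
#' @param epochs,batch_size,learning_rate Training hyperparameters
#'   (Adam optimizer).
#' @param kl_warmup Fraction of epochs over which the KL term's weight is
#'   annealed linearly from 0 to 1 (standard warm-up schedule that avoids
#'   early posterior collapse and keeps reconstructions sharp; the final
#'   objective is the unweighted ELBO).
#' @param seed Integer seed controlling initialization, shuffling and the
#'   reparameterization draws.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 128L,
                       encoder_widths = c(2048L, 1024L, 512L, 256L),
                       decoder_widths = c(512L, 1024L, 2048L),
                       epochs = 200L, batch_size = 128L,
                       learning_rate = 1e-3, kl_warmup = 0.3, seed = 1L) {
  stopifnot(latent_dim > 0L, length(encoder_widths) >= 1L,
            length(decoder_widths) >= 1L, epochs >= 1L, batch_size >= 1L,
            learning_rate > 0, kl_warmup >= 0, kl_warmup <= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 kl_warmup = kl_warmup,
                 seed = as.integer(seed)),
            class = "vae_config")
}

#' Reparameterized latent draw
#'
#' Deterministic transform `z = mu + sigma * eps` that moves the sampling
#' outside the network so gradients can flow through `mu` and `sigma`.
#'
#' @param mu,sigma Numeric vectors (or matrices) of equal shape;
#'   `sigma >= 0` elementwise.
#' @param eps Standard-normal draw of the same shape.
#' @return `mu + sigma * eps`.
#' @export
reparameterize <- function(mu, sigma, eps) {
  if (!all(dim2(mu) == dim2(sigma)) || !all(dim2(mu) == dim2(eps)))
    stop("mu, sigma and eps must have identical shape", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  mu + sigma * eps
}

dim2 <- function(x) if (is.matrix(x)) dim(x) else length(x)

#' Analytic KL divergence to the standard-normal prior
#'
#' KL(N(mu, diag(sigma^2)) || N(0, I)) summed over latent dimensions:
#' `0.5 * sum(mu^2 + sigma^2 - 1 - 2*log(sigma))`. Zero exactly when
#' `mu = 0`, `sigma = 1`.
#'
#' @param mu,sigma Posterior mean and s.d. vectors (or matrices with one
#'   row per cell; the KL is then computed per row and summed over
#'   columns, returning a vector).
#' @return Non-negative KL value(s).
#' @export
kl_gaussian <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  term <- mu^2 + sigma^2 - 1 - 2 * log(sigma)
  if (is.matrix(mu)) 0.5 * rowSums(term) else 0.5 * sum(term)
}

# -- MLP internals ------------------------------------------------------------
# Weights stored as list(W, b) with h_out = h_in %*% t(W) + b, batch in rows.

mlp_init_layer <- function(fan_in, fan_out) {
  list(W = matrix(stats::rnorm(fan_out * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = fan_out),
       b = rep(0, fan_out))
}

mlp_forward <- function(layers, x, final_relu = TRUE) {
  pre <- vector("list", length(layers))
  act <- vector("list", length(layers) + 1L)
  act[[1L]] <- x
  for (i in seq_along(layers)) {
    p <- act[[i]] %*% t(layers[[i]]$W)
    p <- sweep(p, 2L, layers[[i]]$b, "+")
    pre[[i]] <- p
    act[[i + 1L]] <- if (i < length(layers) || final_relu) pmax(p, 0) else p
  }
  list(pre = pre, act = act, out = act[[length(act)]])
}

mlp_backward <- function(layers, fwd, dout, final_relu = TRUE) {
  grads <- vector("list", length(layers))
  d <- dout
  for (i in rev(seq_along(layers))) {
    if (i < length(layers) || final_relu) d <- d * (fwd$pre[[i]] > 0)
    grads[[i]] <- list(W = t(d) %*% fwd$act[[i]], b = colSums(d))
    d <- d %*% layers[[i]]$W
  }
  list(grads = grads, dinput = d)
}

adam_step <- function(state, params, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    for (nm in c("W", "b")) {
      g <- grads[[i]][[nm]]
      state[[i]][[nm]]$m <- beta1 * state[[i]][[nm]]$m + (1 - beta1) * g
      state[[i]][[nm]]$v <- beta2 * state[[i]][[nm]]$v + (1 - beta2) * g^2
      mhat <- state[[i]][[nm]]$m / (1 - beta1^t)
      vhat <- state[[i]][[nm]]$v / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(state = state, params = params)
}

adam_init <- function(params) {
  lapply(params, function(l) {
    list(W = list(m = l$W * 0, v = l$W * 0),
         b = list(m = l$b * 0, v = l$b * 0))
  })
}

vae_encode <- function(model, x) {
  fwd <- mlp_forward(model$enc, x, final_relu = TRUE)
  h <- fwd$out
  mu <- sweep(h %*% t(model$mu_head$W), 2L, model$mu_head$b, "+")
  logvar <- sweep(h %*% t(model$lv_head$W), 2L, model$lv_head$b, "+")
  list(fwd = fwd, mu = mu, logvar = logvar)
}

vae_decode <- function(model, z) {
  mlp_forward(model$dec, z, final_relu = TRUE)
}

vae_loss_parts <- function(model, x, eps, beta = 1) {
  enc <- vae_encode(model, x)
  sigma <- exp(0.5 * enc$logvar)
  z <- reparameterize(enc$mu, sigma, eps)
  dec <- vae_decode(model, z)
  if (!all(is.finite(dec$out)))
    stop("non-finite activations in decoder forward pass", call. = FALSE)
  B <- nrow(x)
  recon <- 0.5 * sum((dec$out - x)^2) / B
  kl <- sum(kl_gaussian(enc$mu, sigma)) / B
  list(enc = enc, dec = dec, sigma = sigma, z = z,
       recon = recon, kl = kl, loss = recon + beta * kl)
}

#' Negative evidence lower bound for a batch
#'
#' Returns the training objective `-(E[log p(x|z)] - KL)` evaluated with a
#' Gaussian (mean-squared-error) reconstruction term: per-cell
#' `0.5 * ||x - xhat||^2 + KL(q(z|x) || N(0, I))`, averaged over the batch.
#'
#' @param model A trained (or initialized) `srt_vae` model.
#' @param batch Expression rows (cells x genes matrix).
#' @param eps Optional reparameterization draw (matrix, cells x latent);
#'   sampled fresh when `NULL`.
#' @param seed Optional seed for the draw.
#' @return Scalar loss (recon + KL), with the two parts attached as
#'   attributes `"recon"` and `"kl"`.
#' @export
elbo_loss <- function(model, batch, eps = NULL, seed = NULL) {
  batch <- matrix(as.double(batch), nrow = NROW(batch))
  if (ncol(batch) != length(model$gene_names))
    stop("batch has ", ncol(batch), " genes; model expects ",
         length(model$gene_names), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(eps))
    eps <- matrix(stats::rnorm(nrow(batch) * model$config$latent_dim),
                  nrow = nrow(batch))
  parts <- vae_loss_parts(model, batch, eps)
  structure(parts$loss, recon = parts$recon, kl = parts$kl)
}

#' Train the expression VAE on a labeled dataset
#'
#' Trains a single VAE on all cells jointly, then fits one diagonal
#' Gaussian per population to the encoder means of that population's
#' training cells. Per-population generation later samples latent vectors
#' from these summaries, exploiting the fact that distinct populations
#' occupy distinct regions of the latent space.
#'
#' @param ds A valid [expression_dataset()] (normalized expression).
#' @param cfg A [vae_config()].
#' @param verbose Print the per-epoch mean loss every 50 epochs.
#' @return An object of class `srt_vae` holding the network weights, the
#'   per-population latent summaries, the gene names, the config, and the
#'   per-epoch loss trace (`$epoch_loss`).
#' @export
train_vae <- function(ds, cfg = vae_config(), verbose = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  x_all <- ds$matrix
  k <- ncol(x_all)
  N <- nrow(x_all)
  set.seed(cfg$seed)

  enc_dims <- c(k, cfg$encoder_widths)
  enc <- purrr::map(seq_len(length(enc_dims) - 1L),
                    ~ mlp_init_layer(enc_dims[.x], enc_dims[.x + 1L]))
  last_w <- enc_dims[length(enc_dims)]
  mu_head <- mlp_init_layer(last_w, cfg$latent_dim)
  lv_head <- mlp_init_layer(last_w, cfg$latent_dim)
  dec_dims <- c(cfg$latent_dim, cfg$decoder_widths, k)
  dec <- purrr::map(seq_len(length(dec_dims) - 1L),
                    ~ mlp_init_layer(dec_dims[.x], dec_dims[.x + 1L]))
  # start the output units alive: a ReLU output unit whose pre-activation
  # goes negative for every input has zero gradient and leaves its gene
  # permanently dark, so the final bias is initialized at the per-gene
  # mean expression
  dec[[length(dec)]]$b <- colMeans(x_all)

  model <- structure(list(enc = enc, mu_head = mu_head, lv_head = lv_head,
                          dec = dec, gene_names = ds$gene_names,
                          config = cfg),
                     class = "srt_vae")

  params <- c(model$enc, list(model$mu_head, model$lv_head), model$dec)
  opt <- adam_init(params)
  n_enc <- length(model$enc)
  n_dec <- length(model$dec)
  t_step <- 0L
  epoch_loss <- numeric(cfg$epochs)

  warm_epochs <- max(1, cfg$kl_warmup * cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    beta <- min(1, epoch / warm_epochs)
    idx <- sample.int(N)
    batch_losses <- c()
    for (start in seq(1L, N, by = cfg$batch_size)) {
      rows <- idx[start:min(start + cfg$batch_size - 1L, N)]
      x <- x_all[rows, , drop = FALSE]
      B <- nrow(x)
      eps <- matrix(stats::rnorm(B * cfg$latent_dim), nrow = B)
      parts <- vae_loss_parts(model, x, eps, beta = beta)
      if (!is.finite(parts$loss))
        stop("non-finite loss at epoch ", epoch, ", batch starting at row ",
             start, call. = FALSE)
      batch_losses <- c(batch_losses, parts$loss)

      # backward: reconstruction through decoder
      dxhat <- (parts$dec$out - x) / B
      back_dec <- mlp_backward(model$dec, parts$dec, dxhat, final_relu = TRUE)
      dz <- back_dec$dinput
      # z = mu + exp(0.5*logvar) * eps
      dmu <- dz + beta * parts$enc$mu / B               # + KL d/dmu
      dlogvar <- dz * eps * 0.5 * parts$sigma +
        beta * 0.5 * (parts$sigma^2 - 1) / B            # + KL d/dlogvar
      # heads
      h <- parts$enc$fwd$out
      g_mu <- list(W = t(dmu) %*% h, b = colSums(dmu))
      g_lv <- list(W = t(dlogvar) %*% h, b = colSums(dlogvar))
      dh <- dmu %*% model$mu_head$W + dlogvar %*% model$lv_head$W
      back_enc <- mlp_backward(model$enc, parts$enc$fwd, dh,
                               final_relu = TRUE)
      grads <- c(back_enc$grads, list(g_mu, g_lv), back_dec$grads)
      t_step <- t_step + 1L
      upd <- adam_step(opt, params, grads, cfg$learning_rate, t_step)
      opt <- upd$state
      params <- upd$params
      model$enc <- params[seq_len(n_enc)]
      model$mu_head <- params[[n_enc + 1L]]
      model$lv_head <- params[[n_enc + 2L]]
      model$dec <- params[n_enc + 2L + seq_len(n_dec)]
    }
    epoch_loss[epoch] <- mean(batch_losses)
    if (verbose && (epoch %% 50L == 0L || epoch == 1L))
      message(sprintf("epoch %d: loss %.4f", epoch, epoch_loss[epoch]))
  }
  model$epoch_loss <- epoch_loss
  model$latent_summaries <- fit_latent_summaries(model, ds)
  model$train_zero_fraction <- mean(x_all == 0)
  model
}

fit_latent_summaries <- function(model, ds) {
  enc <- vae_encode(model, ds$matrix)
  pops <- sort(unique(ds$population))
  summaries <- purrr::map(pops, function(p) {
    rows <- which(ds$population == p)
    mu <- enc$mu[rows, , drop = FALSE]
    center <- colMeans(mu)
    if (nrow(mu) < 2L) {
      warning("population '", p, "' has a single cell; using unit variance",
              call. = FALSE)
      v <- rep(1, ncol(mu))
    } else {
      v <- apply(mu, 2L, stats::var)
      v <- pmax(v, 1e-8)
    }
    list(population = p, mean = center, var = v, n = nrow(mu))
  })
  stats::setNames(summaries, pops)
}

#' @export
print.srt_vae <- function(x, ...) {
  cat(sprintf(
    "<srt_vae> %d genes, latent %d, %d populations, %d epochs (final loss %.3f)\n",
    length(x$gene_names), x$config$latent_dim,
    length(x$latent_summaries), x$config$epochs,
    x$epoch_loss[length(x$epoch_loss)]))
  invisible(x)
}

#' Generate new cells of one population
#'
#' Samples latent vectors from the population's fitted latent Gaussian
#' and decodes them. Output is non-negative by construction (decoder final
#' ReLU) and byte-reproducible under a fixed seed.
#'
#' @param model A trained `srt_vae`.
#' @param population Population label present in the model.
#' @param count Number of cells to generate (0 gives an empty dataset).
#' @param seed Integer seed.
#' @param id_prefix Prefix for the generated cell ids.
#' @return An [expression_dataset()] with `count` cells.
#' @export
generate_cells <- function(model, population, count, seed = 1L,
                           id_prefix = "sim") {
  summ <- model$latent_summaries[[population]]
  if (is.null(summ))
    stop("unknown population: ", population, call. = FALSE)
  stopifnot(count >= 0L)
  d <- model$config$latent_dim
  set.seed(seed)
  if (count == 0L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = length(model$gene_names),
                dimnames = list(NULL, model$gene_names))
    return(expression_dataset(m, population = character(0),
                              cell_ids = character(0)))
  }
  eps <- matrix(stats::rnorm(count * d), nrow = count)
  z <- sweep(sweep(eps, 2L, sqrt(summ$var), "*"), 2L, summ$mean, "+")
  xhat <- vae_decode(model, z)$out
  rownames(xhat) <- sprintf("%s_%s_%04d", id_prefix, population,
                            seq_len(count))
  colnames(xhat) <- model$gene_names
  expression_dataset(xhat, population = rep(population, count))
}

#' Generate cells for several populations at once
#'
#' @param model A trained `srt_vae`.
#' @param counts Named integer vector: cells to generate per population.
#' @param seed Integer seed (per-population seeds are derived by offset).
#' @return One [expression_dataset()] with all generated cells.
#' @export
generate_population_mix <- function(model, counts, seed = 1L) {
  pops <- names(counts)
  stopifnot(!is.null(pops))
  parts <- purrr::imap(counts, function(ct, p) {
    generate_cells(model, p, ct,
                   seed = (seed + 1000L * match(p, pops)) %% .Machine$integer.max)
  })
  m <- do.call(rbind, purrr::map(parts, "matrix"))
  expression_dataset(m,
                     population = unlist(purrr::map(parts,
                                                    ~ unname(.x$population))))
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Model-level summary of a trained VAE
#' @param x An `srt_vae`.
#' @param ... Unused.
#' @return One-row tibble: genes, latent dim, populations, epochs, first
#'   and final epoch loss, training zero fraction.
#' @method glance srt_vae
#' @export
glance.srt_vae <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_names),
    latent_dim = x$config$latent_dim,
    n_populations = length(x$latent_summaries),
    epochs = x$config$epochs,
    first_epoch_loss = x$epoch_loss[1L],
    final_epoch_loss = x$epoch_loss[length(x$epoch_loss)],
    train_zero_fraction = x$train_zero_fraction)
}

#' Per-population latent summaries of a trained VAE
#' @param x An `srt_vae`.
#' @param ... Unused.
#' @return Tibble with one row per population and latent dimension:
#'   `population`, `dimension`, `mean`, `var`, `n_cells`.
#' @method tidy srt_vae
#' @export
tidy.srt_vae <- function(x, ...) {
  purrr::map_dfr(x$latent_summaries, function(s) {
    tibble::tibble(population = s$population,
                   dimension = seq_along(s$mean),
                   mean = s$mean, var = s$var, n_cells = s$n)
  })
}

#' Save / load a trained VAE
#'
#' The checkpoint is a plain-text JSON file holding the weights, the
#' latent summaries, gene names and config, so it survives text-only
#' pipelines; a compact sidecar with the config alone is written next to
#' it for quick inspection.
#'
#' @param model An `srt_vae`.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
save_vae <- function(model, path) {
  ser <- list(
    enc = purrr::map(model$enc, ~ list(W = .x$W, b = .x$b)),
    mu_head = list(W = model$mu_head$W, b = model$mu_head$b),
    lv_head = list(W = model$lv_head$W, b = model$lv_head$b),
    dec = purrr::map(model$dec, ~ list(W = .x$W, b = .x$b)),
    gene_names = model$gene_names,
    config = unclass(model$config),
    epoch_loss = model$epoch_loss,
    train_zero_fraction = model$train_zero_fraction,
    latent_summaries = purrr::map(model$latent_summaries, function(s)
      list(population = s$population, mean = s$mean, var = s$var, n = s$n)))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  cfg_path <- paste0(tools::file_path_sans_ext(path), ".config.json")
  jsonlite::write_json(unclass(model$config), cfg_path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_vae
#' @param path Path written by [save_vae()].
#' @return For `load_vae`, the restored `srt_vae` model.
#' @export
load_vae <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  relayer <- function(l) list(W = as.matrix(l$W), b = as.double(l$b))
  cfg <- do.call(vae_config, ser$config[c("latent_dim", "encoder_widths",
                                          "decoder_widths", "epochs",
                                          "batch_size", "learning_rate",
                                          "kl_warmup", "seed")])
  model <- structure(list(
    enc = purrr::map(seq_len(length(ser$enc$W)),
                     ~ list(W = as.matrix(ser$enc$W[[.x]]),
                            b = as.double(ser$enc$b[[.x]]))),
    mu_head = relayer(ser$mu_head),
    lv_head = relayer(ser$lv_head),
    dec = purrr::map(seq_len(length(ser$dec$W)),
                     ~ list(W = as.matrix(ser$dec$W[[.x]]),
                            b = as.double(ser$dec$b[[.x]]))),
    gene_names = as.character(ser$gene_names),
    config = cfg,
    epoch_loss = as.double(ser$epoch_loss),
    train_zero_fraction = as.double(ser$train_zero_fraction)),
    class = "srt_vae")
  model$latent_summaries <- purrr::map(ser$latent_summaries, function(s)
    list(population = s$population, mean = as.double(s$mean),
         var = as.double(s$var), n = as.integer(s$n)))
  names(model$latent_summaries) <-
    purrr::map_chr(model$latent_summaries, "population")
  model
}
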