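# Twin-encoder internals.  Both legs share one parameter set (tied
# weights); a grid batch is a (18 * D^3) x B matrix in the channel-first
# column layout of grid_column().  Encoder: conv3(18 -> F1) -> ReLU ->
# conv3(F1 -> F2) -> ReLU -> maxpool2 -> conv3(F2 -> latent) -> ReLU ->
# global spatial max pool -> latent vector.  The head is a bias-free
# linear map on the latent difference, so f(a, b) = -f(b, a) exactly.

xavier <- function(nrow, ncol, fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -a, a), nrow, ncol)
}

#' Initialize network parameters
#'
#' Xavier (Glorot) uniform initialization for the three convolutions and the
#' bias-free head; biases start at zero.
#'
#' @param config a [pairpot_config()].
#' @param seed integer seed (the caller's RNG stream is preserved).
#' @return a named list of parameter arrays of class `pairnet_params`.
#' @export
init_params <- function(config = pairpot_config(), seed = 1) {
  F1 <- config$filters1; F2 <- config$filters2; L <- config$latent
  with_seed(derive_seed(seed, "init"), {
    p <- list(
      W1 = xavier(F1, 18 * 27, 18 * 27, F1 * 27), b1 = numeric(F1),
      W2 = xavier(F2, F1 * 27, F1 * 27, F2 * 27), b2 = numeric(F2),
      W3 = xavier(L, F2 * 27, F2 * 27, L * 27), b3 = numeric(L),
      head = drop(xavier(L, 1, L, 1)))
    class(p) <- "pairnet_params"
    p
  })
}

# Forward pass of one leg on a batch; keeps what the backward pass needs.
encode_fwd <- function(params, X, config, keep_cache = TRUE) {
  D <- config$grid_dim; H <- D %/% 2L
  F1 <- config$filters1; F2 <- config$filters2; L <- config$latent
  A1 <- conv3d_fwd(X, params$W1, params$b1, 18L, D)
  M1 <- A1 > 0; Z1 <- A1 * M1
  A2 <- conv3d_fwd(Z1, params$W2, params$b2, F1, D)
  M2 <- A2 > 0; A2 <- A2 * M2
  P <- maxpool2_fwd(A2, F2, D)
  A3 <- conv3d_fwd(P$y, params$W3, params$b3, F2, H)
  M3 <- A3 > 0; A3 <- A3 * M3
  G <- gpool_fwd(A3, L, H^3)
  cache <- if (keep_cache)
    list(X = X, M1 = M1, Z1 = Z1, M2 = M2, pidx = P$idx, P = P$y,
         M3 = M3, gidx = G$idx, n2 = F2 * D^3, n3 = L * H^3)
  list(latent = G$y, cache = cache)
}

encode_bwd <- function(params, cache, dlatent, config) {
  D <- config$grid_dim; H <- D %/% 2L
  F1 <- config$filters1; F2 <- config$filters2
  dZ3 <- maxpool_bwd(cache$gidx, dlatent, cache$n3)
  dA3 <- dZ3 * cache$M3
  g3 <- conv3d_bwd(cache$P, params$W3, dA3, F2, H, TRUE)
  dZ2 <- maxpool_bwd(cache$pidx, g3$dX, cache$n2)
  dA2 <- dZ2 * cache$M2
  g2 <- conv3d_bwd(cache$Z1, params$W2, dA2, F1, D, TRUE)
  dA1 <- g2$dX * cache$M1
  g1 <- conv3d_bwd(cache$X, params$W1, dA1, 18L, D, FALSE)
  list(W1 = g1$dW, b1 = as.numeric(g1$db),
       W2 = g2$dW, b2 = as.numeric(g2$db),
       W3 = g3$dW, b3 = as.numeric(g3$db))
}

#' Encode a voxel grid into the latent representation
#'
#' Runs one leg of the twin network in evaluation mode (dropout off):
#' deterministic for identical grids.
#'
#' @param params a `pairnet_params` list (or a fitted [pairpot()] model).
#' @param grid a `voxel_grid` (or anything with `18 * D^3` values in grid
#'   column layout).
#' @param config a [pairpot_config()].
#' @return numeric latent vector of length `config$latent` (192 by default).
#' @export
encode_grid <- function(params, grid, config = pairpot_config()) {
  if (inherits(params, "pairpot")) {
    config <- params$config; params <- params$params
  }
  X <- matrix(grid_column(grid), ncol = 1)
  drop(encode_fwd(params, X, config, keep_cache = FALSE)$latent)
}

#' Predict the potency difference for one ligand pair
#'
#' `head . (encode(a) - encode(b))`: the predicted `pIC50(a) - pIC50(b)`.
#' Antisymmetric by construction.
#'
#' @inheritParams encode_grid
#' @param grid_a,grid_b voxel grids of the two complexes.
#' @return scalar predicted delta-pIC50.
#' @export
predict_delta <- function(params, grid_a, grid_b,
                          config = pairpot_config()) {
  if (inherits(params, "pairpot")) {
    config <- params$config; params <- params$params
  }
  X <- cbind(grid_column(grid_a), grid_column(grid_b))
  lat <- encode_fwd(params, X, config, keep_cache = FALSE)$latent
  sum(params$head * (lat[, 1] - lat[, 2]))
}

# Batched delta prediction: Xa, Xb are (18*S x B) matrices.
forward_batch <- function(params, Xa, Xb, config) {
  lat <- encode_fwd(params, cbind(Xa, Xb), config, keep_cache = FALSE)$latent
  B <- ncol(Xa)
  as.numeric(crossprod(params$head,
                       lat[, seq_len(B), drop = FALSE] -
                         lat[, B + seq_len(B), drop = FALSE]))
}

#' Enumerate training or test ligand pairs
#'
#' Training pairs are all unordered pairs among the ligands with known
#' potency, in one canonical order (earlier series position first), giving
#' `n(n-1)/2` samples labelled `pIC50(a) - pIC50(b)`; the antisymmetry of
#' the network makes the mirrored pair redundant.  Test pairs are every
#' ordered (test, train) combination, `n * m` samples.
#'
#' @param series a [congeneric_series()].
#' @param train_ids ids with experimentally known potency.
#' @param test_ids if given, build (test, train) pairs instead of training
#'   pairs.
#' @return data frame with columns `a`, `b`, `label` (`NA` when a test
#'   ligand has no recorded potency).
#' @export
build_pairs <- function(series, train_ids, test_ids = NULL) {
  pic <- series_pic50(series)
  if (is.null(test_ids)) {
    known <- train_ids[!is.na(pic[train_ids])]
    if (length(known) < 2)
      stop("need at least 2 ligands with known potency to build ",
           "training pairs (got ", length(known), ")")
    idx <- utils::combn(known, 2)
    data.frame(a = idx[1, ], b = idx[2, ],
               label = pic[idx[1, ]] - pic[idx[2, ]],
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    grid <- expand.grid(b = train_ids, a = test_ids,
                        stringsAsFactors = FALSE)
    data.frame(a = grid$a, b = grid$b, label = pic[grid$a] - pic[grid$b],
               stringsAsFactors = FALSE, row.names = NULL)
  }
}

# Lazily caches unrotated grid columns per ligand and shares the protein
# half of the grid; with a rotation everything is re-voxelized.
make_grid_provider <- function(series, config) {
  cache <- new.env(parent = emptyenv())
  center <- series$pocket_center
  S <- config$grid_dim^3
  base_protein <- NULL
  get_base <- function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    if (is.null(base_protein))
      base_protein <<- matrix(voxelize_protein(series$protein, center,
                                               config), nrow = 8)
    gl <- matrix(voxelize_ligand(series$ligands[[id]], center, config),
                 nrow = 10)
    col <- as.numeric(rbind(base_protein, gl))
    cache[[id]] <- col
    col
  }
  function(ids, rotation = NULL) {
    if (is.null(rotation)) {
      out <- vapply(ids, get_base, numeric(18 * S))
      return(matrix(out, ncol = length(ids)))
    }
    gp <- matrix(voxelize_protein(series$protein, center, config, rotation),
                 nrow = 8)
    out <- vapply(ids, function(id) {
      gl <- matrix(voxelize_ligand(series$ligands[[id]], center, config,
                                   rotation), nrow = 10)
      as.numeric(rbind(gp, gl))
    }, numeric(18 * S))
    matrix(out, ncol = length(ids))
  }
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, state, config, lr) {
  state$t <- state$t + 1
  b1 <- config$adam_beta1; b2 <- config$adam_beta2; eps <- config$adam_eps
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# Single gradient step on one minibatch; returns loss and updated params.
# Columns of Xa/Xb hold the two grids of each pair.
pair_batch_grads <- function(params, Xa, Xb, y, config, dropout_masks) {
  B <- ncol(Xa)
  fw <- encode_fwd(params, cbind(Xa, Xb), config, keep_cache = TRUE)
  lat <- fw$latent
  Za <- lat[, seq_len(B), drop = FALSE]
  Zb <- lat[, B + seq_len(B), drop = FALSE]
  if (!is.null(dropout_masks)) {
    Za <- Za * dropout_masks$a
    Zb <- Zb * dropout_masks$b
  }
  diff <- Za - Zb
  pred <- as.numeric(crossprod(params$head, diff))
  err <- pred - y
  loss <- mean(err^2)
  dpred <- 2 * err / B
  dhead <- as.numeric(diff %*% dpred)
  ddiff <- params$head %o% dpred
  dZa <- ddiff; dZb <- -ddiff
  if (!is.null(dropout_masks)) {
    dZa <- dZa * dropout_masks$a
    dZb <- dZb * dropout_masks$b
  }
  grads <- encode_bwd(params, fw$cache, cbind(dZa, dZb), config)
  grads$head <- dhead
  list(loss = loss, grads = grads, pred = pred)
}

#' Train the twin network on labelled ligand pairs
#'
#' Minimizes the mean squared error of the predicted versus labelled
#' delta-pIC50 with Adam.  With `augment = TRUE` every pair is re-voxelized
#' each epoch under a fresh uniform random rotation applied identically to
#' both grids of the pair.  Fully seeded: identical seeds give identical
#' final weights.
#'
#' @param provider grid provider from `make_grid_provider()`, or a
#'   [congeneric_series()] (a provider is built internally).
#' @param pairs data frame from [build_pairs()] (columns a, b, label).
#' @param config a [pairpot_config()].
#' @param seed run seed; every stochastic choice (initialization, shuffling,
#'   dropout, rotations) derives from it.
#' @param epochs training epochs.
#' @param augment rotation augmentation on/off.
#' @param params optional warm-start parameters (used by [fine_tune()]).
#' @param lr learning rate (defaults to `config$lr`).
#' @param verbose print the per-epoch loss.
#' @return list with elements `params` and `loss` (per-epoch training MSE).
#' @export
train_pairnet <- function(provider, pairs, config = pairpot_config(),
                          seed = 1, epochs = config$epochs,
                          augment = config$augment, params = NULL,
                          lr = config$lr, verbose = FALSE) {
  if (inherits(provider, "congeneric_series"))
    provider <- make_grid_provider(provider, config)
  if (nrow(pairs) < 1) stop("at least one training pair is required")
  if (epochs < 1) stop("epochs must be >= 1")
  if (is.null(params)) params <- init_params(config, seed)
  state <- adam_init(params)
  p_drop <- config$dropout
  losses <- numeric(epochs)
  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(pairs))
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1, nrow(pairs), by = config$batch_size)) {
        sel <- ord[start:min(start + config$batch_size - 1L, nrow(pairs))]
        B <- length(sel)
        if (augment) {
          Xa <- matrix(0, nrow(provider(pairs$a[sel[1]])), B)
          Xb <- Xa
          for (j in seq_len(B)) {
            rot <- random_rotation(
              derive_seed(seed, "rot", (ep - 1L) * nrow(pairs) + sel[j]))
            g <- provider(c(pairs$a[sel[j]], pairs$b[sel[j]]), rot)
            Xa[, j] <- g[, 1]; Xb[, j] <- g[, 2]
          }
        } else {
          Xa <- provider(pairs$a[sel])
          Xb <- provider(pairs$b[sel])
        }
        masks <- if (p_drop > 0) {
          L <- config$latent
          list(a = matrix(rbinom(L * B, 1, 1 - p_drop), L, B) / (1 - p_drop),
               b = matrix(rbinom(L * B, 1, 1 - p_drop), L, B) / (1 - p_drop))
        }
        gb <- pair_batch_grads(params, Xa, Xb, pairs$label[sel], config,
                               masks)
        if (!is.finite(gb$loss))
          stop("non-finite training loss at epoch ", ep,
               " (learning rate too high or degenerate input)")
        upd <- adam_step(params, gb$grads, state, config, lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + gb$loss * B
        nb <- nb + B
      }
      losses[ep] <- ep_loss / nb
      if (verbose)
        message(sprintf("epoch %3d  mse %.5f", ep, losses[ep]))
    }
  })
  list(params = params, loss = losses)
}

# Batched prediction over a pair table (evaluation mode, no rotation).
predict_pairs <- function(params, provider, pairs, config,
                          batch_size = 64L) {
  out <- numeric(nrow(pairs))
  for (start in seq(1, nrow(pairs), by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, nrow(pairs))
    out[sel] <- forward_batch(params, provider(pairs$a[sel]),
                              provider(pairs$b[sel]), config)
  }
  out
}

#' Reconstruct an absolute potency estimate from relative predictions
#'
#' Each known reference gives one estimate `pIC50(ref) + predicted
#' delta(test, ref)`; their mean is the maximum-a-posteriori absolute
#' potency and the spread across references measures its uncertainty.
#'
#' @param ref_pic50 numeric vector of reference potencies.
#' @param deltas predicted `pIC50(test) - pIC50(ref)` for the same
#'   references.
#' @param id optional ligand id carried through to the result.
#' @return list with `mu` (mean estimate), `sigma` (population standard
#'   deviation across references; 0 for a single reference),
#'   `n_references`, and the per-reference `estimates`.
#' @export
predict_absolute <- function(ref_pic50, deltas, id = NULL) {
  if (length(ref_pic50) == 0)
    stop("at least one reference with known potency is required")
  if (length(ref_pic50) != length(deltas))
    stop("ref_pic50 and deltas must have equal length")
  est <- ref_pic50 + deltas
  mu <- mean(est)
  sigma <- sqrt(mean((est - mu)^2))
  list(id = id, mu = mu, sigma = sigma, n_references = length(est),
       estimates = est)
}

#' Continue training from an existing model
#'
#' Continues optimization on the union of newly available pairs and an
#' optional background pair set for a small number of epochs (3 by
#' default), the cheap incremental update used between assay rounds.
#'
#' @param params pretrained `pairnet_params` (or a fitted [pairpot()]
#'   model, whose parameters are updated).
#' @param provider grid provider or [congeneric_series()].
#' @param new_pairs newly labelled pairs (data frame as [build_pairs()]).
#' @param background_pairs optional pair table mixed in with the new data;
#'   empty reduces to plain training on `new_pairs`.
#' @param epochs fine-tuning epochs.
#' @inheritParams train_pairnet
#' @return as [train_pairnet()].
#' @export
fine_tune <- function(params, provider, new_pairs, background_pairs = NULL,
                      config = pairpot_config(), seed = 1,
                      epochs = config$finetune_epochs,
                      augment = config$augment, lr = config$lr) {
  if (inherits(params, "pairpot")) params <- params$params
  if (is.null(params)) stop("pretrained parameters are required")
  pairs <- if (is.null(background_pairs) || nrow(background_pairs) == 0)
    new_pairs else rbind(new_pairs, background_pairs)
  train_pairnet(provider, pairs, config, seed = seed, epochs = epochs,
                augment = augment, params = params)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the weights, configuration, channel and radius
#' tables, the protein and pocket center needed for prediction, and the
#' package version.
#'
#' @param model a fitted [pairpot()] model.
#' @param path checkpoint file.
#' @return `load_checkpoint()` returns the restored `pairpot` model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pairpot"))
  obj <- list(params = model$params, config = model$config,
              series = model$series, train_ids = model$train_ids,
              loss = model$loss, seed = model$seed,
              vdw_table = pp_vdw_table(), channel_rules = pp_channel_rules(),
              version = as.character(utils::packageVersion("pairpot")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  structure(list(params = obj$params, config = obj$config,
                 series = obj$series, train_ids = obj$train_ids,
                 loss = obj$loss, seed = obj$seed),
            class = "pairpot")
}
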