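#' Fit the twin 3D-CNN relative-potency model to a congeneric series
#'
#' Voxelizes every training ligand against the shared protein pocket,
#' enumerates all unordered training pairs among the ligands with known
#' pIC50, and trains the zero-symmetric twin network on the pairwise
#' potency differences.
#'
#' @param series a [congeneric_series()].
#' @param train_ids ligand ids to train on; defaults to all ligands with a
#'   known pIC50.  At least two are required.
#' @param config a [pairpot_config()].
#' @param seed run seed controlling initialization, shuffling, dropout and
#'   rotation augmentation.
#' @param epochs,augment,lr training controls (default from `config`).
#' @param params optional warm-start weights (continues training).
#' @param verbose print per-epoch loss.
#' @return an object of class `pairpot` with components `params`, `config`,
#'   `series`, `train_ids`, `pairs`, `loss` (per-epoch training MSE) and
#'   `seed`.
#' @seealso [predict.pairpot()], [fine_tune()], [continuous_learning_run()]
#' @export
pairpot <- function(series, train_ids = NULL, config = pairpot_config(),
                    seed = 1, epochs = config$epochs,
                    augment = config$augment, lr = config$lr,
                    params = NULL, verbose = FALSE) {
  stopifnot(inherits(series, "congeneric_series"))
  pic <- series_pic50(series)
  if (is.null(train_ids)) train_ids <- series_ids(series)[!is.na(pic)]
  train_ids <- train_ids[!is.na(pic[train_ids])]
  pairs <- build_pairs(series, train_ids)
  provider <- make_grid_provider(series, config)
  fit <- train_pairnet(provider, pairs, config, seed = seed,
                       epochs = epochs, augment = augment, params = params,
                       lr = lr, verbose = verbose)
  structure(list(params = fit$params, config = config, series = series,
                 train_ids = train_ids, pairs = pairs, loss = fit$loss,
                 seed = seed, call = match.call()),
            class = "pairpot")
}

provider_of <- function(object) {
  env <- attr(object, "provider_env")
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    env$provider <- make_grid_provider(object$series, object$config)
  }
  env$provider
}

#' @export
print.pairpot <- function(x, ...) {
  cat("Twin 3D-CNN relative potency model (pairpot)\n")
  cat(sprintf("  series: %d ligands, trained on %d (%d pairs)\n",
              length(x$series$ligands), length(x$train_ids),
              nrow(x$pairs)))
  cat(sprintf("  encoder: %d/%d filters -> latent %d; head: bias-free linear\n",
              x$config$filters1, x$config$filters2, x$config$latent))
  if (length(x$loss))
    cat(sprintf("  training MSE: %.4f (epoch 1) -> %.4f (epoch %d)\n",
                x$loss[1], x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}

#' @export
summary.pairpot <- function(object, ...) {
  res <- residuals(object)
  out <- list(n_ligands = length(object$series$ligands),
              n_train = length(object$train_ids),
              n_pairs = nrow(object$pairs),
              final_mse = object$loss[length(object$loss)],
              train_rmse = sqrt(mean(res^2)),
              loss = object$loss)
  class(out) <- "summary.pairpot"
  out
}

#' @export
print.summary.pairpot <- function(x, ...) {
  cat("Twin 3D-CNN relative potency model\n")
  cat(sprintf("  %d training ligands -> %d pairs; %d epochs\n",
              x$n_train, x$n_pairs, length(x$loss)))
  cat(sprintf("  final epoch MSE %.4f; training-pair RMSE %.4f pIC50\n",
              x$final_mse, x$train_rmse))
  invisible(x)
}

#' @export
coef.pairpot <- function(object, ...) object$params$head

#' @export
fitted.pairpot <- function(object, ...) {
  predict_pairs(object$params, provider_of(object), object$pairs,
                object$config)
}

#' @export
residuals.pairpot <- function(object, ...)
  object$pairs$label - fitted(object)

#' @export
plot.pairpot <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training MSE (pIC50^2)",
                 main = "pairpot training loss", ...)
  invisible(x)
}

#' Predict relative and absolute potencies for series ligands
#'
#' For every requested ligand the model predicts the potency difference
#' against each reference; references with known pIC50 additionally yield a
#' maximum-a-posteriori absolute estimate (mean over references) with an
#' uncertainty (spread across references).
#'
#' @param object a fitted [pairpot()] model.
#' @param ligands ids to predict for; defaults to every series ligand not
#'   in the training set.
#' @param references reference ids with known pIC50; defaults to the
#'   training set.
#' @param type `"absolute"` returns one row per ligand (mu, sigma,
#'   n_references); `"delta"` returns one row per (ligand, reference) pair.
#' @param ... unused.
#' @return a data frame.
#' @export
predict.pairpot <- function(object, ligands = NULL, references = NULL,
                            type = c("absolute", "delta"), ...) {
  type <- match.arg(type)
  series <- object$series
  if (is.null(ligands))
    ligands <- setdiff(series_ids(series), object$train_ids)
  if (is.null(references)) references <- object$train_ids
  if (length(references) == 0) stop("at least one reference is required")
  pic <- series_pic50(series)
  if (any(is.na(pic[references])))
    stop("all references must have a known pIC50")
  pairs <- build_pairs(series, references, test_ids = ligands)
  deltas <- predict_pairs(object$params, provider_of(object), pairs,
                          object$config)
  if (type == "delta")
    return(data.frame(id = pairs$a, reference = pairs$b, delta = deltas,
                      stringsAsFactors = FALSE))
  rows <- lapply(ligands, function(id) {
    sel <- pairs$a == id
    est <- predict_absolute(pic[pairs$b[sel]], deltas[sel], id = id)
    data.frame(id = id, mu = est$mu, sigma = est$sigma,
               n_references = est$n_references, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
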