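#' Upper-confidence-bound acquisition score
#'
#' `UCB = mu + beta * sigma`: predicted potency plus an exploration bonus
#' proportional to the prediction uncertainty.  The study-level default for
#' the exploration factor is `beta = 1.64`.
#'
#' @param mu predicted absolute potency (pIC50).
#' @param sigma prediction standard deviation (pIC50, `>= 0`).
#' @param beta exploration factor (`0` = pure exploitation).
#' @return the acquisition score (vectorized).
#' @export
ucb_score <- function(mu, sigma, beta = 1.64) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  mu + beta * sigma
}

#' Select the next synthesis batch by UCB
#'
#' Picks the top-`batch_size` candidates by [ucb_score()]; fewer when the
#' pool is smaller.  Ties are broken by candidate order.
#'
#' @param candidates data frame with columns `id`, `mu`, `sigma`.
#' @param batch_size compounds per synthesis epoch.
#' @param beta exploration factor.
#' @return character vector of selected ids.
#' @export
select_batch <- function(candidates, batch_size, beta = 1.64) {
  if (nrow(candidates) == 0) stop("candidate pool is empty")
  score <- ucb_score(candidates$mu, candidates$sigma, beta)
  k <- min(batch_size, nrow(candidates))
  candidates$id[order(-score, seq_along(score))[seq_len(k)]]
}

#' Simulate a UCB-driven lead-optimization campaign
#'
#' Starts from a small revealed pool, then loops: update the model on all
#' pairwise differences among revealed ligands, predict an absolute
#' (mu, sigma) for every hidden candidate against all revealed references,
#' reveal the top-UCB batch, and repeat until the most potent ligand of the
#' series has been revealed.  With a single revealed reference the spread
#' across references is zero, so the first epoch is effectively greedy
#' unless several initial compounds are given.
#'
#' @param series a [congeneric_series()] with known pIC50 on every ligand
#'   (the simulator hides and reveals them).
#' @param initial_train ids revealed before the first epoch; defaults to
#'   the earliest ligands by timestamp (or series order) of size
#'   `initial_size`.
#' @param initial_size used when `initial_train` is `NULL`.
#' @param batch_size compounds revealed per synthesis epoch.
#' @param beta UCB exploration factor.
#' @param config a [pairpot_config()].
#' @param seed run seed.
#' @param predictor `"model"` uses the twin network (retrained each epoch
#'   by fine-tuning, or from scratch with `retrain = "full"`); `"oracle"`
#'   returns the true potency with zero uncertainty (perfect-information
#'   baseline); `"random"` scores candidates randomly (random-order
#'   baseline).
#' @param retrain `"finetune"` (default) continues from the previous
#'   epoch's weights for `config$finetune_epochs` epochs; `"full"` retrains
#'   from scratch for `epochs` epochs each epoch.
#' @param epochs training epochs (first epoch, and every epoch under
#'   `retrain = "full"`).
#' @param augment rotation augmentation while training.
#' @return a `campaign_report`: list with `epochs`, `total_sampled`
#'   (`epochs * batch_size`, counting the batch containing the top
#'   compound), `target_id`, `found`, `epoch_log` (per-epoch data frame:
#'   epoch, selected ids, mean revealed-pool pIC50) and the final pools.
#' @export
simulate_campaign <- function(series, initial_train = NULL,
                              initial_size = 4, batch_size = 10,
                              beta = 1.64, config = pairpot_config(),
                              seed = 1,
                              predictor = c("model", "oracle", "random"),
                              retrain = c("finetune", "full"),
                              epochs = config$epochs,
                              augment = config$augment) {
  predictor <- match.arg(predictor)
  retrain <- match.arg(retrain)
  pic <- series_pic50(series)
  if (any(is.na(pic)))
    stop("campaign simulation needs a known pIC50 for every ligand")
  ids <- series_ids(series)
  # target: the unique most potent ligand (earliest on ties)
  target <- ids[which.max(pic)]
  if (is.null(initial_train)) {
    ts <- series_timestamps(series)
    ord <- if (any(is.na(ts))) seq_along(ids) else order(ts)
    initial_train <- ids[ord][seq_len(min(initial_size, length(ids) - 1L))]
  }
  revealed <- initial_train
  hidden <- setdiff(ids, revealed)
  provider <- if (predictor == "model") make_grid_provider(series, config)
  params <- NULL
  log_rows <- list()
  epoch <- 0L
  max_epochs <- ceiling(length(hidden) / batch_size)
  found <- target %in% revealed
  while (!found) {
    epoch <- epoch + 1L
    if (epoch > max_epochs)
      stop("internal error: campaign exceeded the epoch bound")
    est <- switch(predictor,
      oracle = data.frame(id = hidden, mu = pic[hidden], sigma = 0,
                          stringsAsFactors = FALSE),
      random = with_seed(derive_seed(seed, "rand-pick", epoch),
        data.frame(id = hidden, mu = rnorm(length(hidden)), sigma = 0,
                   stringsAsFactors = FALSE)),
      model = {
        pairs <- build_pairs(series, revealed)
        ep_seed <- derive_seed(seed, "campaign", epoch)
        fit <- if (is.null(params) || retrain == "full")
          train_pairnet(provider, pairs, config, seed = ep_seed,
                        epochs = epochs, augment = augment)
        else
          fine_tune(params, provider, pairs, config = config,
                    seed = ep_seed, augment = augment)
        params <- fit$params
        test_pairs <- build_pairs(series, revealed, test_ids = hidden)
        deltas <- predict_pairs(params, provider, test_pairs, config)
        do.call(rbind, lapply(hidden, function(id) {
          sel <- test_pairs$a == id
          a <- predict_absolute(pic[test_pairs$b[sel]], deltas[sel], id)
          data.frame(id = id, mu = a$mu, sigma = a$sigma,
                     stringsAsFactors = FALSE)
        }))
      })
    batch <- select_batch(est, batch_size, beta)
    revealed <- c(revealed, batch)
    hidden <- setdiff(hidden, batch)
    found <- target %in% batch
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, n_selected = length(batch),
      selected = paste(batch, collapse = ","),
      mean_pool_pic50 = mean(pic[revealed]),
      stringsAsFactors = FALSE)
  }
  structure(list(epochs = epoch, total_sampled = epoch * batch_size,
                 batch_size = batch_size, beta = beta, target_id = target,
                 found = TRUE, initial_train = initial_train,
                 epoch_log = do.call(rbind, log_rows),
                 revealed = revealed, seed = seed, predictor = predictor),
            class = "campaign_report")
}

#' @export
print.campaign_report <- function(x, ...) {
  cat(sprintf("Lead-optimization campaign (%s predictor, beta = %g)\n",
              x$predictor, x$beta))
  cat(sprintf("  top compound %s found at synthesis epoch %d; total sampled %d\n",
              x$target_id, x$epochs, x$total_sampled))
  if (!is.null(x$epoch_log))
    cat(sprintf("  mean revealed-pool pIC50: %s\n",
                paste(sprintf("%.2f", x$epoch_log$mean_pool_pic50),
                      collapse = " -> ")))
  invisible(x)
}

#' Sampling advantage over the experimental and random orders
#'
#' How many syntheses the campaign saved relative to the historical
#' experimental order, and relative to the `n/2` expectation of random
#' selection.
#'
#' @param experimental_order position of the top compound in the historical
#'   synthesis order (`1 <= experimental_order <= n`).
#' @param total_sampled ligands sampled by the campaign before stopping.
#' @param n series size.
#' @return list with `advantage_experimental`
#'   (`experimental_order - total_sampled`) and `advantage_random`
#'   (`n/2 - total_sampled`).
#' @export
advantage_report <- function(experimental_order, total_sampled, n) {
  if (experimental_order < 1 || experimental_order > n)
    stop("experimental_order must lie in [1, n]")
  list(advantage_experimental = experimental_order - total_sampled,
       advantage_random = n / 2 - total_sampled)
}

#' Replicate a campaign over independent seeds
#'
#' @inheritParams simulate_campaign
#' @param replicates number of independent runs; each derives its own seed
#'   from `seed`.
#' @param ... passed to [simulate_campaign()].
#' @return data frame with one row per replicate (seed, epochs,
#'   total_sampled) plus a `"mean_total_sampled"` attribute.
#' @export
run_campaigns <- function(series, replicates = 10, seed = 1, ...) {
  rows <- lapply(seq_len(replicates), function(r) {
    rseed <- derive_seed(seed, "replicate", r)
    rep <- simulate_campaign(series, seed = rseed, ...)
    data.frame(replicate = r, seed = rseed, epochs = rep$epochs,
               total_sampled = rep$total_sampled)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_total_sampled") <- mean(out$total_sampled)
  out
}
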