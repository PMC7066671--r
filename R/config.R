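#' Model and pipeline configuration
#'
#' Collects every tunable of the pipeline with its default.  Grid geometry
#' and training defaults follow the published protocol (24 A box at 1 A
#' resolution, 18 channels, Adam with beta1 = 0.9, beta2 = 0.999,
#' epsilon = 1e-4, batch size 32, 50 epochs, 3 fine-tuning epochs,
#' 192-dimensional latent); encoder filter counts, dropout rate and the
#' learning rate are open choices exposed here.
#'
#' @param box_edge physical edge of the cubic pocket box in Angstrom.
#' @param resolution voxel edge in Angstrom (grid is `box_edge/resolution`
#'   voxels per axis).
#' @param cutoff atoms farther than this from a voxel center contribute
#'   nothing (Angstrom); occupancies dropped this way are below 2.5e-6.
#' @param filters1,filters2 filter counts of the first and second
#'   convolution; `latent` channels of the third convolution and hence the
#'   latent dimension after global max pooling.
#' @param latent latent dimension (length of the bias-free head).
#' @param dropout dropout rate applied to each leg's latent during training.
#' @param lr Adam learning rate.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and epsilon.
#' @param batch_size minibatch size (pairs).
#' @param epochs full-training epochs.
#' @param finetune_epochs epochs used by [fine_tune()] and per-epoch model
#'   updates inside campaigns.
#' @param augment logical; re-voxelize each pair under a fresh random
#'   rotation every epoch during training.
#' @param ucb_beta exploration factor of the upper-confidence-bound
#'   acquisition score.
#' @param campaign_batch compounds revealed per synthesis epoch.
#' @param max_series guard on series size accepted by the command line.
#' @param affinity_tag,affinity_unit SD-tag name holding the affinity and
#'   its unit (see [convert_affinity()] for supported units).
#' @param timestamp_tag,crystal_tag optional SD-tag names for the assay
#'   timestamp and the crystal-reference flag.
#' @param include_hetero,include_waters include non-water HETATM records /
#'   water molecules when reading proteins.
#' @param test_against `"all"` scores every (test, train) pair; `"reference"`
#'   scores test ligands only against the series reference.
#' @return an object of class `pairpot_config` (a named list).
#' @export
pairpot_config <- function(box_edge = 24, resolution = 1, cutoff = 5,
                           filters1 = 32, filters2 = 64, latent = 192,
                           dropout = 0.5, lr = 1e-4,
                           adam_beta1 = 0.9, adam_beta2 = 0.999,
                           adam_eps = 1e-4, batch_size = 32, epochs = 50,
                           finetune_epochs = 3, augment = TRUE,
                           ucb_beta = 1.64, campaign_batch = 10,
                           max_series = 1000,
                           affinity_tag = "pIC50",
                           affinity_unit = "pIC50",
                           timestamp_tag = "timestamp",
                           crystal_tag = "crystal_reference",
                           include_hetero = FALSE, include_waters = FALSE,
                           test_against = c("all", "reference")) {
  grid_dim <- box_edge / resolution
  if (grid_dim != round(grid_dim))
    stop("box_edge must be an integer multiple of resolution")
  if (grid_dim %% 2 != 0)
    stop("grid dimension must be even (a 2x max pool follows the convolutions)")
  cfg <- list(box_edge = box_edge, resolution = resolution,
              grid_dim = as.integer(grid_dim), cutoff = cutoff,
              filters1 = as.integer(filters1),
              filters2 = as.integer(filters2), latent = as.integer(latent),
              dropout = dropout, lr = lr,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              adam_eps = adam_eps, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              finetune_epochs = as.integer(finetune_epochs),
              augment = isTRUE(augment), ucb_beta = ucb_beta,
              campaign_batch = as.integer(campaign_batch),
              max_series = as.integer(max_series),
              affinity_tag = affinity_tag, affinity_unit = affinity_unit,
              timestamp_tag = timestamp_tag, crystal_tag = crystal_tag,
              include_hetero = isTRUE(include_hetero),
              include_waters = isTRUE(include_waters),
              test_against = match.arg(test_against))
  class(cfg) <- "pairpot_config"
  cfg
}

#' @export
print.pairpot_config <- function(x, ...) {
  cat("pairpot configuration\n")
  cat(sprintf("  grid: %d A box, %g A voxels -> %d^3, 18 channels\n",
              x$box_edge, x$resolution, x$grid_dim))
  cat(sprintf("  encoder: conv %d -> conv %d -> pool2 -> conv %d -> latent %d\n",
              x$filters1, x$filters2, x$latent, x$latent))
  cat(sprintf("  training: Adam(lr=%g, b1=%g, b2=%g, eps=%g), batch %d, %d epochs, dropout %g\n",
              x$lr, x$adam_beta1, x$adam_beta2, x$adam_eps, x$batch_size,
              x$epochs, x$dropout))
  cat(sprintf("  fine-tune epochs: %d; UCB beta: %g; campaign batch: %d\n",
              x$finetune_epochs, x$ucb_beta, x$campaign_batch))
  invisible(x)
}

#' Read / write a key = value configuration file
#'
#' Plain-text configuration with one `key = value` per line; `#` starts a
#' comment.  Unknown keys are rejected.  Values are coerced to the type of
#' the corresponding [pairpot_config()] default.
#'
#' @param path file path.
#' @param config a `pairpot_config` object.
#' @return `read_config()` returns a `pairpot_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- pairpot_config()
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults) || key == "grid_dim")
      stop("unknown config key: '", key, "'")
    proto <- defaults[[key]]
    overrides[[key]] <- if (is.logical(proto)) as.logical(val)
      else if (is.numeric(proto)) as.numeric(val) else val
  }
  do.call(pairpot_config, overrides)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pairpot_config"))
  keys <- setdiff(names(config), "grid_dim")
  writeLines(sprintf("%s = %s", keys,
                     vapply(config[keys], as.character, "")), path)
  invisible(path)
}

# One run seed drives every stochastic choice.  Each consumer derives its
# own 31-bit stream seed from (seed, stream label, counter) with a small
# multiplicative hash; exact doubles up to 2^53 keep this portable.
derive_seed <- function(seed, stream, counter = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  s <- (as.numeric(seed) %% 2147483647) * 48271 + h * 69621 + counter * 16807
  as.integer(s %% 2147483647L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
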