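# The twin network: latent encoding, antisymmetry, gradients, training,
# absolute-affinity reconstruction.

random_grid_pair <- function(seed, cfg) {
  set.seed(seed)
  n <- 18 * cfg$grid_dim^3
  list(a = matrix(runif(n), ncol = 1), b = matrix(runif(n), ncol = 1))
}

test_that("one leg flattens into the documented latent size", {
  cfg <- pairpot_config()        # default: 192-dimensional latent
  ser <- cached_series(8)
  g <- voxelize(ser, ser$ligands[[1]])
  p <- init_params(cfg, seed = 1)
  lat <- encode_grid(p, g, cfg)
  expect_length(lat, 192)
  expect_identical(lat, encode_grid(p, g, cfg))  # eval mode determinism
  zero <- array(0, c(18, 24, 24, 24))
  expect_true(all(is.finite(encode_grid(p, zero, cfg))))
})

test_that("pair predictions are exactly zero-symmetric", {
  cfg <- tiny_config()
  for (seed in 1:5) {
    p <- init_params(cfg, seed)
    gp <- random_grid_pair(seed, cfg)
    f_ab <- pairpot:::forward_batch(p, gp$a, gp$b, cfg)
    f_ba <- pairpot:::forward_batch(p, gp$b, gp$a, cfg)
    expect_lt(abs(f_ab + f_ba), 1e-6)
    expect_lt(abs(pairpot:::forward_batch(p, gp$a, gp$a, cfg)), 1e-6)
  }
  # all-zero head weights predict zero for every pair
  p0 <- init_params(cfg, 1)
  p0$head[] <- 0
  gp <- random_grid_pair(99, cfg)
  expect_identical(pairpot:::forward_batch(p0, gp$a, gp$b, cfg), 0)
})

test_that("pair enumeration gives n(n-1)/2 training and n*m test pairs", {
  ser <- cached_series(8)
  ids <- names(ser$ligands)
  tr <- build_pairs(ser, ids[1:4])
  expect_equal(nrow(tr), 6)
  te <- build_pairs(ser, ids[1:3], test_ids = ids[4:5])
  expect_equal(nrow(te), 6)
  # canonical label orientation: pIC50(a) - pIC50(b)
  prot <- make_toy_pocket(1)
  l1 <- chain_ligand("a", c("C", "O"), pic50 = 6)
  l2 <- chain_ligand("b", c("C", "N"), pic50 = 8)
  s2 <- congeneric_series(prot, list(l1, l2))
  expect_equal(build_pairs(s2, c("a", "b"))$label, -2)
  expect_error(build_pairs(s2, "a"), "at least 2")
})

test_that("backpropagated gradients agree with finite differences", {
  cfg <- pairpot_config(filters1 = 2, filters2 = 2, latent = 4, dropout = 0)
  p <- init_params(cfg, 2)
  gp <- random_grid_pair(11, cfg)
  y <- 0.7
  gb <- pairpot:::pair_batch_grads(p, gp$a, gp$b, y, cfg, NULL)
  eps <- 1e-5
  loss_at <- function(params)
    (pairpot:::forward_batch(params, gp$a, gp$b, cfg) - y)^2
  # directional derivative along a random direction per parameter block
  set.seed(1)
  for (nm in c("head", "W3", "W2", "W1", "b1", "b2", "b3")) {
    v <- rnorm(length(p[[nm]]))
    dim(v) <- dim(p[[nm]])
    v <- v / sqrt(sum(v^2))
    p1 <- p; p1[[nm]] <- p1[[nm]] + eps * v
    p2 <- p; p2[[nm]] <- p2[[nm]] - eps * v
    num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    ana <- sum(gb$grads[[nm]] * v)
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-4)
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  cfg <- tiny_config()
  ser <- cached_series(12, seed = 21)
  pairs <- build_pairs(ser, names(ser$ligands)[1:5])  # 10 pairs
  fit1 <- train_pairnet(ser, pairs, cfg, seed = 3, epochs = 10)
  expect_lt(fit1$loss[10], fit1$loss[1])
  fit2 <- train_pairnet(ser, pairs, cfg, seed = 3, epochs = 10)
  expect_identical(fit1$params, fit2$params)
  fit3 <- train_pairnet(ser, pairs, cfg, seed = 4, epochs = 2)
  expect_false(identical(fit2$params$head, fit3$params$head))
})

test_that("the network can overfit a small pair set", {
  cfg <- tiny_config(dropout = 0)
  ser <- cached_series(12, seed = 21)
  pairs <- build_pairs(ser, names(ser$ligands)[1:5])
  fit <- train_pairnet(ser, pairs, cfg, seed = 1, epochs = 60,
                       augment = FALSE)
  expect_lt(min(fit$loss), 0.01)
})

test_that("rotation augmentation trains and stays antisymmetric", {
  cfg <- tiny_config(augment = TRUE)
  ser <- cached_series(8)
  pairs <- build_pairs(ser, names(ser$ligands)[1:4])
  fit <- train_pairnet(ser, pairs, cfg, seed = 5, epochs = 2,
                       augment = TRUE)
  expect_length(fit$loss, 2)
  gp <- random_grid_pair(3, cfg)
  f_ab <- pairpot:::forward_batch(fit$params, gp$a, gp$b, cfg)
  f_ba <- pairpot:::forward_batch(fit$params, gp$b, gp$a, cfg)
  expect_lt(abs(f_ab + f_ba), 1e-6)
})

test_that("fine-tuning defaults to 3 epochs and accepts a background set", {
  cfg <- tiny_config()
  ser <- cached_series(12, seed = 21)
  ids <- names(ser$ligands)
  base <- train_pairnet(ser, build_pairs(ser, ids[1:4]), cfg, seed = 1,
                        epochs = 4)
  new_pairs <- build_pairs(ser, ids[5:8])
  ft <- fine_tune(base$params, ser, new_pairs, config = cfg, seed = 2)
  expect_length(ft$loss, 3)                    # default epoch count
  bg <- build_pairs(ser, ids[1:4])
  ft2 <- fine_tune(base$params, ser, new_pairs, background_pairs = bg,
                   config = cfg, seed = 2)
  expect_length(ft2$loss, 3)
  # empty background reduces to plain training on the new pairs
  ft3 <- fine_tune(base$params, ser, new_pairs,
                   background_pairs = new_pairs[0, ], config = cfg,
                   seed = 2)
  expect_equal(ft3$loss, ft$loss)
})

test_that("absolute estimates are reference-wise reconstructions", {
  one <- predict_absolute(7, 1)
  expect_equal(one$mu, 8)
  expect_equal(one$sigma, 0)
  expect_equal(one$n_references, 1)
  two <- predict_absolute(c(6, 8), c(2, 0))
  expect_equal(two$mu, 8)
  expect_equal(two$sigma, 0)
  spread <- predict_absolute(c(6, 8), c(1, 1))   # estimates 7 and 9
  expect_equal(spread$mu, 8)
  expect_equal(spread$sigma, 1)
  expect_error(predict_absolute(numeric(), numeric()), "reference")
  # with perfect deltas the truth is recovered for any reference set
  set.seed(8)
  truth <- 7.3
  refs <- runif(6, 4, 9)
  est <- predict_absolute(refs, truth - refs)
  expect_equal(est$mu, truth)
  expect_equal(est$sigma, 0, tolerance = 1e-12)
})

test_that("the fitted model ranks held-out potency differences", {
  # series of 40 at noise 0.3; train on 20, score Spearman rho on the
  # held-out deltas; expect rho >= 0.5 in at least 8 of 10 seeds
  cfg <- tiny_config()
  ser <- cached_series(40, noise_sigma = 0.3, seed = 11)
  ids <- names(ser$ligands)
  wins <- 0L
  for (seed in 1:10) {
    sp <- split_series(ser, "random", n = 20, seed = seed)
    fit <- train_pairnet(ser, build_pairs(ser, sp$train), cfg,
                         seed = seed, epochs = 6)
    te <- build_pairs(ser, sp$train, test_ids = sp$test)
    pred <- pairpot:::predict_pairs(fit$params,
                                    pairpot:::make_grid_provider(ser, cfg),
                                    te, cfg)
    rho <- evaluate_step(pred, te$label)$spearman
    if (!is.na(rho) && rho >= 0.5) wins <- wins + 1L
  }
  expect_gte(wins, 8)
})

test_that("checkpoints restore a model that predicts identically", {
  cfg <- tiny_config()
  ser <- cached_series(8)
  model <- pairpot(ser, train_ids = names(ser$ligands)[1:5], config = cfg,
                   seed = 2, epochs = 3)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  p1 <- predict(model, type = "absolute")
  p2 <- predict(back, type = "absolute")
  expect_equal(p1, p2)
})

test_that("the pairpot object supports the standard model verbs", {
  cfg <- tiny_config()
  ser <- cached_series(8)
  model <- pairpot(ser, train_ids = names(ser$ligands)[1:5], config = cfg,
                   seed = 2, epochs = 3)
  expect_s3_class(model, "pairpot")
  expect_output(print(model), "relative potency")
  expect_length(coef(model), cfg$latent)
  expect_length(fitted(model), nrow(model$pairs))
  expect_length(residuals(model), nrow(model$pairs))
  s <- summary(model)
  expect_output(print(s), "RMSE")
  pr <- predict(model)
  expect_equal(nrow(pr), 3)        # the three held-out ligands
  expect_true(all(pr$n_references == 5))
  expect_true(all(pr$sigma >= 0))
  de <- predict(model, type = "delta")
  expect_equal(nrow(de), 15)       # 3 test x 5 references
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(model))
})
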