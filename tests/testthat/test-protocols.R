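# Affinity conversion, reference selection, deduplication, splits and
# metrics.

test_that("affinity conversion follows -log10(IC50 [M])", {
  expect_equal(convert_affinity(1e-6, "IC50_M"), 6)
  expect_equal(convert_affinity(1e-8, "IC50_M"), 8)
  expect_equal(convert_affinity(1, "IC50_uM"), 6)
  expect_equal(convert_affinity(10, "IC50_nM"), 8)
  expect_equal(convert_affinity(5.5, "pIC50"), 5.5)
  # dG path: ln(10) * R * T = 1.3642 kcal/mol at 298.15 K
  RT <- 1.9872e-3 * 298.15
  expect_equal(convert_affinity(-log(10) * RT, "dG_kcal_per_mol"), 1)
  expect_equal(convert_affinity(-1.3637, "dG_kcal_per_mol"), 1,
               tolerance = 1e-3)
  expect_error(convert_affinity(-1, "IC50_M"), "positive")
  expect_error(convert_affinity(1, "banana"), "unsupported")
  # strictly monotone decreasing and invertible
  ic50 <- 10^runif(50, -9, -3)
  p <- convert_affinity(ic50, "IC50_M")
  expect_true(all(diff(p[order(ic50)]) < 0))
  expect_equal(10^(-p), ic50)
})

test_that("MCS sizes and distances behave on hand-checked molecules", {
  cco <- chain_ligand("cco", c("C", "C", "O"))
  ccn <- chain_ligand("ccn", c("C", "C", "N"))
  ccc <- chain_ligand("ccc", c("C", "C", "C"))
  # shared substructure of any two of {CCO, CCN, CCC} is the CC unit
  expect_equal(mcs_size(cco, ccn), 2)
  expect_equal(mcs_size(cco, ccc), 2)
  expect_equal(mcs_size(ccn, ccc), 2)
  expect_equal(mcs_size(cco, cco), 3)
  expect_equal(mcs_distance(cco, cco), 0)
  expect_equal(mcs_distance(cco, ccn), 1 - 2 / 3)
  # symmetric
  expect_equal(mcs_distance(cco, ccn), mcs_distance(ccn, cco))
})

test_that("reference selection prefers the crystal ligand, then MCS", {
  prot <- make_toy_pocket(1)
  cco <- chain_ligand("cco", c("C", "C", "O"))
  ccn <- chain_ligand("ccn", c("C", "C", "N"))
  ccc <- chain_ligand("ccc", c("C", "C", "C"))
  cry <- chain_ligand("cry", c("C", "C", "F"), crystal = TRUE)
  with_cry <- congeneric_series(prot, list(cco, ccn, cry))
  expect_equal(select_reference(with_cry)$id, "cry")
  # all pairwise mean MCS distances equal -> first ligand by tie break
  no_cry <- congeneric_series(prot, list(cco, ccn, ccc))
  expect_equal(select_reference(no_cry)$id, "cco")
  same <- congeneric_series(prot, list(
    chain_ligand("x1", c("C", "O")), chain_ligand("x2", c("C", "O")),
    chain_ligand("x3", c("C", "O"))))
  expect_equal(select_reference(same)$id, "x1")
})

test_that("deduplication drops graph-identical ligands, keeping the first", {
  prot <- make_toy_pocket(1)
  ethanol_a <- chain_ligand("eth_a", c("C", "C", "O"), pic50 = 6)
  ethanol_b <- chain_ligand("eth_b", c("C", "C", "O"), pic50 = 6.4)
  amine <- chain_ligand("amine", c("C", "C", "N"), pic50 = 7)
  acid <- chain_ligand("acid", c("C", "O", "O"), pic50 = 5)
  s1 <- congeneric_series(prot, list(ethanol_a, amine))
  s2 <- congeneric_series(prot, list(ethanol_b, acid))
  out <- dedup_ligands(list(s1, s2))
  expect_equal(series_ids(out[[1]]), c("eth_a", "amine"))
  expect_equal(series_ids(out[[2]]), "acid")       # eth_b dropped
  # disjoint ligand sets pass through unchanged
  out2 <- dedup_ligands(list(s1))
  expect_equal(series_ids(out2[[1]]), c("eth_a", "amine"))
  # 3 copies of one ligand plus 2 uniques -> 3 ligands remain
  s3 <- congeneric_series(prot, list(
    chain_ligand("c1", c("C", "C", "O")),
    chain_ligand("c2", c("C", "C", "O")),
    chain_ligand("c3", c("C", "C", "O")),
    chain_ligand("u1", c("C", "N")),
    chain_ligand("u2", c("C", "F"))))
  out3 <- dedup_ligands(list(s3))
  expect_equal(length(out3[[1]]$ligands), 3)
  expect_equal(series_ids(out3[[1]]), c("c1", "u1", "u2"))
})

test_that("circular fingerprints are deterministic and discriminative", {
  a1 <- chain_ligand("a1", c("C", "C", "O"))
  a2 <- chain_ligand("a2", c("C", "C", "O"))
  b <- chain_ligand("b", c("C", "N", "O"))
  expect_identical(ecfp_fingerprint(a1), ecfp_fingerprint(a2))
  expect_equal(tanimoto(ecfp_fingerprint(a1), ecfp_fingerprint(a2)), 1)
  expect_lt(tanimoto(ecfp_fingerprint(a1), ecfp_fingerprint(b)), 1)
  expect_true(all(ecfp_fingerprint(a1) >= 0 &
                    ecfp_fingerprint(a1) < 2048))
})

test_that("splits partition the series under every scheme", {
  ser <- cached_series(15, seed = 2)
  ids <- names(ser$ligands)
  for (scheme in c("random", "temporal", "similarity")) {
    for (n in c(1, 7, 14)) {
      sp <- split_series(ser, scheme, n, seed = 3)
      expect_length(sp$train, n)
      expect_setequal(c(sp$train, sp$test), ids)
      expect_length(intersect(sp$train, sp$test), 0)
    }
  }
  expect_error(split_series(ser, "random", 15), "series size")
  expect_error(split_series(ser, "random", 0), "series size")
})

test_that("the temporal split trains on the earliest ligands", {
  ser <- cached_series(15, seed = 2)
  sp <- split_series(ser, "temporal", 5)
  ts <- vapply(ser$ligands, function(l) l$timestamp, 0)
  expect_setequal(sp$train, names(sort(ts)[1:5]))
  # missing timestamps are an error
  ser2 <- ser
  ser2$ligands[[3]]$timestamp <- NA_real_
  expect_error(split_series(ser2, "temporal", 5), "timestamp")
})

test_that("the random split is seed-stable and seed-sensitive", {
  ser <- cached_series(15, seed = 2)
  s1 <- split_series(ser, "random", 7, seed = 5)
  s2 <- split_series(ser, "random", 7, seed = 5)
  expect_identical(s1, s2)
  s3 <- split_series(ser, "random", 7, seed = 6)
  expect_false(setequal(s1$train, s3$train))
})

test_that("the similarity split grows greedily from the reference", {
  ser <- cached_series(15, seed = 2)
  sp1 <- split_series(ser, "similarity", 6)
  sp2 <- split_series(ser, "similarity", 6, seed = 99)  # seed-independent
  expect_identical(sp1, sp2)
  expect_equal(sp1$train[1], select_reference(ser)$id)
  # each added ligand was at least as similar to the train set as any
  # remaining one at its step
  fps <- lapply(ser$ligands, ecfp_fingerprint)
  best_sim <- function(id, train)
    max(vapply(train, function(t) tanimoto(fps[[id]], fps[[t]]), 0))
  for (k in 2:6) {
    train_so_far <- sp1$train[1:(k - 1)]
    added <- sp1$train[k]
    others <- setdiff(names(ser$ligands), c(train_so_far, added))
    expect_true(all(best_sim(added, train_so_far) >=
                      vapply(others, best_sim, 0,
                             train = train_so_far) - 1e-12))
  }
})

test_that("step metrics match an independent implementation", {
  # worked examples
  m <- evaluate_step(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0)
  expect_equal(m$pearson, 1)
  expect_equal(m$spearman, 1)
  m2 <- evaluate_step(-c(1, 2, 4), c(1, 2, 4))
  expect_equal(m2$pearson, -1)
  m3 <- evaluate_step(c(1, 2, 4) + 0.5, c(1, 2, 4))
  expect_equal(m3$rmse, 0.5)
  expect_equal(m3$pearson, 1)
  # constant input is flagged, not zeroed
  mc <- evaluate_step(c(1, 1, 1), c(1, 2, 3))
  expect_true(mc$constant_input)
  expect_true(is.na(mc$pearson) && is.na(mc$spearman))
  # brute-force reference: explicit formulas including rank transform
  ref_metrics <- function(p, e) {
    rmse <- sqrt(sum((p - e)^2) / length(p))
    r <- function(x, y) {
      xm <- x - mean(x); ym <- y - mean(y)
      sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
    }
    list(rmse = rmse, pearson = r(p, e), spearman = r(rank(p), rank(e)))
  }
  for (i in 1:100) {
    set.seed(i)
    p <- rnorm(sample(3:30, 1))
    e <- rnorm(length(p))
    got <- evaluate_step(p, e)
    want <- ref_metrics(p, e)
    expect_equal(got$rmse, want$rmse, tolerance = 1e-10)
    expect_equal(got$pearson, want$pearson, tolerance = 1e-10)
    expect_equal(got$spearman, want$spearman, tolerance = 1e-10)
  }
  expect_error(evaluate_step(1:3, 1:4), "equal length")
})

test_that("continuous learning produces a well-formed trajectory", {
  cfg <- tiny_config()
  ser <- cached_series(12, seed = 21)
  tr <- continuous_learning_run(ser, "random", schedule = c(2, 6),
                                config = cfg, seeds = 1:2, epochs = 3)
  expect_s3_class(tr, "metric_trajectory")
  expect_equal(nrow(tr), 4)
  expect_equal(tr$n_train, c(2, 6, 2, 6))
  expect_equal(tr$n_test, c(10, 6, 10, 6))
  expect_true(all(tr$rmse >= 0))
  ok <- !is.na(tr$spearman)
  expect_true(all(abs(tr$spearman[ok]) <= 1))
  # deterministic given (series, scheme, seeds)
  tr2 <- continuous_learning_run(ser, "random", schedule = c(2, 6),
                                 config = cfg, seeds = 1:2, epochs = 3)
  expect_equal(tr, tr2)
  # oversized schedule steps are dropped with a warning
  expect_warning(
    tr3 <- continuous_learning_run(ser, "random", schedule = c(2, 50),
                                   config = cfg, seeds = 1, epochs = 2),
    "series size")
  expect_equal(tr3$n_train, 2)
  agg <- aggregate_trajectory(tr)
  expect_equal(agg$n_train, c(2, 6))
  expect_true(all(c("spearman_mean", "rmse_sd") %in% names(agg)))
})
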