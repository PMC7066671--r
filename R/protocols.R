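#' Convert an affinity value to pIC50
#'
#' `pIC50 = -log10(IC50 [M])`.  Free energies are mapped through
#' `pIC50 = -dG / (ln(10) * R * T)` at T = 298.15 K with
#' R = 1.9872e-3 kcal mol^-1 K^-1, which treats the IC50 as a dissociation
#' constant (non-competitive binding assumption).  Strictly monotone
#' decreasing in IC50 and invertible.
#'
#' @param value numeric affinity value(s).
#' @param unit one of `"pIC50"`, `"IC50_M"` (alias `"IC50_molar"`),
#'   `"IC50_mM"`, `"IC50_uM"`, `"IC50_nM"`, `"dG_kcal_per_mol"`.
#' @return pIC50 value(s).
#' @export
convert_affinity <- function(value, unit = "pIC50") {
  scale <- c(IC50_M = 1, IC50_molar = 1, IC50_mM = 1e-3, IC50_uM = 1e-6,
             IC50_nM = 1e-9)
  if (unit == "pIC50") return(as.numeric(value))
  if (unit %in% names(scale)) {
    m <- value * scale[[unit]]
    if (any(!is.na(m) & m <= 0)) stop("IC50 values must be positive")
    return(-log10(m))
  }
  if (unit == "dG_kcal_per_mol") {
    RT <- 1.9872e-3 * 298.15
    return(-value / (log(10) * RT))
  }
  stop("unsupported affinity unit: '", unit, "'")
}

# Molecular graph over heavy atoms, element as vertex attribute.
mol_graph <- function(ligand) {
  heavy <- which(ligand$elements != "H")
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  igraph::V(g)$element <- ligand$elements[heavy]
  if (!is.null(ligand$bonds) && nrow(ligand$bonds)) {
    map <- match(seq_along(ligand$elements), heavy)
    b <- ligand$bonds
    keep <- !is.na(map[b$a1]) & !is.na(map[b$a2])
    if (any(keep))
      g <- igraph::add_edges(g, rbind(map[b$a1[keep]], map[b$a2[keep]]))
  }
  g
}

#' Maximum common substructure size of two ligands
#'
#' Heavy-atom MCS computed as the maximum clique of the modular product of
#' the two element-labelled molecular graphs (vertices pair atoms of equal
#' element; edges connect compatible pairs that agree on bonding).  Exact,
#' and intended for the small molecules of a congeneric series.
#'
#' @param a,b [ligand_pose()] objects.
#' @return number of heavy atoms in the largest common substructure.
#' @export
mcs_size <- function(a, b) {
  ga <- mol_graph(a); gb <- mol_graph(b)
  na <- igraph::vcount(ga); nb <- igraph::vcount(gb)
  if (na == 0 || nb == 0) return(0L)
  ea <- igraph::V(ga)$element; eb <- igraph::V(gb)$element
  pairs <- which(outer(ea, eb, `==`), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(0L)
  aa <- as.matrix(igraph::as_adjacency_matrix(ga)) > 0
  ab <- as.matrix(igraph::as_adjacency_matrix(gb)) > 0
  np <- nrow(pairs)
  gp <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (np > 1) {
    cmb <- utils::combn(np, 2)
    i1 <- pairs[cmb[1, ], 1]; j1 <- pairs[cmb[1, ], 2]
    i2 <- pairs[cmb[2, ], 1]; j2 <- pairs[cmb[2, ], 2]
    ok <- i1 != i2 & j1 != j2 &
      (aa[cbind(i1, i2)] == ab[cbind(j1, j2)])
    if (any(ok))
      gp <- igraph::add_edges(gp, rbind(cmb[1, ok], cmb[2, ok]))
  }
  as.integer(igraph::clique_num(gp))
}

#' @rdname mcs_size
#' @return `mcs_distance()` returns
#'   `1 - |MCS| / max(heavy_atoms(a), heavy_atoms(b))`, bounded in `[0, 1]`
#'   and symmetric.
#' @export
mcs_distance <- function(a, b)
  1 - mcs_size(a, b) / max(n_heavy(a), n_heavy(b))

# TRUE when the common substructure covers all heavy atoms of both
# molecules, i.e. the element-labelled graphs are isomorphic.
ligands_identical <- function(a, b) {
  ga <- mol_graph(a); gb <- mol_graph(b)
  if (igraph::vcount(ga) != igraph::vcount(gb) ||
      igraph::ecount(ga) != igraph::ecount(gb)) return(FALSE)
  if (!identical(sort(igraph::V(ga)$element),
                 sort(igraph::V(gb)$element))) return(FALSE)
  lv <- sort(unique(c(igraph::V(ga)$element, igraph::V(gb)$element)))
  igraph::is_isomorphic_to(
    ga, gb, method = "vf2",
    vertex.color1 = match(igraph::V(ga)$element, lv),
    vertex.color2 = match(igraph::V(gb)$element, lv))
}

#' Select the reference ligand of a series
#'
#' The crystal-structure ligand when one is flagged; otherwise the ligand
#' with the lowest average MCS distance to the rest of the series.  Ties
#' are broken by series order.
#'
#' @param series a [congeneric_series()].
#' @return the reference [ligand_pose()].
#' @export
select_reference <- function(series) {
  ligs <- series$ligands
  if (length(ligs) == 0) stop("series is empty")
  cry <- Find(function(l) l$is_crystal_reference, ligs)
  if (!is.null(cry)) return(cry)
  if (length(ligs) == 1) return(ligs[[1]])
  n <- length(ligs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- mcs_distance(ligs[[i]], ligs[[j]])
  avg <- rowSums(d) / (n - 1)
  ligs[[which.min(avg)]]          # which.min keeps the first on ties
}

#' Remove duplicated ligands across series of one target cluster
#'
#' Within a caller-defined group of series (e.g. one protein cluster), a
#' ligand whose common substructure with an already-kept ligand covers all
#' heavy atoms of both molecules is dropped; the first occurrence (series
#' order, then ligand order) is kept.
#'
#' @param series_group list of [congeneric_series()] objects.
#' @return the list with duplicated ligands removed (series keep their
#'   protein and pocket center; a series can end up empty).
#' @export
dedup_ligands <- function(series_group) {
  kept <- list()
  lapply(series_group, function(ser) {
    keep_ids <- character()
    for (id in series_ids(ser)) {
      lig <- ser$ligands[[id]]
      dup <- any(vapply(kept, function(k) ligands_identical(k, lig), TRUE))
      if (!dup) {
        kept[[length(kept) + 1L]] <<- lig
        keep_ids <- c(keep_ids, id)
      }
    }
    ser$ligands <- ser$ligands[keep_ids]
    ser
  })
}

# -- circular fingerprint ---------------------------------------------------

# Deterministic 31-bit mixing of an integer vector (exact in doubles).
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

#' Circular (ECFP4-style) fingerprint of a ligand
#'
#' Morgan-style extended-connectivity fingerprint over the heavy-atom
#' graph: atom invariants (element, heavy degree, attached hydrogens) are
#' iteratively combined with sorted neighbour (bond order, invariant)
#' pairs up to the given radius, and all invariants are folded into a fixed
#' bit vector.  Hashing is package-deterministic: fingerprints are
#' comparable with each other (as used by the chemical-similarity split)
#' but not bit-compatible with other toolkits.
#'
#' @param ligand a [ligand_pose()] (bonds required).
#' @param radius neighbourhood radius (2 corresponds to ECFP4).
#' @param nbits folded fingerprint length.
#' @return sorted integer vector of set bit positions (in `0:(nbits-1)`).
#' @export
ecfp_fingerprint <- function(ligand, radius = 2, nbits = 2048) {
  heavy <- which(ligand$elements != "H")
  n <- length(heavy)
  if (n == 0) return(integer())
  map <- match(seq_along(ligand$elements), heavy)
  nb <- vector("list", n)
  bo <- vector("list", n)
  nH <- integer(n)
  if (!is.null(ligand$bonds) && nrow(ligand$bonds)) {
    for (k in seq_len(nrow(ligand$bonds))) {
      i <- ligand$bonds$a1[k]; j <- ligand$bonds$a2[k]
      o <- ligand$bonds$order[k]
      hi <- map[i]; hj <- map[j]
      if (!is.na(hi) && !is.na(hj)) {
        nb[[hi]] <- c(nb[[hi]], hj); bo[[hi]] <- c(bo[[hi]], o)
        nb[[hj]] <- c(nb[[hj]], hi); bo[[hj]] <- c(bo[[hj]], o)
      } else if (!is.na(hi)) nH[hi] <- nH[hi] + 1L
      else if (!is.na(hj)) nH[hj] <- nH[hj] + 1L
    }
  }
  inv <- vapply(seq_len(n), function(i)
    hash_ints(c(match(ligand$elements[heavy[i]], PP_ELEMENTS),
                length(nb[[i]]), nH[i])), 0)
  bits <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      if (!length(nb[[i]])) return(hash_ints(c(r, inv[i])))
      nbr <- cbind(bo[[i]], inv[nb[[i]]])
      nbr <- nbr[order(nbr[, 1], nbr[, 2]), , drop = FALSE]
      hash_ints(c(r, inv[i], t(nbr)))
    }, 0)
    bits <- c(bits, inv)
  }
  sort(unique(as.integer(bits %% nbits)))
}

#' Tanimoto similarity of two bit-set fingerprints
#'
#' @param fp_a,fp_b integer vectors of set bit positions, as returned by
#'   [ecfp_fingerprint()].
#' @return `|intersection| / |union|` (1 when both are empty).
#' @export
tanimoto <- function(fp_a, fp_b) {
  u <- length(union(fp_a, fp_b))
  if (u == 0) return(1)
  length(intersect(fp_a, fp_b)) / u
}

#' Split a series into train and test ligands
#'
#' Three schemes: `"random"` (seeded shuffle, first `n` train), `"temporal"`
#' (the `n` earliest by assay timestamp train, the rest test) and
#' `"similarity"` (greedy growth from the series reference: repeatedly add
#' the untested ligand with the highest fingerprint Tanimoto similarity to
#' any train-set member until `n` are selected; ties broken by series
#' order).  Train and test always partition the series.
#'
#' @param series a [congeneric_series()].
#' @param scheme `"random"`, `"temporal"` or `"similarity"`.
#' @param n number of training ligands, `1 <= n < series size`.
#' @param seed seed for the random scheme.
#' @return list with character vectors `train` and `test`.
#' @export
split_series <- function(series, scheme = c("random", "temporal",
                                            "similarity"),
                         n, seed = 1) {
  scheme <- match.arg(scheme)
  ids <- series_ids(series)
  if (n < 1 || n >= length(ids))
    stop("n must satisfy 1 <= n < series size")
  train <- switch(scheme,
    random = with_seed(derive_seed(seed, "split"), sample(ids))[seq_len(n)],
    temporal = {
      ts <- series_timestamps(series)
      if (any(is.na(ts)))
        stop("temporal split requires timestamps on every ligand")
      ids[order(ts)][seq_len(n)]
    },
    similarity = {
      fps <- lapply(series$ligands, ecfp_fingerprint)
      train <- select_reference(series)$id
      while (length(train) < n) {
        pool <- setdiff(ids, train)
        sims <- vapply(pool, function(id)
          max(vapply(train, function(t) tanimoto(fps[[id]], fps[[t]]), 0)),
          0)
        best <- pool[which.max(sims)]  # first-position tie break
        train <- c(train, best)
      }
      train
    })
  list(train = train, test = setdiff(ids, train))
}

#' Error and rank metrics for one evaluation step
#'
#' Root mean squared error, Pearson correlation and Spearman rank
#' correlation between experimental and predicted potency differences.
#' Correlations on constant input are reported as `NA` with
#' `constant_input = TRUE` rather than silently zero.
#'
#' @param predicted,experimental numeric vectors of equal length (length
#'   >= 2 for the correlations, >= 1 for the RMSE).
#' @return list with `rmse`, `pearson`, `spearman`, `n`, `constant_input`.
#' @export
evaluate_step <- function(predicted, experimental) {
  if (length(predicted) != length(experimental))
    stop("predicted and experimental must have equal length")
  if (length(predicted) < 1) stop("at least one value is required")
  rmse <- sqrt(mean((predicted - experimental)^2))
  const <- stats::var(predicted) == 0 || stats::var(experimental) == 0
  if (length(predicted) < 2 || const) {
    list(rmse = rmse, pearson = NA_real_, spearman = NA_real_,
         n = length(predicted), constant_input = TRUE)
  } else {
    list(rmse = rmse,
         pearson = cor(predicted, experimental),
         spearman = cor(predicted, experimental, method = "spearman"),
         n = length(predicted), constant_input = FALSE)
  }
}

#' Incremental train-and-test evaluation of a congeneric series
#'
#' Emulates a live campaign: for each training-set size `n` in `schedule`,
#' split the series, train on all pairwise differences among the `n` train
#' ligands (or fine-tune from a warm-start model), predict every (test,
#' train) difference, and score against experiment.  Repeated over
#' independent seeds.
#'
#' @param series a [congeneric_series()] with at least 3 labelled ligands.
#' @param scheme split scheme, see [split_series()].
#' @param schedule integer vector of training-set sizes; steps not below
#'   the series size are skipped with a warning.
#' @param config a [pairpot_config()].
#' @param seeds integer vector of independent run seeds.
#' @param epochs training epochs per step.
#' @param augment rotation augmentation during training.
#' @param warm_start optional fitted [pairpot()] model or `pairnet_params`;
#'   when given each step fine-tunes from it for
#'   `config$finetune_epochs` epochs instead of training from scratch.
#' @return a `metric_trajectory` data frame with one row per (seed, step):
#'   seed, n_train, n_test, rmse, pearson, spearman.
#' @export
continuous_learning_run <- function(series, scheme = "random",
                                    schedule = c(1, 2, 5, 10, 20),
                                    config = pairpot_config(), seeds = 1:5,
                                    epochs = config$epochs,
                                    augment = config$augment,
                                    warm_start = NULL) {
  pic <- series_pic50(series)
  if (sum(!is.na(pic)) < 3)
    stop("series needs at least 3 ligands with known potency")
  n_total <- length(series$ligands)
  bad <- schedule >= n_total
  if (any(bad)) {
    warning("dropping schedule step(s) ", paste(schedule[bad], collapse = ", "),
            " not below the series size (", n_total, ")")
    schedule <- schedule[!bad]
  }
  provider <- make_grid_provider(series, config)
  warm <- if (!is.null(warm_start)) {
    if (inherits(warm_start, "pairpot")) warm_start$params else warm_start
  }
  rows <- list()
  for (seed in seeds) {
    for (n in schedule) {
      sp <- split_series(series, scheme, n, seed = seed)
      step_seed <- derive_seed(seed, "cl-step", n)
      if (n >= 2) {
        pairs <- build_pairs(series, sp$train)
        fit <- if (is.null(warm))
          train_pairnet(provider, pairs, config, seed = step_seed,
                        epochs = epochs, augment = augment)
        else
          fine_tune(warm, provider, pairs, config = config,
                    seed = step_seed, augment = augment)
        params <- fit$params
      } else {
        # minimal-data condition: one reference ligand, no trainable pair;
        # score the model as initialized (or the warm start as provided)
        params <- warm %||% init_params(config, step_seed)
      }
      refs <- if (config$test_against == "reference")
        select_reference(series)$id else sp$train
      refs <- intersect(refs, sp$train)
      test_pairs <- build_pairs(series, refs, test_ids = sp$test)
      keep <- !is.na(test_pairs$label)
      test_pairs <- test_pairs[keep, , drop = FALSE]
      pred <- predict_pairs(params, provider, test_pairs, config)
      m <- evaluate_step(pred, test_pairs$label)
      rows[[length(rows) + 1L]] <-
        data.frame(seed = seed, n_train = n, n_test = length(sp$test),
                   rmse = m$rmse, pearson = m$pearson,
                   spearman = m$spearman)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_trajectory", class(out))
  out
}

#' Aggregate a metric trajectory over seeds
#'
#' @param trajectory result of [continuous_learning_run()].
#' @return data frame with mean and standard deviation of each metric per
#'   training-set size.
#' @export
aggregate_trajectory <- function(trajectory) {
  agg <- function(f) stats::aggregate(
    trajectory[c("rmse", "pearson", "spearman")],
    by = list(n_train = trajectory$n_train), FUN = f)
  mu <- agg(function(x) mean(x, na.rm = TRUE))
  s <- agg(function(x) sd(x, na.rm = TRUE))
  names(mu)[-1] <- paste0(names(mu)[-1], "_mean")
  names(s)[-1] <- paste0(names(s)[-1], "_sd")
  merge(mu, s, by = "n_train")
}

#' @export
print.metric_trajectory <- function(x, ...) {
  cat("Continuous-learning metric trajectory\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
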