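# Shared fixtures: everything is generated in code at test time.

# Small planted dataset for fast end-to-end tests.
tiny_dataset <- function(nm = 30, nd = 20, signal = 6, seed = 7,
                         missing_frac = 0.2, mask_target = TRUE) {
  gen <- generate_associations(nm, nd, rank = 3, density = 0.15,
                               signal = signal, seed = seed)
  onto <- generate_ontology(nd, max_parents = 2, seed = seed + 1, prefix = "d")
  mfs <- generate_functional_similarity(gen$model, missing_frac = missing_frac,
                                        seed = seed + 2)
  sims <- compute_similarities(gen$assoc, onto, mfs)
  pairs <- balanced_pairs(gen$assoc, seed = seed + 3)
  fs <- build_pair_features(sims$MS, sims$DS, gen$assoc, pairs,
                            y = attr(pairs, "y"), mask_target = mask_target)
  list(gen = gen, onto = onto, mfs = mfs, sims = sims, fs = fs)
}

# Cheap hyperparameters for mechanics tests (not benchmarks).
fast_pipeline_config <- function(seed = 1, mode = "svm", max_levels = 2) {
  pipeline_config(
    sae_epochs = 8, sae_batch = 64,
    cascade = cascade_config(mode = mode, trees_per_estimator = 15,
                             inner_folds = 3, max_levels = max_levels),
    seed = seed)
}

subset_tiny <- function(fs, idx) {
  fs$pairs <- fs$pairs[idx, , drop = FALSE]
  fs$X <- fs$X[idx, , drop = FALSE]
  fs$y <- fs$y[idx]
  fs
}

# random DAG as edge matrix over n nodes named n1..; child -> earlier parent
random_dag_edges <- function(n, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%d", seq_len(n))
    out <- list()
    for (k in seq_len(n)[-1]) {
      np <- sample.int(min(2, k - 1L), 1L)
      for (p in sample.int(k - 1L, np))
        out[[length(out) + 1L]] <- c(nodes[k], nodes[p])
    }
    list(nodes = nodes, edges = do.call(rbind, out))
  })
}
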