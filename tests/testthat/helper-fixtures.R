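# Small fixtures built in code, shared across test files.

# two-group table with a planted shift, small enough for fast fits
small_table <- function(seed = 7, n_per_group = 6, n_metabolites = 40,
                        n_differential = 4, effect = 3) {
  generate_metabolite_table(n_per_group, n_metabolites, n_differential,
                            effect_size = effect, seed = seed)
}

# metabolite table wrapped directly around a given matrix (positive shift)
table_from_matrix <- function(X, groups) {
  metabolite_table(exp(X / max(1, max(abs(X)))), groups)
}

# expression cohort with planted informative targets; returns dataset,
# per-pathway activities (tumor subset) and the truth
macs_fixture <- function(seed, n_tumor = 200, n_normal = 60,
                         n_targets = 40, n_informative = 5,
                         coupling = 0.8, genes_per_pathway = 8,
                         n_pathways = 3) {
  mg <- sprintf("MG%02d", seq_len(genes_per_pathway * n_pathways))
  tg <- sprintf("TGT%02d", seq_len(n_targets))
  gen <- generate_expression_dataset(n_tumor, n_normal, mg, tg,
                                     n_informative, coupling = coupling,
                                     seed = seed)
  acts <- lapply(seq_len(n_pathways), function(i) {
    idx <- (genes_per_pathway * (i - 1) + 1):(genes_per_pathway * i)
    pathway_activity(gen$dataset, mg[idx], pathway_id = paste0("P", i),
                     subset = "tumor")
  })
  tumor <- gen$dataset$condition == "tumor"
  list(dataset = gen$dataset, activities = acts, truth = gen$truth,
       tumor_expr = gen$dataset$expr[tumor, tg, drop = FALSE],
       metabolic_genes = mg, targets = tg)
}

# independent greedy-step oracle: recompute the mRMR argmax from scratch
# at every step, by exhaustive evaluation over the remaining candidates
oracle_mrmr_order <- function(X, activities, config) {
  ids <- colnames(X)
  D <- vapply(ids, function(g) {
    mean(vapply(activities,
                function(a) estimate_mi(X[, g], a$activity, config), 0))
  }, 0)
  selected <- character(0)
  remaining <- ids
  while (length(remaining)) {
    score <- vapply(remaining, function(g) {
      red <- if (length(selected) == 0) 0 else {
        mean(vapply(selected,
                    function(s) estimate_mi(X[, g], X[, s], config), 0))
      }
      D[[g]] - red
    }, 0)
    best <- remaining[score >= max(score) - 1e-12]
    pick <- sort(best)[1]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

# exact hypergeometric upper-tail by direct enumeration of the pmf
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
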