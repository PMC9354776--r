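# Synthetic-data generators with planted ground truth.  Every input the
# pipeline consumes (metabolite table, pathway database + annotation,
# expression cohorts, target-gene link table) can be simulated, so all
# downstream stages are testable without external data.

#' Generate a two-group metabolite intensity table with planted shifts
#'
#' Intensities are log-normal: log-intensities are normal with a
#' per-metabolite baseline mean (uniform on log(1e5)..log(1e7), i.e. typical
#' LC-MS peak areas) and standard deviation `sigma_log = 0.3`.  In the
#' treated group the `n_differential` planted metabolites have their
#' log-scale means shifted by `effect_size` standard deviations, with
#' alternating sign (first planted metabolite up, second down, ...), so both
#' up- and down-regulated metabolites occur.
#'
#' @param n_per_group Samples per group (>= 3).
#' @param n_metabolites Number of metabolites (> 0).
#' @param n_differential Number of planted differential metabolites
#'   (0 <= n_differential <= n_metabolites).
#' @param effect_size Shift of the treated-group mean, in units of the
#'   log-scale standard deviation.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @param sigma_log Log-scale standard deviation of intensities.
#'
#' @return A list with elements `table` (a [metabolite_table]) and `truth`
#'   (list with `differential_metabolites`, `directions`, `seed`).
#' @export
generate_metabolite_table <- function(n_per_group, n_metabolites,
                                      n_differential, effect_size = 2,
                                      seed = 1, sigma_log = 0.3) {
  if (n_per_group < 3L) stop("`n_per_group` must be at least 3")
  if (n_metabolites < 1L) stop("`n_metabolites` must be positive")
  if (n_differential < 0L || n_differential > n_metabolites) {
    stop("`n_differential` must lie in [0, n_metabolites]")
  }
  set.seed(seed)
  met_ids <- sprintf("M%03d", seq_len(n_metabolites))
  n <- 2L * n_per_group
  groups <- rep(c("control", "treated"), each = n_per_group)
  base_mu <- runif(n_metabolites, log(1e5), log(1e7))
  logx <- matrix(rnorm(n * n_metabolites, sd = sigma_log), nrow = n)
  logx <- sweep(logx, 2L, base_mu, "+")
  planted <- character(0)
  directions <- character(0)
  if (n_differential > 0L) {
    idx <- sort(sample.int(n_metabolites, n_differential))
    planted <- met_ids[idx]
    signs <- rep_len(c(1, -1), n_differential)
    directions <- ifelse(signs > 0, "up", "down")
    treated <- groups == "treated"
    for (i in seq_along(idx)) {
      logx[treated, idx[i]] <- logx[treated, idx[i]] +
        signs[i] * effect_size * sigma_log
    }
  }
  tab <- metabolite_table(
    exp(logx), groups,
    sample_ids = paste0(ifelse(groups == "control", "C", "T"),
                        rep(seq_len(n_per_group), 2L)),
    metabolite_ids = met_ids
  )
  list(table = tab,
       truth = list(differential_metabolites = planted,
                    directions = directions, seed = seed))
}

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# connected random graph over `nodes`: spanning tree + extra random edges
random_connected_graph <- function(nodes) {
  n <- length(nodes)
  perm <- sample(nodes)
  # attach node i+1 to a uniformly chosen earlier node in the permutation
  parent <- vapply(seq_len(n - 1L), function(i) perm[sample.int(i, 1L)], "")
  edges <- cbind(perm[-1], parent)
  n_extra <- max(0L, floor(n / 3))
  if (n_extra > 0L && n > 2L) {
    for (k in seq_len(n_extra)) {
      e <- sample(nodes, 2L)
      edges <- rbind(edges, e)
    }
  }
  # deduplicate undirected edges, drop self loops
  key <- apply(edges, 1L, function(e) paste(sort(e), collapse = "\r"))
  edges <- edges[!duplicated(key) & edges[, 1L] != edges[, 2L], , drop = FALSE]
  unname(edges)
}

#' Generate a pathway database and metabolite-to-gene annotation
#'
#' Builds `n_pathways` pathway definitions over the supplied metabolite
#' universe.  The first `n_core_planted` pathways are enriched in the planted
#' differential metabolites: every differential metabolite is assigned to one
#' of them (and occasionally, with probability 0.2, also to a non-core
#' pathway).  Each pathway carries a connected random graph over its members.
#' The annotation maps every metabolite of the universe to 1..3 genes drawn
#' from a shared enzyme-gene pool, so genes can serve several metabolites.
#'
#' @param n_pathways Number of pathways.
#' @param size_range Integer pair: minimum/maximum pathway size (min >= 2).
#' @param n_core_planted Number of pathways enriched in differential
#'   metabolites (<= n_pathways).
#' @param metabolite_ids Metabolite universe (character).
#' @param differential_ids Planted differential metabolites (subset of
#'   `metabolite_ids`; may be empty).
#' @param gene_pool_size Size of the enzyme-gene pool the annotation draws
#'   from.
#' @param seed Integer seed.
#'
#' @return A list with `pathways` (list of [pathway_definition]),
#'   `annotation` (data frame with columns `metabolite`, `gene`) and `truth`
#'   (list with `core_pathways`, `pathway_assignments`, `seed`).
#' @export
generate_pathway_db <- function(n_pathways, size_range = c(4L, 12L),
                                n_core_planted = 0L, metabolite_ids,
                                differential_ids = character(),
                                gene_pool_size = 80L, seed = 1) {
  if (n_pathways < 1L) stop("`n_pathways` must be positive")
  if (size_range[1L] < 2L) stop("`size_range` lower bound must be at least 2")
  if (n_core_planted > n_pathways) {
    stop("`n_core_planted` cannot exceed `n_pathways`")
  }
  if (!all(differential_ids %in% metabolite_ids)) {
    stop("`differential_ids` must be a subset of `metabolite_ids`")
  }
  set.seed(seed)
  p_ids <- sprintf("P%02d", seq_len(n_pathways))
  sizes <- resample(seq(size_range[1L], size_range[2L]), n_pathways,
                    replace = TRUE)
  members <- vector("list", n_pathways)
  names(members) <- p_ids
  # assign each differential metabolite to one planted-core pathway
  if (length(differential_ids) && n_core_planted > 0L) {
    core_of <- rep_len(seq_len(n_core_planted), length(differential_ids))
    for (i in seq_along(differential_ids)) {
      members[[core_of[i]]] <- c(members[[core_of[i]]], differential_ids[i])
      if (n_core_planted < n_pathways && runif(1) < 0.2) {
        j <- resample((n_core_planted + 1L):n_pathways, 1L)
        members[[j]] <- c(members[[j]], differential_ids[i])
      }
    }
  }
  background <- setdiff(metabolite_ids, differential_ids)
  for (i in seq_len(n_pathways)) {
    need <- max(0L, sizes[i] - length(members[[i]]))
    need <- min(need, length(background))
    if (need > 0L) members[[i]] <- c(members[[i]], resample(background, need))
    if (length(members[[i]]) < 2L) {
      members[[i]] <- unique(c(members[[i]],
                               resample(metabolite_ids,
                                        2L - length(members[[i]]) + 1L)))[1:2]
    }
  }
  pathways <- lapply(seq_len(n_pathways), function(i) {
    pathway_definition(p_ids[i], sprintf("Pathway %02d", i), members[[i]],
                       random_connected_graph(members[[i]]))
  })
  gene_pool <- sprintf("ENZ%03d", seq_len(gene_pool_size))
  ann <- do.call(rbind, lapply(metabolite_ids, function(m) {
    g <- sample(gene_pool, sample.int(3L, 1L))
    data.frame(metabolite = m, gene = g, stringsAsFactors = FALSE)
  }))
  ann <- unique(ann)
  rownames(ann) <- NULL
  assignments <- lapply(pathways, function(p) p$members)
  names(assignments) <- p_ids
  list(pathways = pathways, annotation = ann,
       truth = list(core_pathways = p_ids[seq_len(n_core_planted)],
                    pathway_assignments = assignments, seed = seed))
}

#' Generate a tumor/normal expression cohort with planted informative targets
#'
#' One latent pathway-activity factor `f` (standard normal per sample, with
#' an additive mean shift of `tumor_shift` in tumor samples, modelling
#' pathway dysregulation in the tumor state) drives all supplied metabolic
#' genes at loading `gene_loading`; a planted subset of targets is coupled to
#' the same factor at correlation `coupling`; all remaining genes are
#' independent noise.  Each gene receives its own baseline mean (uniform on
#' 4..12, a log2-microarray-like scale).
#'
#' @param n_tumor,n_normal Sample counts per condition.
#' @param metabolic_genes Character vector of metabolic gene ids.
#' @param targets Character vector of candidate target gene ids.
#' @param n_informative_targets How many targets to couple to the factor
#'   (<= length(targets)).
#' @param coupling Target-factor correlation, in `[0, 1)`.
#' @param seed Integer seed.
#' @param dataset_id Cohort identifier.
#' @param gene_loading Metabolic-gene/factor correlation.
#' @param tumor_shift Mean shift of the latent factor in tumor samples.
#' @param informative_targets Optional explicit informative-target set
#'   (subset of `targets`); overrides the seeded random draw, so several
#'   cohorts can share the same planted targets.
#'
#' @return A list with `dataset` (an [expression_dataset]) and `truth` (list
#'   with `informative_targets`, `factor` (per-sample latent activity),
#'   `seed`).
#' @export
generate_expression_dataset <- function(n_tumor, n_normal, metabolic_genes,
                                        targets, n_informative_targets,
                                        coupling = 0.8, seed = 1,
                                        dataset_id = "synthetic",
                                        gene_loading = 0.8,
                                        tumor_shift = 1,
                                        informative_targets = NULL) {
  if (length(metabolic_genes) == 0L || length(targets) == 0L) {
    stop("`metabolic_genes` and `targets` must be non-empty")
  }
  if (n_informative_targets > length(targets)) {
    stop("`n_informative_targets` cannot exceed the number of targets")
  }
  if (coupling < 0 || coupling >= 1) stop("`coupling` must lie in [0, 1)")
  if (n_tumor < 2L || n_normal < 0L) stop("invalid sample counts")
  if (!is.null(informative_targets) &&
      !all(informative_targets %in% targets)) {
    stop("`informative_targets` must be a subset of `targets`")
  }
  set.seed(seed)
  informative <- if (!is.null(informative_targets)) {
    sort(informative_targets)
  } else if (n_informative_targets > 0L) {
    sort(sample(targets, n_informative_targets))
  } else character(0)
  n <- n_tumor + n_normal
  condition <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
  f <- rnorm(n) + tumor_shift * (condition == "tumor")
  genes <- unique(c(metabolic_genes, targets))
  expr <- matrix(rnorm(n * length(genes)), nrow = n,
                 dimnames = list(NULL, genes))
  for (g in metabolic_genes) {
    expr[, g] <- gene_loading * f + sqrt(1 - gene_loading^2) * expr[, g]
  }
  for (g in informative) {
    expr[, g] <- coupling * f + sqrt(1 - coupling^2) * expr[, g]
  }
  baseline <- runif(length(genes), 4, 12)
  expr <- sweep(expr, 2L, baseline, "+")
  ds <- expression_dataset(
    expr, condition, dataset_id = dataset_id,
    sample_ids = paste0(dataset_id, "_s", seq_len(n))
  )
  list(dataset = ds,
       truth = list(informative_targets = informative, factor = f,
                    seed = seed))
}

#' Generate a target-to-metabolic-gene link table
#'
#' Stand-in for an external protein-interaction link table (synthetic):
#' each target is linked to a random handful of metabolic genes.
#'
#' @param targets,metabolic_genes Gene id vectors.
#' @param links_per_target Mean number of links per target.
#' @param seed Integer seed.
#' @return Data frame with columns `target`, `gene`.
#' @export
generate_target_gene_links <- function(targets, metabolic_genes,
                                       links_per_target = 3L, seed = 1) {
  if (length(targets) == 0L || length(metabolic_genes) == 0L) {
    stop("`targets` and `metabolic_genes` must be non-empty")
  }
  set.seed(seed)
  out <- do.call(rbind, lapply(targets, function(tg) {
    k <- min(length(metabolic_genes),
             max(1L, stats::rpois(1L, links_per_target)))
    data.frame(target = tg, gene = sample(metabolic_genes, k),
               stringsAsFactors = FALSE)
  }))
  unique(out)
}
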