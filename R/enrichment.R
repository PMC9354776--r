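# Metabolite-set over-representation with Holm and Benjamini-Hochberg
# adjustment, topology-based pathway impact, and the core-pathway flag.

#' Hypergeometric over-representation p-value for one pathway
#'
#' `p = P(X >= k)` where `X ~ Hypergeometric(N = |universe|,
#' K = |pathway members in universe|, n = |hits|)` and `k` is the observed
#' overlap between hits and pathway members.
#'
#' @param hits Character vector of differential metabolite ids (must be a
#'   subset of `universe`).
#' @param pathway A [pathway_definition].
#' @param universe Character vector: all metabolites measured in the study.
#' @return The raw upper-tail p-value.
#' @export
ora_hypergeometric <- function(hits, pathway, universe) {
  if (length(universe) == 0L) stop("the metabolite universe is empty")
  if (!all(hits %in% universe)) {
    stop("`hits` must be a subset of `universe`")
  }
  K <- length(intersect(pathway$members, universe))
  if (K == 0L) stop("pathway '", pathway$id, "' shares no metabolite with ",
                    "the universe")
  n <- length(unique(hits))
  k <- length(intersect(hits, pathway$members))
  N <- length(unique(universe))
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Holm step-down adjusted p-values
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order, monotone and capped
#'   at 1.
#' @export
adjust_holm <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "holm")
}

#' Benjamini-Hochberg FDR q-values
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order, monotone and capped at 1.
#' @export
adjust_bh <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Topology-based pathway impact
#'
#' Impact is the sum of relative betweenness centralities (betweenness
#' normalized by `(n-1)(n-2)/2` on the undirected, unit-weight pathway
#' graph) of the hit members, divided by the sum over all members; 0 when
#' no member has positive centrality.  Isolated members (not on any edge)
#' have zero centrality.  Hits outside the pathway are silently ignored
#' (being outside any given pathway is the normal case for a hit).
#'
#' @param pathway A [pathway_definition].
#' @param hits Character vector of differential metabolite ids.
#' @return Impact value in `[0, 1]`.
#' @export
pathway_impact <- function(pathway, hits) {
  hits <- intersect(hits, pathway$members)
  g <- igraph::graph_from_data_frame(
    as.data.frame(pathway$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = pathway$members, stringsAsFactors = FALSE)
  )
  n <- length(pathway$members)
  if (n < 3L) return(0)
  btw <- igraph::betweenness(g, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  total <- sum(btw)
  if (total <= 0) return(0)
  sum(btw[hits]) / total
}

#' Enrich a pathway database against a hit set
#'
#' Runs [ora_hypergeometric()] and [pathway_impact()] for every pathway,
#' attaches Holm and BH adjustments and the core-pathway flag.
#'
#' @param hits Differential metabolite ids.
#' @param pathways List of [pathway_definition] objects.
#' @param universe All measured metabolites.
#' @param core_alpha Core-pathway threshold on the raw p (strict).
#' @return An `enrichment_result` data frame with columns `pathway`,
#'   `name`, `size`, `overlap`, `p`, `p_holm`, `q`, `impact`, `is_core`,
#'   ordered by increasing p.
#' @export
enrich_pathways <- function(hits, pathways, universe, core_alpha = 0.05) {
  if (length(pathways) == 0L) stop("no pathways supplied")
  res <- do.call(rbind, lapply(pathways, function(pw) {
    data.frame(
      pathway = pw$id, name = pw$name, size = length(pw$members),
      overlap = length(intersect(hits, pw$members)),
      p = ora_hypergeometric(hits, pw, universe),
      impact = pathway_impact(pw, hits),
      stringsAsFactors = FALSE
    )
  }))
  res$p_holm <- adjust_holm(res$p)
  res$q <- adjust_bh(res$p)
  res <- flag_core_pathways(res, core_alpha)
  res <- res[order(res$p), c("pathway", "name", "size", "overlap", "p",
                             "p_holm", "q", "impact", "is_core")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Flag core pathways
#'
#' A pathway is core iff its raw over-representation p-value is strictly
#' below `core_alpha`.  The raw p is used (adjusted values are reported
#' alongside for inspection).
#'
#' @param results Data frame with a `p` column (e.g. from
#'   [enrich_pathways()]).
#' @param core_alpha Strict threshold.
#' @return `results` with an `is_core` logical column set.
#' @export
flag_core_pathways <- function(results, core_alpha = 0.05) {
  if (is.null(results$p)) stop("`results` must contain a raw `p` column")
  results$is_core <- results$p < core_alpha
  results
}
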