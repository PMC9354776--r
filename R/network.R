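# Mapping of core-pathway metabolites to metabolic genes through a
# user-supplied annotation table, and assembly/export of the multilevel
# compound-target-gene-metabolite-pathway network.

#' Map differential metabolites in core pathways to metabolic genes
#'
#' The metabolic gene set is the union of annotation genes of the
#' differential metabolites that are members of at least one core pathway;
#' the bipartite network contains exactly those metabolite-gene pairs.
#'
#' @param core_pathways List of [pathway_definition] objects (the core
#'   pathways only).
#' @param differential Character vector of differential metabolite ids, or
#'   the data frame returned by [select_differential()].
#' @param annotation Data frame with columns `metabolite`, `gene`.
#' @return A list with `edges` (data frame `metabolite`, `gene`), `genes`
#'   (character), `metabolites` (character), and `per_pathway` (named list:
#'   core pathway id -> genes of its differential members).
#' @export
map_metabolites_to_genes <- function(core_pathways, differential,
                                     annotation) {
  if (is.data.frame(differential)) differential <- differential$metabolite
  if (!all(c("metabolite", "gene") %in% names(annotation))) {
    stop("`annotation` needs columns `metabolite` and `gene`")
  }
  core_members <- unique(unlist(lapply(core_pathways, `[[`, "members")))
  mets <- intersect(differential, core_members)
  edges <- unique(annotation[annotation$metabolite %in% mets,
                             c("metabolite", "gene")])
  if (nrow(edges) == 0L) {
    stop("no metabolic genes mapped: check that the annotation covers the ",
         "differential metabolites of the core pathways")
  }
  rownames(edges) <- NULL
  per_pathway <- lapply(core_pathways, function(pw) {
    m <- intersect(differential, pw$members)
    sort(unique(edges$gene[edges$metabolite %in% m]))
  })
  names(per_pathway) <- vapply(core_pathways, `[[`, "", "id")
  per_pathway <- per_pathway[vapply(per_pathway, length, 0L) > 0L]
  list(edges = edges, genes = sort(unique(edges$gene)),
       metabolites = sort(unique(edges$metabolite)),
       per_pathway = per_pathway)
}

LAYERS <- c("compound", "target", "metabolic_gene", "metabolite", "pathway")

#' Assemble the multilevel compound-target-gene-metabolite-pathway network
#'
#' Node layers: one (or more) compounds, retained targets, metabolic genes,
#' metabolites, pathways.  Typed edges: compound-target (every target),
#' target-metabolic_gene (from the link table), metabolic_gene-metabolite
#' (the bipartite mapping), metabolite-pathway (memberships).  Edges are
#' deduplicated; any edge referencing an undeclared node is an error.
#' Node identifiers may repeat across layers (a gene can be both a target
#' and a metabolic gene); internally vertices are keyed `layer:id`.
#'
#' @param compound Compound id(s).
#' @param targets Retained target gene ids.
#' @param target_gene_links Data frame `target`, `gene`.
#' @param metabolite_gene_edges Data frame `metabolite`, `gene` (from
#'   [map_metabolites_to_genes()]).
#' @param metabolite_pathways Data frame `metabolite`, `pathway`.
#' @return A `multilevel_network` wrapping an igraph with vertex
#'   attributes `label` and `layer` and edge attribute `type`.
#' @export
build_multilevel_network <- function(compound, targets, target_gene_links,
                                     metabolite_gene_edges,
                                     metabolite_pathways) {
  genes <- sort(unique(metabolite_gene_edges$gene))
  mets <- sort(unique(metabolite_gene_edges$metabolite))
  pws <- sort(unique(metabolite_pathways$pathway))
  dangle <- c(
    setdiff(target_gene_links$target, targets),
    setdiff(target_gene_links$gene, genes),
    setdiff(metabolite_pathways$metabolite, mets)
  )
  if (length(dangle)) {
    stop("dangling edge reference(s): ",
         paste(unique(dangle), collapse = ", "))
  }
  key <- function(layer, id) paste0(layer, ":", id)
  verts <- data.frame(
    name = c(key("compound", compound), key("target", targets),
             key("metabolic_gene", genes), key("metabolite", mets),
             key("pathway", pws)),
    label = c(compound, targets, genes, mets, pws),
    layer = rep(LAYERS, c(length(compound), length(targets), length(genes),
                          length(mets), length(pws))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(verts$name)) stop("duplicate node within a layer")
  ed <- rbind(
    if (length(targets)) data.frame(
      from = key("compound", rep(compound, each = length(targets))),
      to = key("target", rep(targets, length(compound))),
      type = "compound-target", stringsAsFactors = FALSE),
    if (nrow(target_gene_links)) data.frame(
      from = key("target", target_gene_links$target),
      to = key("metabolic_gene", target_gene_links$gene),
      type = "target-metabolic_gene", stringsAsFactors = FALSE),
    data.frame(
      from = key("metabolic_gene", metabolite_gene_edges$gene),
      to = key("metabolite", metabolite_gene_edges$metabolite),
      type = "metabolic_gene-metabolite", stringsAsFactors = FALSE),
    if (nrow(metabolite_pathways)) data.frame(
      from = key("metabolite", metabolite_pathways$metabolite),
      to = key("pathway", metabolite_pathways$pathway),
      type = "metabolite-pathway", stringsAsFactors = FALSE)
  )
  ed <- unique(ed)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
  structure(list(graph = g), class = "multilevel_network")
}

#' @export
print.multilevel_network <- function(x, ...) {
  layer <- igraph::V(x$graph)$layer
  counts <- table(factor(layer, levels = LAYERS))
  cat("<multilevel_network> ", igraph::vcount(x$graph), " nodes (",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
      "), ", igraph::ecount(x$graph), " edges, ",
      igraph::count_components(x$graph), " component(s)\n", sep = "")
  invisible(x)
}

#' Export / import the multilevel network
#'
#' GraphML preserves all typed attributes and round-trips exactly through
#' [read_network_graphml()]; SIF is a three-column
#' `node <tab> edge-type <tab> node` table (labels, not internal keys).
#'
#' @param network A `multilevel_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  # igraph stores its own "id" attribute on graphml import; drop it
  if ("id" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::delete_vertex_attr(g, "id")
  }
  structure(list(graph = g), class = "multilevel_network")
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(network, path) {
  g <- network$graph
  el <- igraph::as_edgelist(g, names = TRUE)
  lab <- setNames(igraph::V(g)$label, igraph::V(g)$name)
  df <- data.frame(from = lab[el[, 1L]], type = igraph::E(g)$type,
                   to = lab[el[, 2L]], stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
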