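#' Two-group metabolite intensity table
#'
#' The basic container for chemometric analysis: a samples-by-metabolites
#' matrix of positive intensities (LC-MS peak areas or comparable) together
#' with a two-level group factor (control vs. treated).
#'
#' @param intensity Numeric matrix, samples in rows, metabolites in columns.
#'   All values must be finite and strictly positive.
#' @param groups Character or factor of length `nrow(intensity)` with exactly
#'   two levels; the first level (alphabetical unless a factor with explicit
#'   levels is supplied) is treated as the control/reference group.
#' @param sample_ids,metabolite_ids Optional identifiers; default to the
#'   dimnames of `intensity`.
#'
#' @return An object of class `metabolite_table`: a list with elements
#'   `intensity`, `groups`, `sample_ids`, `metabolite_ids`.
#' @export
metabolite_table <- function(intensity, groups,
                             sample_ids = rownames(intensity),
                             metabolite_ids = colnames(intensity)) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("`intensity` must be a numeric matrix (samples x metabolites)")
  }
  if (any(!is.finite(intensity))) stop("`intensity` contains non-finite values")
  if (any(intensity <= 0)) stop("`intensity` must be strictly positive")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(intensity)))
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(ncol(intensity)))
  if (length(metabolite_ids) != ncol(intensity)) {
    stop("metabolite id count must equal the number of intensity columns")
  }
  if (length(groups) != nrow(intensity) || anyNA(groups)) {
    stop("`groups` must label every sample, with no missing values")
  }
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) != 2L) stop("`groups` must have exactly two levels")
  if (any(table(groups) < 3L)) stop("each group needs at least 3 samples")
  dimnames(intensity) <- list(sample_ids, metabolite_ids)
  structure(
    list(intensity = intensity, groups = groups,
         sample_ids = sample_ids, metabolite_ids = metabolite_ids),
    class = "metabolite_table"
  )
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("<metabolite_table> ", nrow(x$intensity), " samples x ",
      ncol(x$intensity), " metabolites; groups: ",
      paste(sprintf("%s=%d", levels(x$groups), table(x$groups)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tumor/normal gene-expression dataset
#'
#' @param expr Numeric matrix, samples in rows, genes in columns (assumed to
#'   be on a log-like scale, e.g. log2 microarray intensities).
#' @param condition Character or factor of per-sample labels, values
#'   `"tumor"` or `"normal"`.
#' @param dataset_id Short identifier for the cohort (e.g. a series name).
#' @param sample_ids,gene_ids Optional identifiers; default to dimnames.
#'
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(expr, condition, dataset_id = "dataset",
                               sample_ids = rownames(expr),
                               gene_ids = colnames(expr)) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric matrix (samples x genes)")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(expr)))
  if (is.null(gene_ids)) stop("`expr` must have gene ids as column names")
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (length(condition) != nrow(expr) || anyNA(condition)) {
    stop("`condition` must label every sample, with no missing values")
  }
  condition <- as.character(condition)
  if (!all(condition %in% c("tumor", "normal"))) {
    stop("`condition` values must be 'tumor' or 'normal'")
  }
  dimnames(expr) <- list(sample_ids, gene_ids)
  structure(
    list(expr = expr, condition = condition, dataset_id = dataset_id,
         sample_ids = sample_ids, gene_ids = gene_ids),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset '", x$dataset_id, "'> ", nrow(x$expr),
      " samples (", sum(x$condition == "tumor"), " tumor / ",
      sum(x$condition == "normal"), " normal) x ", ncol(x$expr),
      " genes\n", sep = "")
  invisible(x)
}

#' Pathway definition: member metabolites plus an undirected graph
#'
#' @param id Pathway identifier.
#' @param name Human-readable pathway name.
#' @param members Character vector of member metabolite ids (>= 2).
#' @param edges Two-column character matrix (or data frame) of undirected
#'   edges; both endpoints must be members.
#'
#' @return An object of class `pathway_definition`.
#' @export
pathway_definition <- function(id, name = id, members, edges) {
  members <- as.character(members)
  if (length(members) < 2L) stop("a pathway needs at least 2 member metabolites")
  if (anyDuplicated(members)) stop("pathway members must be unique")
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(), ncol = 2L)
  if (ncol(edges) != 2L) stop("`edges` must have two columns")
  mode(edges) <- "character"
  bad <- setdiff(c(edges), members)
  if (length(bad)) {
    stop("pathway edges reference non-members: ", paste(bad, collapse = ", "))
  }
  structure(list(id = as.character(id), name = as.character(name),
                 members = members, edges = edges),
            class = "pathway_definition")
}
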