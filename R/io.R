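# Readers and writers for the pipeline's file formats.  All tables are
# tab-separated with '#'-prefixed header comment lines; the pathway
# database is JSON.

write_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read and write metabolite tables
#'
#' The on-disk format is a TSV with a `sample` column, a `group` column and
#' one column per metabolite; '#'-prefixed lines are comments.
#'
#' @param path File path.
#' @param table A [metabolite_table] (for writing).
#' @param comments Optional comment lines recorded in the file header.
#' @return [read_metabolite_table()] returns a [metabolite_table];
#'   [write_metabolite_table()] returns `path` invisibly.
#' @export
read_metabolite_table <- function(path) {
  df <- read_tsv(path)
  if (!all(c("sample", "group") %in% names(df))) {
    stop("metabolite table needs `sample` and `group` columns: ", path)
  }
  met_cols <- setdiff(names(df), c("sample", "group"))
  metabolite_table(as.matrix(df[met_cols]), df$group,
                   sample_ids = df$sample, metabolite_ids = met_cols)
}

#' @rdname read_metabolite_table
#' @export
write_metabolite_table <- function(table, path, comments = character()) {
  df <- data.frame(sample = table$sample_ids,
                   group = as.character(table$groups),
                   table$intensity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, comments)
}

#' Read and write expression datasets
#'
#' TSV with `sample` and `condition` columns plus one column per gene.
#'
#' @param path File path.
#' @param dataset An [expression_dataset] (for writing).
#' @param dataset_id Identifier for the cohort being read; defaults to the
#'   file name without extension.
#' @param comments Optional header comment lines.
#' @return [read_expression_dataset()] returns an [expression_dataset].
#' @export
read_expression_dataset <- function(path, dataset_id = NULL) {
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- read_tsv(path)
  if (!all(c("sample", "condition") %in% names(df))) {
    stop("expression table needs `sample` and `condition` columns: ", path)
  }
  gene_cols <- setdiff(names(df), c("sample", "condition"))
  expression_dataset(as.matrix(df[gene_cols]), df$condition,
                     dataset_id = dataset_id, sample_ids = df$sample,
                     gene_ids = gene_cols)
}

#' @rdname read_expression_dataset
#' @export
write_expression_dataset <- function(dataset, path, comments = character()) {
  df <- data.frame(sample = dataset$sample_ids,
                   condition = dataset$condition, dataset$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, comments)
}

#' Read and write the pathway database (JSON)
#'
#' The format is a JSON array of objects
#' `{id, name, members: [...], edges: [[a, b], ...]}`.
#'
#' @param path File path.
#' @param pathways List of [pathway_definition] objects (for writing).
#' @return [read_pathway_db()] returns a list of [pathway_definition].
#' @export
read_pathway_db <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(pw) {
    edges <- if (length(pw$edges)) {
      do.call(rbind, lapply(pw$edges, function(e) c(e[[1L]], e[[2L]])))
    } else {
      matrix(character(), ncol = 2L)
    }
    pathway_definition(pw$id, pw$name, unlist(pw$members), edges)
  })
}

#' @rdname read_pathway_db
#' @export
write_pathway_db <- function(pathways, path) {
  obj <- lapply(pathways, function(pw) {
    list(id = pw$id, name = pw$name, members = as.list(pw$members),
         edges = lapply(seq_len(nrow(pw$edges)),
                        function(i) as.list(pw$edges[i, ])))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read small auxiliary tables
#'
#' `read_annotation()` expects columns `metabolite`, `gene`;
#' `read_gene_list()` one id per line ('#' comments allowed);
#' `read_target_gene_links()` columns `target`, `gene`.
#'
#' @param path File path.
#' @return A data frame (annotation, links) or character vector (gene
#'   list).
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path)
  if (!all(c("metabolite", "gene") %in% names(df))) {
    stop("annotation needs `metabolite` and `gene` columns: ", path)
  }
  df[c("metabolite", "gene")]
}

#' @rdname read_annotation
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_annotation
#' @export
read_target_gene_links <- function(path) {
  df <- read_tsv(path)
  if (!all(c("target", "gene") %in% names(df))) {
    stop("link table needs `target` and `gene` columns: ", path)
  }
  df[c("target", "gene")]
}
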