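# Per-dataset correlation matrices between metabolic genes and candidate
# targets, cross-dataset aggregation, and the candidate-filter gate that
# feeds the MACS ranking.

subset_samples <- function(dataset, subset = c("tumor", "normal", "all")) {
  subset <- match.arg(subset)
  if (subset == "all") rep(TRUE, nrow(dataset$expr))
  else dataset$condition == subset
}

#' Coexpression matrix between candidate targets and metabolic genes
#'
#' Pearson correlation (with two-sided t-based p-values) between every
#' requested target (rows) and metabolic gene (columns) over the chosen
#' sample subset (tumor by default: the disease state is the biology of
#' interest).  Genes absent from the dataset are dropped with a warning;
#' constant genes yield `NA` cells.
#'
#' @param dataset An [expression_dataset].
#' @param metabolic_genes,targets Gene id vectors.
#' @param subset `"tumor"` (default), `"normal"` or `"all"`.
#' @return A `coexpression_matrix`: list with matrices `r` and `p`
#'   (targets x metabolic genes), `n`, `dataset_id`.
#' @export
compute_coexpression <- function(dataset, metabolic_genes, targets,
                                 subset = c("tumor", "normal", "all")) {
  keep <- subset_samples(dataset, subset)
  n <- sum(keep)
  if (n < 4L) stop("need at least 4 samples in the '", match.arg(subset),
                   "' subset (found ", n, ")")
  miss <- setdiff(c(metabolic_genes, targets), dataset$gene_ids)
  if (length(miss)) {
    warning("genes absent from dataset '", dataset$dataset_id, "': ",
            paste(miss, collapse = ", "))
  }
  mg <- intersect(metabolic_genes, dataset$gene_ids)
  tg <- intersect(targets, dataset$gene_ids)
  if (length(mg) == 0L || length(tg) == 0L) {
    stop("no metabolic genes or no targets present in dataset '",
         dataset$dataset_id, "'")
  }
  Tm <- dataset$expr[keep, tg, drop = FALSE]
  Mm <- dataset$expr[keep, mg, drop = FALSE]
  const_t <- apply(Tm, 2L, sd) < .Machine$double.eps * 100
  const_m <- apply(Mm, 2L, sd) < .Machine$double.eps * 100
  if (any(const_t) || any(const_m)) {
    message("constant gene(s) reported as NA: ",
            paste(c(tg[const_t], mg[const_m]), collapse = ", "))
  }
  r <- suppressWarnings(cor(Tm, Mm))
  r[const_t, ] <- NA_real_
  r[, const_m] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  structure(list(r = r, p = p, n = n, dataset_id = dataset$dataset_id),
            class = "coexpression_matrix")
}

#' @export
print.coexpression_matrix <- function(x, ...) {
  cat("<coexpression_matrix '", x$dataset_id, "'> ", nrow(x$r),
      " targets x ", ncol(x$r), " metabolic genes, n=", x$n, "\n", sep = "")
  invisible(x)
}

#' Aggregate coexpression matrices across datasets
#'
#' Element-wise median (default; robust to one discordant cohort) or mean
#' over the datasets in which a cell is non-missing, on the intersection of
#' row/column ids.  The aggregated `p` is the same element-wise summary of
#' the per-dataset p-values and is descriptive only.
#'
#' @param matrices List of `coexpression_matrix` objects (>= 1).
#' @param method `"median"` (default) or `"mean"`.
#' @return A consensus `coexpression_matrix` with `dataset_id =
#'   "consensus"`.
#' @export
aggregate_coexpression <- function(matrices, method = c("median", "mean")) {
  method <- match.arg(method)
  if (length(matrices) == 0L) stop("no coexpression matrices supplied")
  rows <- Reduce(intersect, lapply(matrices, function(m) rownames(m$r)))
  cols <- Reduce(intersect, lapply(matrices, function(m) colnames(m$r)))
  if (length(rows) == 0L || length(cols) == 0L) {
    stop("the datasets share no targets or no metabolic genes")
  }
  agg_fun <- if (method == "median") {
    function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  } else {
    function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  stack <- function(field) {
    arr <- vapply(matrices, function(m) m[[field]][rows, cols, drop = FALSE],
                  matrix(0, length(rows), length(cols)))
    dim(arr) <- c(length(rows), length(cols), length(matrices))
    out <- apply(arr, c(1L, 2L), agg_fun)
    dimnames(out) <- list(rows, cols)
    out
  }
  structure(list(r = stack("r"), p = stack("p"),
                 n = median(vapply(matrices, `[[`, 0, "n")),
                 dataset_id = "consensus"),
            class = "coexpression_matrix")
}

#' Filter candidate targets by maximum absolute coexpression
#'
#' A target survives when its maximum `|r|` across metabolic genes reaches
#' `r_min`.  `r_min = 0` disables the gate (all targets retained).
#'
#' @param consensus A `coexpression_matrix`.
#' @param r_min Threshold in `[0, 1)`.
#' @return Character vector of retained target ids.
#' @export
filter_candidate_targets <- function(consensus, r_min = 0.3) {
  if (nrow(consensus$r) == 0L) stop("empty coexpression matrix")
  if (r_min <= 0) return(rownames(consensus$r))
  maxabs <- apply(abs(consensus$r), 1L, function(v) {
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
  })
  rownames(consensus$r)[maxabs >= r_min]
}
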