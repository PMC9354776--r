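# Maximum activity contribution score (MACS): mutual-information relevance
# of candidate targets to core-pathway activity, redundancy among targets,
# greedy max-relevance/min-redundancy ranking, and above-average retention.
#
# All mutual information is reported in nats.

#' Mutual-information estimator configuration
#'
#' @param method `"knn"` (Kraskov-Stoegbauer-Grassberger k-nearest-neighbour
#'   estimator, default: low bias for continuous expression data) or
#'   `"histogram"` (plug-in estimate on an equal-frequency binned joint
#'   table: deterministic and exact for discrete data, but positively
#'   biased for continuous data).
#' @param k Neighbour count for the knn method (>= 1).
#' @param bins Bin count for the histogram method; `NULL` means
#'   `ceiling(sqrt(n))` equal-frequency bins.
#' @return An object of class `mi_config`.
#' @export
mi_config <- function(method = c("knn", "histogram"), k = 3L, bins = NULL) {
  method <- match.arg(method)
  if (k < 1L) stop("`k` must be at least 1")
  if (!is.null(bins) && bins < 2L) stop("`bins` must be at least 2")
  structure(list(method = method, k = as.integer(k), bins = bins),
            class = "mi_config")
}

#' Estimate mutual information between two vectors (nats)
#'
#' `method = "knn"` uses the KSG (algorithm 1) estimator; `"histogram"`
#' uses the plug-in estimate on a joint table of equal-frequency bins.
#' Negative estimates (estimator noise) are clipped to 0.  Both estimators
#' depend on the data only through differences/ranks, so adding a constant
#' to either vector leaves the estimate unchanged.
#'
#' @param x,y Numeric vectors of equal length (>= 20), finite.
#' @param config An [mi_config()].
#' @return Non-negative mutual information in nats.
#' @export
estimate_mi <- function(x, y, config = mi_config()) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 20L) stop("need at least 20 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`x` and `y` must be finite")
  }
  mi <- if (config$method == "knn") {
    ksg_mi_cpp(as.numeric(x), as.numeric(y), config$k)
  } else {
    histogram_mi(x, y, config$bins)
  }
  max(0, mi)
}

# plug-in MI on an equal-frequency binned joint table; binning is on the
# empirical CDF (max-ties rank), so tied values always share a bin and the
# estimate is invariant under monotone shifts
histogram_mi <- function(x, y, bins = NULL) {
  n <- length(x)
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  cut_ef <- function(v) {
    ceiling(rank(v, ties.method = "max") * bins / n)
  }
  joint <- table(cut_ef(x), cut_ef(y)) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / outer(px, py)[pos]))
}

#' Per-sample activity of a core pathway
#'
#' Activity is the per-sample mean of the z-scored constituent metabolic
#' gene expressions, re-standardized to zero mean and unit variance over
#' the chosen sample subset.  This operationalizes the pathway as a random
#' variable observable sample-wise alongside each candidate target.
#'
#' @param dataset An [expression_dataset].
#' @param genes Constituent metabolic genes of the pathway (>= 1 present
#'   in the dataset).
#' @param pathway_id Identifier carried through to the result.
#' @param subset Sample subset, as in [compute_coexpression()].
#' @return A `pathway_activity`: list with `pathway`, `activity` (numeric,
#'   one value per subset sample), `genes`, `n`.
#' @export
pathway_activity <- function(dataset, genes, pathway_id = "pathway",
                             subset = c("tumor", "normal", "all")) {
  keep <- subset_samples(dataset, subset)
  present <- intersect(genes, dataset$gene_ids)
  if (length(present) == 0L) {
    stop("no constituent gene of pathway '", pathway_id,
         "' is present in dataset '", dataset$dataset_id, "'")
  }
  if (length(present) < length(genes)) {
    message("pathway '", pathway_id, "': ",
            length(genes) - length(present), " gene(s) absent from '",
            dataset$dataset_id, "'")
  }
  Z <- dataset$expr[keep, present, drop = FALSE]
  sds <- apply(Z, 2L, sd)
  ok <- sds > .Machine$double.eps * 100
  if (!any(ok)) stop("all constituent genes of pathway '", pathway_id,
                     "' are constant")
  Z <- scale(Z[, ok, drop = FALSE])
  a <- rowMeans(Z)
  if (var(a) < 1e-10) {
    stop("degenerate activity for pathway '", pathway_id,
         "': constituent genes cancel (variance < 1e-10)")
  }
  structure(list(pathway = pathway_id, activity = drop(scale(a)),
                 genes = present[ok], n = sum(keep)),
            class = "pathway_activity")
}

#' Mutual-information relevance of a target to the core pathways
#'
#' The relevance contribution `D` of a target is the mean mutual
#' information between its expression vector and the activity vectors of
#' the core pathways.
#'
#' @param x Target expression vector (over the same samples as the
#'   activities).
#' @param activities List of `pathway_activity` objects (>= 1).
#' @param config An [mi_config()].
#' @return Mean MI in nats (non-negative).
#' @export
relevance <- function(x, activities, config = mi_config()) {
  if (length(activities) == 0L) {
    stop("no core pathways: relevance is undefined")
  }
  mean(vapply(activities,
              function(a) estimate_mi(x, a$activity, config), 0))
}

#' Greedy max-relevance / min-redundancy target ranking
#'
#' Produces a full ranking of candidate targets.  The first selection
#' maximizes relevance `D`; each subsequent selection maximizes the
#' marginal score `D(g) - R(g | S)` where `R(g | S)` is the mean pairwise
#' mutual information between `g` and the already-selected set `S`.  Ties
#' are broken lexicographically by gene id.  The marginal score at the
#' moment of selection is each target's MACS value.
#'
#' @param candidates Numeric matrix, samples x candidate targets (>= 2
#'   columns, named), or a named list of equal-length vectors.
#' @param activities List of `pathway_activity` objects over the same
#'   samples.
#' @param config An [mi_config()].
#' @return A `macs_result` data frame with columns `target`, `rank`,
#'   `relevance`, `redundancy`, `score` (`= relevance - redundancy`, nats).
#' @export
greedy_mrmr_rank <- function(candidates, activities, config = mi_config()) {
  if (is.list(candidates) && !is.matrix(candidates)) {
    candidates <- do.call(cbind, candidates)
  }
  if (is.null(colnames(candidates))) stop("candidates must be named")
  m <- ncol(candidates)
  if (m < 2L) stop("need at least 2 candidate targets")
  nlen <- length(activities[[1L]]$activity)
  if (nrow(candidates) != nlen) {
    stop("candidate vectors and activities differ in length")
  }
  ids <- colnames(candidates)
  D <- vapply(seq_len(m),
              function(j) relevance(candidates[, j], activities, config), 0)
  names(D) <- ids
  # full pairwise MI matrix among candidates
  M <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      M[i, j] <- M[j, i] <- estimate_mi(candidates[, i], candidates[, j],
                                        config)
    }
  }
  selected <- character(0)
  res <- data.frame(target = character(m), rank = seq_len(m),
                    relevance = numeric(m), redundancy = numeric(m),
                    score = numeric(m), stringsAsFactors = FALSE)
  remaining <- ids
  for (step in seq_len(m)) {
    red <- if (length(selected) == 0L) {
      setNames(numeric(length(remaining)), remaining)
    } else {
      colMeans(M[selected, remaining, drop = FALSE])
    }
    score <- D[remaining] - red
    best <- remaining[score >= max(score) - 1e-12]
    pick <- sort(best)[1L]
    if (length(best) > 1L) {
      message("tie at rank ", step, " broken lexicographically: ", pick)
    }
    res$target[step] <- pick
    res$relevance[step] <- D[pick]
    res$redundancy[step] <- red[pick]
    res$score[step] <- score[pick]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  class(res) <- c("macs_result", "data.frame")
  attr(res, "mi_config") <- config
  res
}

#' Aggregate per-dataset MACS rankings and apply above-average retention
#'
#' Scores are aggregated per target across datasets (mean by default) on
#' the shared candidate set; a target is retained iff its aggregated score
#' is strictly greater than the mean aggregated score over all targets.
#'
#' @param rankings A single `macs_result` or a list of them (one per
#'   dataset).
#' @param aggregation `"mean"` (default) or `"median"`.
#' @return A `macs_result` data frame with per-dataset score columns, the
#'   aggregated `score`, `rank` (by decreasing score) and `retained`.
#' @export
macs_scores <- function(rankings, aggregation = c("mean", "median")) {
  aggregation <- match.arg(aggregation)
  if (inherits(rankings, "macs_result")) rankings <- list(rankings)
  if (length(rankings) == 0L) stop("no rankings supplied")
  shared <- Reduce(intersect, lapply(rankings, function(r) r$target))
  if (length(shared) == 0L) stop("rankings share no candidate targets")
  dropped <- unique(unlist(lapply(rankings,
                                  function(r) setdiff(r$target, shared))))
  if (length(dropped)) {
    message("targets absent from some datasets dropped: ",
            paste(dropped, collapse = ", "))
  }
  per_ds <- vapply(rankings, function(r) {
    setNames(r$score, r$target)[shared]
  }, numeric(length(shared)))
  per_ds <- matrix(per_ds, nrow = length(shared),
                   dimnames = list(shared, paste0("score_", seq_along(rankings))))
  agg <- apply(per_ds, 1L, if (aggregation == "mean") mean else median)
  D <- vapply(rankings, function(r) {
    setNames(r$relevance, r$target)[shared]
  }, numeric(length(shared)))
  D <- rowMeans(matrix(D, nrow = length(shared)))
  retained <- agg > mean(agg)
  if (!any(retained)) {
    warning("no target scores strictly above the average; nothing retained")
  }
  out <- data.frame(target = shared, score = agg, relevance = D,
                    retained = retained, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(per_ds))
  out <- out[order(-out$score, out$target), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("macs_result", "data.frame")
  out
}
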