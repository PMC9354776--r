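# Univariate testing, the VIP-and-p selection rule, direction annotation,
# and metabolite-metabolite correlation analysis.

#' Per-metabolite Welch two-sample t-test
#'
#' Two-sided Welch (unequal-variance) t-test of treated vs. control for
#' every metabolite.  When both groups are essentially constant the p-value
#' is 1 if the group means agree (no evidence of a difference) and ~0
#' otherwise, with a message.
#'
#' @param table A [metabolite_table].
#' @return Named numeric vector of p-values (one per metabolite).
#' @export
univariate_test <- function(table) {
  g <- table$groups
  x1 <- table$intensity[g == levels(g)[1L], , drop = FALSE]
  x2 <- table$intensity[g == levels(g)[2L], , drop = FALSE]
  p <- vapply(seq_len(ncol(x1)), function(j) {
    tryCatch(t.test(x2[, j], x1[, j])$p.value,
             error = function(e) {
               same <- isTRUE(all.equal(mean(x1[, j]), mean(x2[, j])))
               message("metabolite ", table$metabolite_ids[j],
                       " is essentially constant; p set to ",
                       if (same) 1 else 0, " by convention")
               if (same) 1 else 0
             })
  }, 0)
  names(p) <- table$metabolite_ids
  p
}

#' Select differential metabolites by the VIP-and-p rule
#'
#' A metabolite is retained iff `VIP > vip_threshold` AND
#' `p < p_threshold`, both inequalities strict.  Direction is `"up"` when
#' the treated-group mean exceeds the control mean.
#'
#' @param vip Named VIP vector (from [compute_vip()]).
#' @param pvals Named p-value vector (from [univariate_test()]); must cover
#'   the same metabolite set as `vip`.
#' @param table The [metabolite_table], used for group means.
#' @param vip_threshold,p_threshold Strict selection thresholds.
#'
#' @return Data frame with columns `metabolite`, `vip`, `p`, `direction`,
#'   `mean_control`, `mean_treated`, ordered by increasing p.
#' @export
select_differential <- function(vip, pvals, table, vip_threshold = 1,
                                p_threshold = 0.05) {
  diff_ids <- union(setdiff(names(vip), names(pvals)),
                    setdiff(names(pvals), names(vip)))
  if (length(diff_ids)) {
    stop("`vip` and `pvals` cover different metabolites: ",
         paste(diff_ids, collapse = ", "))
  }
  ids <- names(vip)
  g <- table$groups
  m_ctrl <- colMeans(table$intensity[g == levels(g)[1L], ids, drop = FALSE])
  m_trt <- colMeans(table$intensity[g == levels(g)[2L], ids, drop = FALSE])
  keep <- vip > vip_threshold & pvals[ids] < p_threshold
  out <- data.frame(
    metabolite = ids[keep],
    vip = unname(vip[keep]),
    p = unname(pvals[ids][keep]),
    direction = ifelse(m_trt[keep] > m_ctrl[keep], "up", "down"),
    mean_control = unname(m_ctrl[keep]),
    mean_treated = unname(m_trt[keep]),
    stringsAsFactors = FALSE
  )
  out[order(out$p), , drop = FALSE]
}

#' Pearson correlation matrix among a metabolite subset
#'
#' @param table A [metabolite_table].
#' @param metabolites Character vector of metabolite ids (>= 2).
#' @return A list with symmetric matrices `r` and `p` (two-sided t-based
#'   p-values; unit diagonal in `r`).  Constant metabolites get `NA`
#'   rows/columns, with a message.
#' @export
metabolite_correlation <- function(table, metabolites = table$metabolite_ids) {
  if (length(metabolites) < 2L) stop("need at least 2 metabolites")
  missing <- setdiff(metabolites, table$metabolite_ids)
  if (length(missing)) {
    stop("unknown metabolites: ", paste(missing, collapse = ", "))
  }
  X <- table$intensity[, metabolites, drop = FALSE]
  n <- nrow(X)
  sds <- apply(X, 2L, sd)
  const <- sds < .Machine$double.eps * 100
  if (any(const)) {
    message("constant metabolite(s) reported as NA: ",
            paste(metabolites[const], collapse = ", "))
  }
  r <- suppressWarnings(cor(X))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r)[!const] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  p[is.na(r)] <- NA_real_
  list(r = r, p = p, n = n)
}
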