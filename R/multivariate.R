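# Chemometric latent-variable models of the two-group metabolite table:
# PCA, NIPALS PLS-DA, Trygg-Wold OPLS-DA, VIP, S-plot, cross-validated Q2
# and label-permutation validation.

# ---- scaling --------------------------------------------------------------

# Center (always) and scale a matrix.  "uv" = unit variance (autoscaling,
# the SIMCA default for this workflow), "pareto" = sqrt(sd), "center" = no
# variance scaling.
scale_matrix <- function(X, scaling = c("uv", "center", "pareto")) {
  scaling <- match.arg(scaling)
  ctr <- colMeans(X)
  sds <- apply(X, 2L, sd)
  scl <- switch(scaling,
                uv = sds,
                pareto = sqrt(sds),
                center = rep(1, ncol(X)))
  if (scaling != "center" && any(sds < .Machine$double.eps * 100)) {
    bad <- colnames(X)[sds < .Machine$double.eps * 100]
    stop("constant column(s) cannot be ", scaling, "-scaled: ",
         paste(bad, collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  list(X = Xs, center = ctr, scale = scl, scaling = scaling)
}

apply_scaling <- function(X, sc) {
  sweep(sweep(X, 2L, sc$center, "-"), 2L, sc$scale, "/")
}

# fix component sign so the largest-|.| loading entry is positive
fix_sign <- function(loading) {
  i <- which.max(abs(loading))
  if (loading[i] < 0) -1 else 1
}

# y coded -1 for the alphabetically first group level, +1 for the second
encode_y <- function(groups) {
  y <- ifelse(as.integer(groups) == 1L, -1, 1)
  y - mean(y)
}

new_latent_model <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat("<latent_model ", x$kind, "> ", ncol(x$scores), " component(s)",
      if (!is.null(x$ortho_scores) && ncol(x$ortho_scores) > 0)
        paste0(" + ", ncol(x$ortho_scores), " orthogonal"),
      "; R2X=", round(sum(x$R2X), 3),
      if (!is.null(x$R2Y)) paste0(", R2Y=", round(x$R2Y, 3)),
      if (!is.null(x$Q2)) paste0(", Q2=", round(x$Q2, 3)),
      "\n", sep = "")
  invisible(x)
}

# ---- PCA ------------------------------------------------------------------

#' Principal component analysis of a metabolite table
#'
#' Components are the leading singular directions of the centered (and
#' optionally scaled) intensity matrix.  Each component's sign is fixed so
#' that its largest-magnitude loading entry is positive.
#'
#' @param table A [metabolite_table].
#' @param n_components Number of components
#'   (<= min(samples - 1, metabolites)).
#' @param scaling `"uv"` (autoscaling, default), `"center"` or `"pareto"`.
#'
#' @return A `latent_model` with `scores`, `loadings`, per-component
#'   explained variance (`var_explained`) and `R2X` fractions.
#' @export
fit_pca <- function(table, n_components = 2L,
                    scaling = c("uv", "center", "pareto")) {
  X <- table$intensity
  a_max <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1L || n_components > a_max) {
    stop("`n_components` must lie in [1, ", a_max, "]")
  }
  sc <- scale_matrix(X, scaling)
  sv <- svd(sc$X, nu = n_components, nv = n_components)
  signs <- vapply(seq_len(n_components), function(a) fix_sign(sv$v[, a]), 0)
  scores <- sweep(sv$u, 2L, sv$d[seq_len(n_components)] * signs, "*")
  loadings <- sweep(sv$v, 2L, signs, "*")
  dimnames(scores) <- list(table$sample_ids,
                           paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(table$metabolite_ids, colnames(scores))
  ve <- sv$d[seq_len(n_components)]^2 / (nrow(X) - 1L)
  total_var <- sum(sc$X^2) / (nrow(X) - 1L)
  new_latent_model("PCA", scores = scores, loadings = loadings,
                   var_explained = ve, R2X = ve / total_var,
                   total_variance = total_var, scaling = sc)
}

# ---- PLS-DA ---------------------------------------------------------------

# NIPALS PLS1 on a pre-scaled X and centered y; returns weights W, scores
# T, x-loadings P, y-loadings c, all sign-fixed.
nipals_pls1 <- function(Xs, y, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); cvec <- numeric(ncomp)
  Xd <- Xs
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10 || sum(Xd^2) < 1e-10) {
      stop("`n_components` exceeds the informative rank of X (component ",
           a, ")")
    }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pvec <- drop(crossprod(Xd, t)) / tt
    s <- fix_sign(pvec)
    w <- w * s; t <- t * s; pvec <- pvec * s
    W[, a] <- w; Tm[, a] <- t; P[, a] <- pvec
    cvec[a] <- sum(t * y) / tt
    Xd <- Xd - tcrossprod(t, pvec)
  }
  list(W = W, T = Tm, P = P, c = cvec)
}

# regression coefficients (scaled-X space) of a NIPALS PLS1 fit
pls1_coef <- function(fit) {
  A <- ncol(fit$W)
  drop(fit$W %*% solve(crossprod(fit$P, fit$W), fit$c[seq_len(A)]))
}

#' Partial least-squares discriminant analysis (NIPALS PLS1)
#'
#' The two-level group factor is coded -1/+1 (alphabetical order of labels)
#' and centered; components are extracted by NIPALS with X-deflation.
#'
#' @param table A [metabolite_table].
#' @param n_components Number of latent components (>= 1).
#' @param scaling Column scaling, as in [fit_pca()].
#' @param cv_folds Folds for the cross-validated Q2 (stratified; reduced
#'   with a warning when a group is smaller than the fold count).
#' @param cv_seed Seed for the fold assignment.
#'
#' @return A `latent_model` with `weights`, `scores`, `loadings`,
#'   `y_loadings`, `R2X`, `R2Y` and `Q2`.
#' @export
fit_plsda <- function(table, n_components = 2L,
                      scaling = c("uv", "center", "pareto"),
                      cv_folds = 7L, cv_seed = 1L) {
  if (n_components < 1L) stop("`n_components` must be at least 1")
  sc <- scale_matrix(table$intensity, scaling)
  y <- encode_y(table$groups)
  fit <- nipals_pls1(sc$X, y, n_components)
  yhat <- drop(fit$T %*% fit$c)
  R2Y <- 1 - sum((y - yhat)^2) / sum(y^2)
  ssx <- sum(sc$X^2)
  R2X <- vapply(seq_len(n_components), function(a) {
    sum(fit$T[, a]^2) * sum(fit$P[, a]^2) / ssx
  }, 0)
  dimnames(fit$T) <- list(table$sample_ids, paste0("t", seq_len(n_components)))
  dimnames(fit$W) <- list(table$metabolite_ids, colnames(fit$T))
  dimnames(fit$P) <- dimnames(fit$W)
  ssy_comp <- fit$c^2 * colSums(fit$T^2)
  Q2 <- cv_q2(table, n_components, scaling = sc$scaling, folds = cv_folds,
              seed = cv_seed, n_orthogonal = NA)
  new_latent_model("PLS-DA", scores = fit$T, loadings = fit$P,
                   weights = fit$W, y_loadings = fit$c, y = y,
                   R2X = R2X, R2Y = R2Y, Q2 = Q2, ssy_comp = ssy_comp,
                   scaling = sc, groups = levels(table$groups))
}

# ---- OPLS-DA --------------------------------------------------------------

#' Orthogonal PLS discriminant analysis (single response)
#'
#' Trygg-Wold O-PLS: `n_orthogonal` y-orthogonal components are extracted
#' and removed from X, then a single predictive component is fitted on the
#' filtered matrix.  Orthogonal score vectors are exactly uncorrelated with
#' the (centered) class vector by construction.
#'
#' @param table A [metabolite_table].
#' @param n_orthogonal Number of orthogonal components (>= 0); 0 reduces the
#'   model to a one-component PLS-DA.
#' @param scaling Column scaling, as in [fit_pca()].
#' @param cv_folds,cv_seed Cross-validation controls for Q2, as in
#'   [fit_plsda()].
#'
#' @return A `latent_model` with predictive `scores`/`loadings`/`weights`
#'   plus `ortho_scores`, `ortho_loadings`, `ortho_weights`.
#' @export
fit_oplsda <- function(table, n_orthogonal = 1L,
                       scaling = c("uv", "center", "pareto"),
                       cv_folds = 7L, cv_seed = 1L) {
  if (n_orthogonal < 0L) stop("`n_orthogonal` must be non-negative")
  sc <- scale_matrix(table$intensity, scaling)
  y <- encode_y(table$groups)
  fit <- opls_core(sc$X, y, n_orthogonal)
  yhat <- fit$t * fit$c
  R2Y <- 1 - sum((y - yhat)^2) / sum(y^2)
  ssx <- sum(sc$X^2)
  scores <- matrix(fit$t, dimnames = list(table$sample_ids, "t1"))
  loadings <- matrix(fit$p, dimnames = list(table$metabolite_ids, "t1"))
  weights <- matrix(fit$w, dimnames = list(table$metabolite_ids, "t1"))
  if (n_orthogonal > 0L) {
    dimnames(fit$To) <- list(table$sample_ids,
                             paste0("to", seq_len(n_orthogonal)))
    dimnames(fit$Po) <- list(table$metabolite_ids, colnames(fit$To))
    dimnames(fit$Wo) <- dimnames(fit$Po)
  }
  Q2 <- cv_q2(table, 1L, scaling = sc$scaling, folds = cv_folds,
              seed = cv_seed, n_orthogonal = n_orthogonal)
  new_latent_model("OPLS-DA", scores = scores, loadings = loadings,
                   weights = weights, y_loadings = fit$c, y = y,
                   R2X = sum(fit$t^2) * sum(fit$p^2) / ssx, R2Y = R2Y,
                   Q2 = Q2, ssy_comp = fit$c^2 * sum(fit$t^2),
                   ortho_scores = fit$To, ortho_loadings = fit$Po,
                   ortho_weights = fit$Wo, n_orthogonal = n_orthogonal,
                   scaling = sc, groups = levels(table$groups))
}

opls_core <- function(Xs, y, n_ortho) {
  p <- ncol(Xs)
  w <- drop(crossprod(Xs, y))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("y carries no covariance with X; OPLS undefined")
  w <- w / nw
  To <- matrix(0, nrow(Xs), n_ortho)
  Po <- matrix(0, p, n_ortho); Wo <- matrix(0, p, n_ortho)
  Xd <- Xs
  if (n_ortho > 0L) for (a in seq_len(n_ortho)) {
    t <- drop(Xd %*% w)
    pv <- drop(crossprod(Xd, t)) / sum(t^2)
    wo <- pv - drop(crossprod(w, pv)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) {
      stop("`n_orthogonal` exceeds the y-orthogonal rank of X (component ",
           a, ")")
    }
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    s <- fix_sign(po)
    wo <- wo * s; to <- to * s; po <- po * s
    Wo[, a] <- wo; To[, a] <- to; Po[, a] <- po
    Xd <- Xd - tcrossprod(to, po)
  }
  t <- drop(Xd %*% w)
  pv <- drop(crossprod(Xd, t)) / sum(t^2)
  s <- fix_sign(pv)
  w <- w * s; t <- t * s; pv <- pv * s
  cc <- sum(t * y) / sum(t^2)
  list(w = w, t = t, p = pv, c = cc,
       To = if (n_ortho > 0L) To else NULL,
       Po = if (n_ortho > 0L) Po else NULL,
       Wo = if (n_ortho > 0L) Wo else NULL)
}

# predict centered-y for new (unscaled) X rows from a train-side fit
opls_predict <- function(Xnew_s, w, Wo, Po, cc) {
  if (!is.null(Wo)) {
    for (a in seq_len(ncol(Wo))) {
      to <- drop(Xnew_s %*% Wo[, a])
      Xnew_s <- Xnew_s - tcrossprod(to, Po[, a])
    }
  }
  drop(Xnew_s %*% w) * cc
}

# ---- cross-validated Q2 ---------------------------------------------------

# stratified fold ids: within each class, shuffled then dealt round-robin
stratified_folds <- function(groups, folds, seed) {
  set.seed(seed)
  ids <- integer(length(groups))
  for (g in levels(groups)) {
    idx <- sample(which(groups == g))
    ids[idx] <- rep_len(seq_len(folds), length(idx))
  }
  ids
}

# Q2 = 1 - PRESS/SSY under stratified k-fold CV.  n_orthogonal = NA fits a
# plain PLS with `ncomp` components; otherwise an OPLS with one predictive
# and `n_orthogonal` orthogonal components.
cv_q2 <- function(table, ncomp, scaling, folds = 7L, seed = 1L,
                  n_orthogonal = NA) {
  groups <- table$groups
  min_g <- min(table(groups))
  if (min_g < folds) {
    warning("reducing cv folds from ", folds, " to ", min_g,
            " (smallest group size)")
    folds <- min_g
  }
  fold_id <- stratified_folds(groups, folds, seed)
  y_all <- encode_y(groups)
  X <- table$intensity
  press <- 0
  for (f in seq_len(folds)) {
    test <- fold_id == f
    sc <- scale_matrix(X[!test, , drop = FALSE], scaling)
    ytr <- y_all[!test]
    ytr_c <- ytr - mean(ytr)
    Xte <- apply_scaling(X[test, , drop = FALSE], sc)
    yhat <- if (is.na(n_orthogonal)) {
      fit <- nipals_pls1(sc$X, ytr_c, ncomp)
      drop(Xte %*% pls1_coef(fit)) + mean(ytr)
    } else {
      fit <- opls_core(sc$X, ytr_c, n_orthogonal)
      opls_predict(Xte, fit$w, fit$Wo, fit$Po, fit$c) + mean(ytr)
    }
    press <- press + sum((y_all[test] - yhat)^2)
  }
  1 - press / sum((y_all - mean(y_all))^2)
}

# ---- VIP ------------------------------------------------------------------

#' Variable importance in projection
#'
#' Standard VIP from the (normalized) component weights, weighted by the
#' per-component explained y-variance:
#' `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)`.  For OPLS-DA the
#' predictive component is used (orthogonal components explain no
#' y-variance).  `sum(VIP^2)` equals the number of metabolites by
#' construction.
#'
#' @param model A fitted PLS-DA or OPLS-DA `latent_model`.
#' @return Named numeric vector of VIP scores (one per metabolite).
#' @export
compute_vip <- function(model) {
  if (!inherits(model, "latent_model") || model$kind == "PCA") {
    stop("VIP is defined only for PLS-DA / OPLS-DA models")
  }
  W <- model$weights
  ssy <- model$ssy_comp
  p <- nrow(W)
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(W)
  vip
}

# ---- S-plot ---------------------------------------------------------------

#' S-plot statistics (covariance and correlation against predictive scores)
#'
#' @param model A PLS-DA or OPLS-DA `latent_model` with a predictive
#'   component.
#' @param table The [metabolite_table] the model was fitted on.
#' @return Data frame with columns `metabolite`, `covariance`,
#'   `correlation`.  Zero-variance metabolites get `NA` correlation.
#' @export
s_plot <- function(model, table) {
  if (!inherits(model, "latent_model") || model$kind == "PCA") {
    stop("the S-plot requires a PLS-DA / OPLS-DA model")
  }
  t1 <- model$scores[, 1L]
  Xs <- apply_scaling(table$intensity, model$scaling)
  covs <- drop(cov(t1, Xs))
  sds <- apply(Xs, 2L, sd)
  cors <- ifelse(sds < .Machine$double.eps * 100, NA_real_,
                 covs / (sd(t1) * sds))
  data.frame(metabolite = table$metabolite_ids, covariance = covs,
             correlation = cors, row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- permutation validation ----------------------------------------------

#' Label-permutation validation of a PLS-DA model
#'
#' Refits the model on permuted class labels (identity permutation
#' excluded) and declares the original model valid when every permuted R2Y
#' and Q2 falls strictly below the original values.
#'
#' @param table A [metabolite_table].
#' @param n_components Components of the PLS-DA model.
#' @param n_permutations Number of label permutations (>= 20).
#' @param cv_folds Folds for Q2 (stratified).
#' @param seed Seed controlling permutations and fold assignment.
#' @param scaling Column scaling, as in [fit_pca()].
#'
#' @return A list of class `permutation_validation`: `R2Y`, `Q2`,
#'   `perm_R2Y`, `perm_Q2`, `valid`, `correlations` (label-overlap of each
#'   permutation with the original labels).
#' @export
permutation_validate <- function(table, n_components = 2L,
                                 n_permutations = 100L, cv_folds = 7L,
                                 seed = 1L,
                                 scaling = c("uv", "center", "pareto")) {
  if (n_permutations < 20L) stop("`n_permutations` must be at least 20")
  scaling <- match.arg(scaling)
  orig <- fit_plsda(table, n_components, scaling = scaling,
                    cv_folds = cv_folds, cv_seed = seed)
  set.seed(seed)
  n <- length(table$groups)
  perm_R2Y <- numeric(n_permutations)
  perm_Q2 <- numeric(n_permutations)
  cors <- numeric(n_permutations)
  g0 <- table$groups
  for (b in seq_len(n_permutations)) {
    repeat {
      perm <- sample.int(n)
      if (!all(perm == seq_len(n)) && !all(g0[perm] == g0)) break
    }
    tb <- table
    tb$groups <- g0[perm]
    fit <- suppressWarnings(
      fit_plsda(tb, n_components, scaling = scaling, cv_folds = cv_folds,
                cv_seed = seed + b)
    )
    perm_R2Y[b] <- fit$R2Y
    perm_Q2[b] <- fit$Q2
    cors[b] <- mean(g0[perm] == g0)
  }
  structure(
    list(R2Y = orig$R2Y, Q2 = orig$Q2, perm_R2Y = perm_R2Y,
         perm_Q2 = perm_Q2,
         valid = all(perm_R2Y < orig$R2Y) && all(perm_Q2 < orig$Q2),
         correlations = cors, n_permutations = n_permutations),
    class = "permutation_validation"
  )
}

#' @export
print.permutation_validation <- function(x, ...) {
  cat("<permutation_validation> R2Y=", round(x$R2Y, 3), " Q2=",
      round(x$Q2, 3), "; ", x$n_permutations, " permutations; model ",
      if (x$valid) "VALID" else "NOT validated", "\n", sep = "")
  invisible(x)
}
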