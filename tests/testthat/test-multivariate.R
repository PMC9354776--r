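test_that("PCA matches prcomp and reproduces the rank-1 two-sample case", {
  g <- small_table()
  m <- fit_pca(g$table, 3)
  ref <- prcomp(g$table$intensity, center = TRUE, scale. = TRUE)
  for (a in 1:3) {
    # loadings agree up to sign
    expect_lt(min(sum((m$loadings[, a] - ref$rotation[, a])^2),
                  sum((m$loadings[, a] + ref$rotation[, a])^2)), 1e-16)
    expect_equal(m$var_explained[a], ref$sdev[a]^2, tolerance = 1e-10)
  }
  # explained variance non-increasing and bounded by the total
  expect_true(all(diff(m$var_explained) <= 1e-12))
  expect_lte(sum(m$var_explained), m$total_variance + 1e-10)

  # two samples: the single component is the between-sample difference
  X <- matrix(exp(rnorm(10)), nrow = 2)
  tab2 <- list(intensity = X, groups = factor(c("a", "b")),
               sample_ids = c("s1", "s2"), metabolite_ids = colnames(X))
  tab2$metabolite_ids <- paste0("m", 1:5)
  colnames(tab2$intensity) <- tab2$metabolite_ids
  class(tab2) <- "metabolite_table"
  m2 <- fit_pca(tab2, 1, scaling = "center")
  d <- X[2, ] - X[1, ]
  expect_equal(abs(cor(m2$loadings[, 1], d)), 1, tolerance = 1e-10)
})

test_that("PCA separates planted clusters on component 1", {
  g <- small_table(seed = 21, n_metabolites = 30, n_differential = 10,
                   effect = 4)
  m <- fit_pca(g$table, 2)
  s1 <- m$scores[g$table$groups == "control", 1]
  s2 <- m$scores[g$table$groups == "treated", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("PCA errors on constant columns under uv scaling, naming them", {
  X <- exp(matrix(rnorm(40), 8, 5))
  X[, 3] <- 2
  colnames(X) <- paste0("m", 1:5)
  tab <- metabolite_table(X, rep(c("a", "b"), each = 4))
  expect_error(fit_pca(tab, 2, scaling = "uv"), "m3")
  expect_silent({m <- fit_pca(tab, 2, scaling = "center")})
  expect_error(fit_pca(tab, 20), "n_components")
})

test_that("one-component PLS weights are proportional to X'y (closed form)", {
  g <- small_table(seed = 2)
  m <- suppressWarnings(fit_plsda(g$table, 1, cv_folds = 3))
  Xs <- scale(g$table$intensity)
  y <- ifelse(g$table$groups == levels(g$table$groups)[1], -1, 1)
  w_ref <- drop(crossprod(Xs, y - mean(y)))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_lt(min(sum((m$weights[, 1] - w_ref)^2),
                sum((m$weights[, 1] + w_ref)^2)), 1e-16)
})

test_that("a perfectly separating metabolite dominates PLS component 1", {
  set.seed(4)
  n <- 12
  groups <- rep(c("control", "treated"), each = n / 2)
  X <- matrix(rnorm(n * 20, sd = 1), n, 20)
  X[, 7] <- ifelse(groups == "treated", 3, -3) + rnorm(n, sd = 0.05)
  colnames(X) <- paste0("m", 1:20)
  tab <- table_from_matrix(X, groups)
  m <- suppressWarnings(fit_plsda(tab, 1, cv_folds = 3))
  expect_equal(which.max(abs(m$weights[, 1])), c(m7 = 7L))
})

test_that("duplicating all columns leaves PLS R2Y unchanged", {
  g <- small_table(seed = 5, n_metabolites = 20)
  m1 <- suppressWarnings(fit_plsda(g$table, 2, cv_folds = 3))
  X2 <- cbind(g$table$intensity,
              `colnames<-`(g$table$intensity,
                           paste0(colnames(g$table$intensity), "_dup")))
  tab2 <- metabolite_table(X2, g$table$groups)
  m2 <- suppressWarnings(fit_plsda(tab2, 2, cv_folds = 3))
  expect_equal(m1$R2Y, m2$R2Y, tolerance = 1e-10)
})

test_that("OPLS-DA with zero orthogonal components equals one-component PLS-DA", {
  g <- small_table(seed = 6)
  pls <- suppressWarnings(fit_plsda(g$table, 1, cv_folds = 3))
  opls <- suppressWarnings(fit_oplsda(g$table, 0, cv_folds = 3))
  expect_equal(unname(opls$scores[, 1]), unname(pls$scores[, 1]),
               tolerance = 1e-10)
  expect_equal(unname(opls$loadings[, 1]), unname(pls$loadings[, 1]),
               tolerance = 1e-10)
  expect_equal(opls$R2Y, pls$R2Y, tolerance = 1e-10)
})

test_that("OPLS orthogonal scores are uncorrelated with y on every fit", {
  for (seed in 1:5) {
    g <- small_table(seed = seed, n_metabolites = 25)
    m <- suppressWarnings(fit_oplsda(g$table, 2, cv_folds = 3))
    for (a in seq_len(ncol(m$ortho_scores))) {
      expect_lt(abs(cor(m$ortho_scores[, a], m$y)), 1e-8)
    }
  }
})

test_that("OPLS removes a planted y-orthogonal component exactly", {
  # clean rank-1 predictive structure: X = y w' (plus a baseline to keep
  # intensities positive); augmented with one y-orthogonal rank-1 term
  set.seed(8)
  n <- 12; p <- 15
  groups <- rep(c("control", "treated"), each = n / 2)
  y <- ifelse(groups == "treated", 1, -1)
  w <- rnorm(p); w <- w / sqrt(sum(w^2))
  X_clean <- outer(y, w)
  t_add <- rnorm(n); t_add <- t_add - y * sum(t_add * y) / sum(y^2)
  t_add <- t_add - mean(t_add)
  q <- rnorm(p)
  X_aug <- X_clean + outer(t_add, q)
  expect_lt(abs(sum(t_add * y)), 1e-10)
  y_c <- y - mean(y)
  fit_lin <- function(X, n_ortho) {
    metamacs:::opls_core(scale(X, scale = FALSE), y_c, n_ortho)
  }
  f_clean <- fit_lin(X_clean, 0)
  f_aug <- fit_lin(X_aug, 1)
  expect_equal(f_aug$w, f_clean$w, tolerance = 1e-8)
  expect_equal(f_aug$p, f_clean$p, tolerance = 1e-6)
  expect_equal(f_aug$t, f_clean$t, tolerance = 1e-6)
})

test_that("VIP obeys its closed forms and normalization", {
  # two metabolites, one-component model with weights (1, 0) -> (sqrt2, 0):
  # m1 is the class vector, m2 is made exactly orthogonal to it
  set.seed(10)
  n <- 10
  groups <- rep(c("a", "b"), each = n / 2)
  y <- ifelse(groups == "b", 1, -1)
  m2 <- rnorm(n)
  m2 <- m2 - mean(m2)
  m2 <- m2 - y * sum(m2 * y) / sum(y^2)
  tab <- list(intensity = cbind(m1 = y + 10, m2 = m2 + 10),
              groups = factor(groups), sample_ids = paste0("s", 1:n),
              metabolite_ids = c("m1", "m2"))
  class(tab) <- "metabolite_table"
  m <- suppressWarnings(fit_plsda(tab, 1, cv_folds = 3))
  v <- compute_vip(m)
  expect_equal(unname(v["m1"]), sqrt(2), tolerance = 1e-8)
  expect_lt(v["m2"], 1e-8)
  # sum VIP^2 = p and mean(VIP^2) = 1 on a generic fit
  g <- small_table(seed = 11)
  mm <- suppressWarnings(fit_plsda(g$table, 2, cv_folds = 3))
  vv <- compute_vip(mm)
  expect_equal(sum(vv^2), length(vv), tolerance = 1e-6)
  expect_equal(mean(vv^2), 1, tolerance = 1e-6)
  # VIP undefined for PCA
  expect_error(compute_vip(fit_pca(g$table, 2)), "PCA|PLS")
})

test_that("S-plot covariances/correlations behave as defined", {
  g <- small_table(seed = 12, n_metabolites = 30, n_differential = 5,
                   effect = 4)
  m <- suppressWarnings(fit_oplsda(g$table, 1, cv_folds = 3))
  sp <- s_plot(m, g$table)
  expect_true(all(abs(sp$correlation) <= 1 + 1e-12, na.rm = TRUE))
  # planted metabolites occupy the extreme |corr| ranks
  top <- sp$metabolite[order(-abs(sp$correlation))][1:5]
  expect_gte(length(intersect(top, g$truth$differential_metabolites)), 4)
  # a metabolite equal to the score vector correlates at 1
  Xs <- metamacs:::apply_scaling(g$table$intensity, m$scaling)
  j <- which.max(abs(sp$correlation))
  expect_equal(abs(cor(m$scores[, 1], Xs[, j])),
               abs(sp$correlation[j]), tolerance = 1e-10)
})

test_that("permutation validation flags a strong planted effect as valid", {
  g <- small_table(seed = 13, n_metabolites = 30, n_differential = 6,
                   effect = 3)
  pv <- suppressWarnings(
    permutation_validate(g$table, 2, n_permutations = 30, cv_folds = 5,
                         seed = 1))
  expect_true(pv$valid)
  expect_true(all(pv$perm_R2Y < pv$R2Y))
  expect_true(all(pv$perm_Q2 < pv$Q2))
  # permuted label vectors never equal the originals
  expect_true(all(pv$correlations < 1))
  expect_error(permutation_validate(g$table, 2, n_permutations = 5),
               "n_permutations")
})

test_that("fold counts shrink with a warning when groups are small", {
  g <- small_table(seed = 14, n_per_group = 4)
  expect_warning(fit_plsda(g$table, 1, cv_folds = 7), "reducing cv folds")
})
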