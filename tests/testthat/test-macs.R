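test_that("MI estimator matches closed forms, independence, and contracts", {
  set.seed(61)
  n <- 5000
  x <- rnorm(n)
  # independence: estimate clipped near 0
  expect_lte(estimate_mi(x, rnorm(n)), 0.05)
  # bivariate Gaussian closed form -0.5*log(1-rho^2)
  rho <- 0.8
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_lt(abs(estimate_mi(x, y) - (-0.5 * log(1 - rho^2))), 0.08)
  # discrete identity: plug-in MI equals ln 4 exactly on balanced levels
  v <- sample(rep(1:4, 25))
  expect_equal(estimate_mi(v, v, mi_config("histogram")), log(4),
               tolerance = 1e-12)
  # contracts
  expect_error(estimate_mi(1:30, 1:29), "equal length")
  expect_error(estimate_mi(1:10, 1:10), "at least 20")
  expect_error(estimate_mi(c(1:29, NA), 1:30), "finite")
})

test_that("MI estimates are symmetric and shift-invariant", {
  set.seed(62)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  for (cfg in list(mi_config("knn"), mi_config("histogram"))) {
    expect_lt(abs(estimate_mi(x, y, cfg) - estimate_mi(y, x, cfg)), 1e-10)
    expect_equal(estimate_mi(x + 100, y - 7, cfg), estimate_mi(x, y, cfg),
                 tolerance = 1e-12)
  }
})

test_that("knn MI recovers the Gaussian closed form across rho (averaged seeds)", {
  for (rho in c(0.3, 0.6, 0.9)) {
    est <- vapply(1:5, function(s) {
      set.seed(s)
      x <- rnorm(2000)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(2000)
      estimate_mi(x, y)
    }, 0)
    expect_lt(abs(mean(est) - (-0.5 * log(1 - rho^2))), 0.05)
  }
})

test_that("pathway activity tracks the latent factor and flags degeneracy", {
  fx <- macs_fixture(seed = 63)
  f_tumor <- fx$truth$factor[fx$dataset$condition == "tumor"]
  for (a in fx$activities) {
    expect_equal(mean(a$activity), 0, tolerance = 1e-10)
    expect_equal(sd(a$activity), 1, tolerance = 1e-10)
    expect_gt(cor(a$activity, f_tumor), 0.9)
  }
  # single-gene pathway: activity is that gene z-scored
  a1 <- pathway_activity(fx$dataset, fx$metabolic_genes[1], subset = "all")
  expect_equal(as.numeric(a1$activity),
               as.numeric(scale(fx$dataset$expr[, fx$metabolic_genes[1]])),
               tolerance = 1e-12)
  # cancellation: a gene and its negation average to nothing
  X <- cbind(a = rnorm(50), b = 0)
  X[, "b"] <- -X[, "a"]
  ds <- expression_dataset(X + 10, rep("tumor", 50), "deg",
                           sample_ids = paste0("s", 1:50))
  expect_error(pathway_activity(ds, c("a", "b")), "degenerate")
  expect_error(pathway_activity(ds, "zz"), "no constituent gene")
})

test_that("relevance averages MI over core pathways", {
  fx <- macs_fixture(seed = 64)
  cfg <- mi_config()
  x <- fx$tumor_expr[, 1]
  direct <- mean(vapply(fx$activities,
                        function(a) estimate_mi(x, a$activity, cfg), 0))
  expect_equal(relevance(x, fx$activities, cfg), direct, tolerance = 1e-12)
  # the activity vector itself has maximal relevance
  a1 <- fx$activities[[1]]
  expect_gt(relevance(a1$activity, fx$activities, cfg),
            relevance(x, fx$activities, cfg))
  expect_error(relevance(x, list(), cfg), "no core pathways")
})

test_that("greedy ranking defers a duplicated informative gene", {
  set.seed(65)
  n <- 100
  f <- rnorm(n)
  act <- structure(list(pathway = "P1", activity = drop(scale(f)),
                        genes = "g", n = n), class = "pathway_activity")
  g1 <- 0.9 * f + sqrt(1 - 0.81) * rnorm(n)
  X <- cbind(g1 = g1,
             g2 = g1,                               # exact duplicate
             g3 = 0.4 * f + sqrt(1 - 0.16) * rnorm(n))  # weakly informative
  rk <- suppressMessages(greedy_mrmr_rank(X, list(act)))
  expect_identical(rk$target, c("g1", "g3", "g2"))
  # duplicate's redundancy at selection reflects its MI with g1
  expect_gt(rk$redundancy[rk$target == "g2"],
            rk$relevance[rk$target == "g2"] * 0.5)
})

test_that("mutually independent candidates rank by descending relevance", {
  set.seed(66)
  n <- 150
  f <- rnorm(n)
  act <- structure(list(pathway = "P1", activity = drop(scale(f)),
                        genes = "g", n = n), class = "pathway_activity")
  couplings <- c(a = 0.9, b = 0.7, c = 0.45, d = 0)
  X <- sapply(couplings, function(r) r * f + sqrt(1 - r^2) * rnorm(n))
  rk <- greedy_mrmr_rank(X, list(act))
  expect_identical(rk$target[1:3], c("a", "b", "c"))
  expect_true(all(diff(rk$relevance[1:3]) < 0))
  expect_error(greedy_mrmr_rank(X[, 1, drop = FALSE], list(act)),
               "at least 2")
})

test_that("every greedy step equals the exhaustive oracle argmax", {
  for (s in 1:6) {
    set.seed(100 + s)
    n <- 60
    m <- sample(5:8, 1)
    f1 <- rnorm(n); f2 <- rnorm(n)
    acts <- list(
      structure(list(pathway = "P1", activity = drop(scale(f1)),
                     genes = "x", n = n), class = "pathway_activity"),
      structure(list(pathway = "P2", activity = drop(scale(f2)),
                     genes = "y", n = n), class = "pathway_activity"))
    X <- sapply(seq_len(m), function(j) {
      r <- runif(1, 0, 0.9)
      w <- runif(1)
      r * (w * f1 + (1 - w) * f2) / sqrt(w^2 + (1 - w)^2) +
        sqrt(1 - r^2) * rnorm(n)
    })
    colnames(X) <- sprintf("g%02d", seq_len(m))
    cfg <- mi_config()
    rk <- suppressMessages(greedy_mrmr_rank(X, acts, cfg))
    expect_identical(rk$target, oracle_mrmr_order(X, acts, cfg))
  }
})

test_that("score aggregation and above-average retention follow the strict rule", {
  mk <- function(targets, scores, D = scores) {
    structure(data.frame(target = targets, rank = seq_along(targets),
                         relevance = D, redundancy = 0, score = scores),
              class = c("macs_result", "data.frame"))
  }
  # scores {3,1,2}: mean 2, only the 3 retained
  out <- macs_scores(mk(c("a", "b", "c"), c(3, 1, 2)))
  expect_identical(out$target[out$retained], "a")
  # all equal: nothing retained, warning
  expect_warning(out2 <- macs_scores(mk(c("a", "b"), c(1, 1))),
                 "nothing retained")
  expect_false(any(out2$retained))
  # single dataset: aggregated equals per-dataset scores
  one <- macs_scores(mk(c("a", "b", "c"), c(0.5, 0.1, 0.3)))
  expect_equal(setNames(one$score, one$target)[c("a", "b", "c")],
               c(a = 0.5, b = 0.1, c = 0.3))
  # two datasets aggregate by mean on the shared set
  two <- suppressMessages(suppressWarnings(
    macs_scores(list(mk(c("a", "b", "c"), c(1, 0, 0.5)),
                     mk(c("a", "b"), c(0.2, 0.6))))))
  expect_setequal(two$target, c("a", "b"))
  expect_equal(two$score[two$target == "a"], 0.6)
  expect_equal(two$score[two$target == "b"], 0.3)
  expect_error(macs_scores(list(mk("a", 1), mk("b", 1))), "share no")
})

test_that("planted informative targets are ranked first and retained", {
  fx <- macs_fixture(seed = 67)
  rk <- suppressMessages(greedy_mrmr_rank(fx$tumor_expr, fx$activities))
  expect_setequal(rk$target[1:5], fx$truth$informative_targets)
  sc <- macs_scores(rk)
  expect_true(all(fx$truth$informative_targets %in%
                    sc$target[sc$retained]))
  # ranks are a permutation and D, R are non-negative
  expect_setequal(rk$rank, seq_len(ncol(fx$tumor_expr)))
  expect_true(all(rk$relevance >= 0 & rk$redundancy >= 0))
})
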