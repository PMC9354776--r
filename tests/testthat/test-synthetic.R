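test_that("metabolite generator plants the requested shifts and is deterministic", {
  g <- generate_metabolite_table(6, 200, 10, effect_size = 2, seed = 7)
  expect_equal(dim(g$table$intensity), c(12L, 200L))
  expect_length(g$truth$differential_metabolites, 10L)
  expect_true(all(g$truth$differential_metabolites %in%
                    g$table$metabolite_ids))
  # alternating shift signs: both directions present
  expect_setequal(unique(g$truth$directions), c("up", "down"))
  g2 <- generate_metabolite_table(6, 200, 10, effect_size = 2, seed = 7)
  expect_identical(g$table$intensity, g2$table$intensity)
  expect_identical(g$truth, g2$truth)
  # a different seed gives different data
  g3 <- generate_metabolite_table(6, 200, 10, effect_size = 2, seed = 8)
  expect_false(identical(g$table$intensity, g3$table$intensity))
})

test_that("null metabolite generator draws both groups from one distribution", {
  g <- generate_metabolite_table(50, 60, 0, seed = 11)
  expect_length(g$truth$differential_metabolites, 0L)
  p <- univariate_test(g$table)
  # p-values approximately uniform: about 5% below 0.05
  expect_lt(mean(p < 0.05), 0.12)
  expect_gt(mean(p < 0.5), 0.35)
})

test_that("metabolite generator rejects bad arguments", {
  expect_error(generate_metabolite_table(2, 10, 0), "n_per_group")
  expect_error(generate_metabolite_table(4, 0, 0), "n_metabolites")
  expect_error(generate_metabolite_table(4, 10, 11), "n_differential")
})

test_that("pathway db covers the universe, plants cores, and is deterministic", {
  met <- sprintf("M%03d", 1:120)
  diff <- sprintf("M%03d", seq(5, 50, by = 5))
  db <- generate_pathway_db(10, c(4, 10), 3, met, diff, seed = 3)
  expect_length(db$pathways, 10L)
  # every metabolite annotated to at least one gene
  expect_true(all(met %in% db$annotation$metabolite))
  # planted core pathways hold at least half of the differential metabolites
  core_members <- unique(unlist(lapply(
    db$pathways[1:3], function(p) p$members)))
  expect_gte(length(intersect(diff, core_members)), length(diff) / 2)
  # each pathway graph is connected and references members only
  for (pw in db$pathways) {
    g <- igraph::graph_from_data_frame(
      as.data.frame(pw$edges), directed = FALSE,
      vertices = data.frame(name = pw$members))
    expect_true(igraph::is_connected(g))
  }
  db2 <- generate_pathway_db(10, c(4, 10), 3, met, diff, seed = 3)
  expect_identical(db$annotation, db2$annotation)
  expect_identical(db$pathways, db2$pathways)
})

test_that("minimal pathway db: one 3-member pathway has a connected graph", {
  db <- generate_pathway_db(1, c(3, 3), 0, sprintf("M%02d", 1:10), seed = 1)
  pw <- db$pathways[[1]]
  expect_length(pw$members, 3L)
  expect_gte(nrow(pw$edges), 2L)
  expect_error(generate_pathway_db(1, c(1, 3), 0, sprintf("M%02d", 1:10)),
               "lower bound")
  expect_error(generate_pathway_db(2, c(3, 3), 3, sprintf("M%02d", 1:10)),
               "n_core_planted")
})

test_that("expression generator couples informative targets to the latent factor", {
  mg <- sprintf("MG%02d", 1:10)
  tg <- sprintf("TGT%02d", 1:20)
  gen <- generate_expression_dataset(200, 0, mg, tg, 5, coupling = 0.9,
                                     seed = 5)
  expect_length(gen$truth$informative_targets, 5L)
  r <- vapply(gen$truth$informative_targets, function(g) {
    cor(gen$dataset$expr[, g], gen$truth$factor)
  }, 0)
  expect_true(all(abs(r - 0.9) < 0.1))
  # identical seed, identical matrices
  gen2 <- generate_expression_dataset(200, 0, mg, tg, 5, coupling = 0.9,
                                      seed = 5)
  expect_identical(gen$dataset$expr, gen2$dataset$expr)
})

test_that("zero coupling makes informative and noise targets indistinguishable", {
  mg <- sprintf("MG%02d", 1:10)
  tg <- sprintf("TGT%02d", 1:20)
  gen <- generate_expression_dataset(150, 0, mg, tg, 5, coupling = 0,
                                     seed = 9)
  r <- abs(cor(gen$dataset$expr[, tg], gen$truth$factor))
  # all target-factor correlations are sampling noise around 0
  expect_lt(max(r), 4 / sqrt(150))
  expect_error(
    generate_expression_dataset(100, 0, character(), tg, 2),
    "non-empty")
  expect_error(
    generate_expression_dataset(100, 0, mg, tg, 21),
    "n_informative_targets")
})
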