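test_that("toy ground truth matches its closed forms", {
  gt <- generate_toy_model(toy_model_spec(uptake_capacity = 10,
                                          biomass_yield = 0.1))$ground_truth
  expect_equal(gt$max_growth, 1.0)
  gt2 <- generate_toy_model(toy_model_spec(product_capacity = 2))$ground_truth
  expect_equal(gt2$max_product, 2)   # supply-capped, at zero growth
  # carbon-capped regime: huge capacity, three precursors at 1 each
  gt3 <- generate_toy_model(toy_model_spec(product_capacity = 100))$ground_truth
  expect_equal(gt3$max_product, 10 / 3)
  expect_error(toy_model_spec(uptake_capacity = 0),
               class = "fluxscape_spec_error")
  expect_error(toy_model_spec(biomass_yield = -1),
               class = "fluxscape_spec_error")
})

test_that("generated models validate, solve, and match ground truth optima", {
  for (seed in 1:8) {
    toy <- generate_toy_model(random_toy_spec(seed))
    expect_s3_class(validate_model(toy$model), "metabolic_model")
    mu <- fba(toy$model, toy$ground_truth$biomass_id)
    qp <- fba(toy$model, toy$ground_truth$product_id)
    expect_equal(mu$status, "optimal")
    expect_equal(mu$objective_value, toy$ground_truth$max_growth,
                 tolerance = 1e-8)
    expect_equal(qp$objective_value, toy$ground_truth$max_product,
                 tolerance = 1e-8)
  }
})

test_that("the same seed reproduces byte-identical model files", {
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_model(generate_toy_model(toy_model_spec(seed = 42))$model, f1)
  write_model(generate_toy_model(toy_model_spec(seed = 42))$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed relabels genes
  m1 <- generate_toy_model(toy_model_spec(seed = 1))$model
  m2 <- generate_toy_model(toy_model_spec(seed = 2))$model
  expect_false(identical(m1$genes, m2$genes))
})

test_that("noise-free expression separates planted active genes exactly", {
  toy <- generate_toy_model(toy_model_spec())
  genes <- c(toy$model$genes, sprintf("bg%03d", 1:60))
  active <- toy$ground_truth$genes_product_mode
  expr <- generate_expression(genes, active, noise_sd = 0, seed = 5)
  th <- compute_thresholds(expr)
  for (tp in c("T1", "T2", "T3", "T4")) {
    q3 <- th$q3[th$timepoint == tp]
    called_high <- expr$gene_id[expr[[tp]] > q3]
    expect_setequal(called_high, active)
  }
  # reaction level: the planted supply step is HIGH; the growth-only
  # branch is never called HIGH. (With zero noise every inactive gene
  # sits exactly at Q1, so the strict < Q1 rule makes no LOW call —
  # i.e. zero noise gives zero wrong calls, not spurious ones.)
  cl <- classify_reactions(toy$model, expr, "T1")
  expect_equal(as.character(cl$class[cl$reaction_id == "CCR"]), "HIGH")
  expect_false(as.character(cl$class[cl$reaction_id == "COF"]) == "HIGH")
  # with mild noise the inactive spread drops the growth branch below Q1
  expr2 <- generate_expression(genes, active, noise_sd = 0.5, seed = 11)
  cl2 <- classify_reactions(toy$model, expr2, "T1")
  expect_equal(as.character(cl2$class[cl2$reaction_id == "CCR"]), "HIGH")
})

test_that("expression tables are reproducible per seed and validated", {
  toy <- generate_toy_model(toy_model_spec())
  genes <- toy$model$genes
  e1 <- generate_expression(genes, genes[1:2], seed = 7)
  e2 <- generate_expression(genes, genes[1:2], seed = 7)
  expect_identical(e1, e2)
  e3 <- generate_expression(genes, genes[1:2], seed = 8)
  expect_false(identical(e1, e3))
  expect_true(all(as.matrix(e1[, -1]) >= 0))
  expect_error(generate_expression(genes, "not_a_gene"),
               class = "fluxscape_spec_error")
  # per-time-point active sets are honored
  e4 <- generate_expression(genes, list(T1 = genes[1], T2 = genes[2]),
                            timepoints = c("T1", "T2"), noise_sd = 0)
  expect_gt(e4$T1[e4$gene_id == genes[1]], e4$T1[e4$gene_id == genes[2]])
  expect_gt(e4$T2[e4$gene_id == genes[2]], e4$T2[e4$gene_id == genes[1]])
})

test_that("classification recovery degrades as expression noise grows", {
  toy <- generate_toy_model(toy_model_spec())
  genes <- c(toy$model$genes, sprintf("bg%03d", 1:40))
  active <- toy$ground_truth$genes_product_mode
  recovery <- function(noise_sd) {
    hits <- vapply(1:8, function(seed) {
      expr <- generate_expression(genes, active, timepoints = "T1",
                                  noise_sd = noise_sd, seed = seed)
      q3 <- compute_thresholds(expr)$q3
      called <- expr$gene_id[expr$T1 > q3]
      length(intersect(called, active)) / length(active)
    }, numeric(1))
    mean(hits)
  }
  rates <- vapply(c(0, 1.2, 3, 6), recovery, numeric(1))
  expect_equal(rates[1], 1)
  expect_true(all(diff(rates) <= 1e-9))
})
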