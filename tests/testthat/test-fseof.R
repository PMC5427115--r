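test_that("the planted supply step is selected with a rising profile", {
  toy <- generate_toy_model(toy_model_spec())
  sc <- fseof_scan(toy$model, "EX_product", base_rate = 0.1, n_steps = 10)
  row <- tibble::as_tibble(sc)[sc$reaction_id == toy$ground_truth$planted_supply_reaction, ]
  expect_true(row$selected)
  prof <- row$profile[[1]]
  expect_length(prof, 11L)                    # baseline + ten optimizations
  expect_true(all(diff(abs(prof)) >= -1e-9))  # monotone ramp on the toy
  expect_gt(abs(prof[11]), abs(prof[1]))
  # the product reaction itself is always selected: its profile is the ramp
  prod_row <- tibble::as_tibble(sc)[sc$reaction_id == "EX_product", ]
  expect_true(prod_row$selected)
  expect_equal(prod_row$profile[[1]],
               c(0.1, 0.1 + (1:10) * (attr(sc, "theoretical_max") - 0.1) / 10),
               tolerance = 1e-8)
})

test_that("the enforced ramp reaches the theoretical maximum and growth declines", {
  toy <- generate_toy_model(toy_model_spec(seed = 9))
  sc <- fseof_scan(toy$model, "EX_product", base_rate = 0.2, n_steps = 10)
  expect_equal(attr(sc, "theoretical_max"),
               fba(toy$model, "EX_product")$objective_value, tolerance = 1e-8)
  prod_prof <- tibble::as_tibble(sc)$profile[[
    which(sc$reaction_id == "EX_product")]]
  expect_equal(prod_prof[11], attr(sc, "theoretical_max"), tolerance = 1e-8)
  bio_prof <- tibble::as_tibble(sc)$profile[[which(sc$reaction_id == "BIOMASS")]]
  expect_true(all(diff(bio_prof) <= 1e-9))    # more product, less growth
  expect_false(sc$selected[sc$reaction_id == "BIOMASS"])
  # growth-only branch: flux tracks biomass downward, never selected
  expect_false(sc$selected[sc$reaction_id == "COF"])
})

test_that("a base rate above the theoretical maximum is an error", {
  toy <- generate_toy_model(toy_model_spec())$model
  expect_error(fseof_scan(toy, "EX_product", base_rate = 5),
               class = "fluxscape_infeasible_error")
})

test_that("filters exclude decoys with the stated reasons", {
  toy <- generate_toy_model(toy_model_spec())
  sc <- fseof_scan(toy$model, "EX_product", base_rate = 0.1)
  ft <- filter_targets(sc, toy$model)
  reason <- stats::setNames(ft$exclusion_reason, ft$reaction_id)
  for (id in names(toy$ground_truth$decoy_reasons)) {
    expect_equal(unname(reason[id]), unname(toy$ground_truth$decoy_reasons[id]))
  }
  survivors <- ft$reaction_id[is.na(ft$exclusion_reason)]
  expect_equal(survivors, toy$ground_truth$planted_supply_reaction)
  expect_equal(target_genes(ft), toy$ground_truth$planted_gene)
  g <- glance(ft)
  expect_equal(g$n_targets, 1)
  expect_equal(g$n_excluded_exchange, 1)
  expect_equal(g$n_excluded_gap_fill, 1)
  expect_equal(g$n_excluded_multi_gene, 2)
})

test_that("selection is invariant to flipping a reversible reaction's direction", {
  toy <- generate_toy_model(toy_model_spec(seed = 12))$model
  sc1 <- fseof_scan(toy, "EX_product", base_rate = 0.1)
  flipped <- toy$reactions[, c("id", "name", "stoich", "lb", "ub", "gpr", "subsystem")]
  i <- match("CCR", flipped$id)
  flipped$stoich[[i]] <- -flipped$stoich[[i]]
  old_lb <- flipped$lb[i]; old_ub <- flipped$ub[i]
  flipped$lb[i] <- -old_ub; flipped$ub[i] <- -old_lb
  m2 <- metabolic_model(flipped, objective = "BIOMASS")
  sc2 <- fseof_scan(m2, "EX_product", base_rate = 0.1)
  expect_equal(sc1$selected, sc2$selected)
  expect_equal(abs(tibble::as_tibble(sc2)$profile[[i]]),
               abs(tibble::as_tibble(sc1)$profile[[i]]), tolerance = 1e-8)
})

test_that("the report ranks by slope with lexicographic tie-breaking", {
  toy <- generate_toy_model(toy_model_spec())
  sc <- fseof_scan(toy$model, "EX_product", base_rate = 0.1)
  ft <- filter_targets(sc, toy$model)
  rep <- report_targets(ft, toy$model)
  expect_equal(rep$reaction_id, toy$ground_truth$planted_supply_reaction)
  # empty filtered set gives a header-only table (and file)
  none <- ft[0, ]
  attr(none, "genes") <- character(0)
  class(none) <- class(ft)
  path <- withr::local_tempfile(fileext = ".tsv")
  rep0 <- report_targets(none, toy$model, path = path)
  expect_equal(nrow(rep0), 0L)
  expect_equal(length(readLines(path)), 1L)
  # ties in slope break lexicographically: build a two-survivor scan
  spec2 <- toy_model_spec(product_precursors = c(p1 = 1, p2 = 1),
                          decoys = FALSE)
  toy2 <- generate_toy_model(spec2)
  sc2 <- fseof_scan(toy2$model, "EX_product", base_rate = 0.1)
  ft2 <- filter_targets(sc2, toy2$model)
  rep2 <- report_targets(ft2, toy2$model)
  same <- rep2[abs(rep2$slope - max(rep2$slope)) < 1e-12, ]
  expect_equal(same$reaction_id, sort(same$reaction_id))
})
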