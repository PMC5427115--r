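test_that("FBA solves the linear chain and reports infeasibility honestly", {
  m <- chain_model(cap = 10)
  res <- fba(m)
  expect_equal(res$status, "optimal")
  expect_equal(res$objective_value, 10)
  expect_equal(unname(res$fluxes), c(10, 10, 10))
  # forcing more flux than the uptake cap admits
  forced <- m
  forced$reactions$lb[forced$reactions$id == "SINK_B"] <- 11
  forced$reactions$ub[forced$reactions$id == "SINK_B"] <- 11
  expect_equal(fba(forced)$status, "infeasible")
})

test_that("FBA on a branched yield trade-off matches vertex enumeration", {
  m <- branched_model()
  # rich route: 3 B per 2 A, capped at 4; analytically: 4*3 + (10-8)*1 = 14
  res <- fba(m)
  expect_equal(res$objective_value, 14)
  S <- build_stoich_matrix(m)
  oracle <- enumerate_lp_optimum(
    as.numeric(m$reactions$id == "SINK_B"), S,
    m$reactions$lb, m$reactions$ub
  )
  expect_equal(res$objective_value, oracle, tolerance = 1e-8)
})

test_that("every optimal flux vector satisfies mass balance and bounds", {
  for (seed in 1:5) {
    toy <- generate_toy_model(random_toy_spec(seed))
    for (method in list(fba, pfba)) {
      res <- method(toy$model)
      expect_equal(res$status, "optimal")
      S <- as.matrix(build_stoich_matrix(toy$model))
      expect_lt(max(abs(S %*% res$fluxes)), 1e-6)
      expect_true(all(res$fluxes >= toy$model$reactions$lb - 1e-9))
      expect_true(all(res$fluxes <= toy$model$reactions$ub + 1e-9))
    }
  }
})

test_that("the optimum is invariant under reordering and reversible splitting", {
  toy <- generate_toy_model(toy_model_spec(seed = 2))$model
  opt <- fba(toy)$objective_value
  perm <- sample(seq_len(nrow(toy$reactions)))
  shuffled <- metabolic_model(
    toy$reactions[perm, c("id", "name", "stoich", "lb", "ub", "gpr", "subsystem")],
    metabolites = toy$metabolites, objective = toy$objective
  )
  expect_equal(fba(shuffled)$objective_value, opt, tolerance = 1e-9)
  # split the reversible carbon exchange into irreversible halves
  split <- toy$reactions[, c("id", "name", "stoich", "lb", "ub", "gpr", "subsystem")]
  i <- match("EX_carbon", split$id)
  fwd <- split[i, ]; rev <- split[i, ]
  fwd$lb <- 0
  rev$id <- "EX_carbon_rev"; rev$stoich <- list(-split$stoich[[i]])
  rev$lb <- 0; rev$ub <- -split$lb[i]
  split$lb[i] <- 0
  split2 <- dplyr::bind_rows(split[-i, ], fwd, rev)
  m2 <- metabolic_model(split2, objective = toy$objective)
  expect_equal(fba(m2)$objective_value, opt, tolerance = 1e-9)
})

test_that("pFBA picks the least-total-flux representative", {
  m <- parallel_model(cap = 10)
  plain <- fba(m)
  pars <- pfba(m)
  expect_equal(pars$objective_value, plain$objective_value)
  f <- pars$fluxes
  # the one-step route carries everything; the two-step detour is idle
  expect_equal(unname(f["DIRECT"]), 10)
  expect_equal(unname(f["DETOUR1"]), 0)
  expect_equal(unname(f["DETOUR2"]), 0)
  # the thermodynamically meaningless 2-cycle is driven to zero
  expect_equal(unname(f["CYC_F"]), 0)
  expect_equal(unname(f["CYC_R"]), 0)
  expect_lte(sum(abs(pars$fluxes)), sum(abs(plain$fluxes)) + 1e-9)
  # on a single-path model pFBA equals FBA
  ch <- chain_model()
  expect_equal(pfba(ch)$fluxes, fba(ch)$fluxes)
})

test_that("FVA brackets the feasible flux range", {
  m <- chain_model(cap = 10)
  expect_equal(fva(m, "SINK_B", fraction = 0),
               tibble::tibble(id = "SINK_B", min = 0, max = 10))
  expect_equal(fva(m, "SINK_B", fraction = 1)$min, 10)
  # a dead-end side reaction can never carry flux
  dead <- metabolic_model(
    tibble::tibble(
      id = c("EX_A", "A_to_B", "A_to_D", "SINK_B"),
      stoich = list(c(A = 1), c(A = -1, B = 1), c(A = -1, D = 1), c(B = -1)),
      lb = c(0, 0, 0, 0), ub = c(10, 1000, 1000, 1000)
    ),
    objective = "SINK_B"
  )
  expect_equal(fva(dead, "A_to_D", fraction = 0),
               tibble::tibble(id = "A_to_D", min = 0, max = 0))
  # random feasible points always fall inside the FVA interval
  toy <- generate_toy_model(toy_model_spec(seed = 5))$model
  rng <- fva(toy, c("CCR", "BIOMASS", "EX_product"), fraction = 0)
  for (seed in 1:20) {
    withr::with_seed(seed, {
      mu <- stats::runif(1, 0, 1)
    })
    pt <- pfba(fix_flux(toy, "BIOMASS", mu), objective = "EX_product")
    for (k in seq_len(nrow(rng))) {
      v <- pt$fluxes[[rng$id[k]]]
      expect_gte(v, rng$min[k] - 1e-8)
      expect_lte(v, rng$max[k] + 1e-8)
    }
  }
})

test_that("media set uptake bounds with the exchange sign convention", {
  toy <- generate_toy_model(toy_model_spec())$model
  m <- apply_medium(toy, medium_spec(c(EX_carbon = 5), closed_default = FALSE))
  expect_equal(m$reactions$lb[m$reactions$id == "EX_carbon"], -5)
  # closed_default blocks unlisted uptake but leaves secretion alone
  m2 <- apply_medium(toy, medium_spec(c(EX_carbon = 5)))
  salt <- m2$reactions[m2$reactions$id == "EX_salt", ]
  expect_equal(salt$lb, 0)
  expect_equal(salt$ub, 1000)
  expect_error(apply_medium(toy, medium_spec(c(EX_bogus = 1))),
               "EX_bogus", class = "fluxscape_medium_error")
  expect_error(medium_spec(c(EX_carbon = -2)), class = "fluxscape_medium_error")
})
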