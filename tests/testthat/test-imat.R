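test_that("quartile thresholds use linear-interpolation quantiles", {
  prof <- tibble::tibble(gene_id = paste0("g", 1:5),
                         T1 = c(0, 10, 20, 30, 40))
  th <- compute_thresholds(prof)
  expect_equal(th$q1, 10)
  expect_equal(th$q3, 30)
  prof2 <- tibble::tibble(gene_id = paste0("g", 1:8), T1 = 1:8)
  th2 <- compute_thresholds(prof2)
  expect_equal(th2$q1, 2.75)
  expect_equal(th2$q3, 6.25)
  prof3 <- tibble::tibble(gene_id = paste0("g", 1:6), T1 = rep(7, 6))
  th3 <- compute_thresholds(prof3)
  expect_equal(th3$q1, 7)
  expect_equal(th3$q3, 7)
  expect_error(compute_thresholds(tibble::tibble(gene_id = "g1", T1 = 1)),
               class = "fluxscape_spec_error")
})

test_that("reaction classes follow the GPR min/max mapping", {
  m <- metabolic_model(
    tibble::tibble(
      id = c("EX", "ISO", "CPLX", "NOGPR"),
      stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1, C = 1), c(C = -1)),
      gpr = c("", "g1 or g2", "g1 and g2", "")
    ),
    objective = "NOGPR"
  )
  prof <- tibble::tibble(gene_id = c("g1", "g2", paste0("bg", 1:8)),
                         T1 = c(100, 1, 10, 12, 14, 16, 18, 20, 22, 24))
  th <- compute_thresholds(prof)   # q1 = 10.5, q3 = 19.5 over all ten genes
  cl <- classify_reactions(m, prof, "T1", th)
  expect_equal(as.character(cl$class),
               c("MODERATE", "HIGH", "LOW", "MODERATE"))
  expect_equal(cl$expression[cl$reaction_id == "ISO"], 100)   # OR -> max
  expect_equal(cl$expression[cl$reaction_id == "CPLX"], 1)    # AND -> min
  # a gene absent from the profile is reported and degrades gracefully
  m2 <- metabolic_model(
    tibble::tibble(id = c("EX", "R"), stoich = list(c(A = 1), c(A = -1)),
                   gpr = c("", "g1 and gZ")),
    objective = "R"
  )
  expect_message(cl2 <- classify_reactions(m2, prof, "T1", th), "missing")
  expect_equal(as.character(cl2$class[cl2$reaction_id == "R"]), "MODERATE")
})

test_that("a fully consistent all-HIGH chain scores every call", {
  m <- metabolic_model(
    tibble::tibble(
      id = c("EX_A", "R1", "R2", "SINK"),
      stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1, C = 1), c(C = -1)),
      lb = c(1, 0, 0, 0), ub = c(10, 1000, 1000, 1000)
    ),
    objective = "SINK"
  )
  classes <- tibble::tibble(reaction_id = m$reactions$id,
                            class = factor(rep("HIGH", 4)))
  res <- imat(m, classes, epsilon = 1e-3)
  expect_equal(res$status, "optimal")
  expect_equal(res$score, 4)
  expect_true(all(res$active))
  S <- as.matrix(build_stoich_matrix(m))
  expect_lt(max(abs(S %*% res$fluxes)), 1e-6)
})

test_that("conflicting calls resolve to the enumeration optimum", {
  # chain where upstream is LOW but downstream HIGH: not all calls can win
  m <- chain_model(cap = 10)
  classes <- tibble::tibble(
    reaction_id = c("EX_A", "A_to_B", "SINK_B"),
    class = factor(c("LOW", "HIGH", "HIGH"))
  )
  res <- imat(m, classes, epsilon = 1e-3)
  oracle <- imat_brute_force(m, classes, epsilon = 1e-3)
  expect_equal(res$score, oracle)
  expect_equal(res$score, 2)  # run the chain: both HIGH win, LOW loses
})

test_that("MILP scores equal brute-force enumeration on random tiny models", {
  for (seed in 1:6) {
    toy <- generate_toy_model(random_toy_spec(seed, minimal = TRUE))$model
    classes <- withr::with_seed(seed + 100, {
      picked <- sample(toy$reactions$id, 5)
      tibble::tibble(
        reaction_id = picked,
        class = factor(sample(c("HIGH", "LOW"), 5, replace = TRUE,
                              prob = c(0.6, 0.4)))
      )
    })
    fix <- if (seed %% 2 == 0) c(BIOMASS = 1e-10) else NULL
    res <- imat(toy, classes, fix = fix, epsilon = 1e-3)
    oracle <- imat_brute_force(toy, classes, fix = fix, epsilon = 1e-3)
    expect_equal(res$score, oracle)
  }
})

test_that("raising the activation threshold never raises the score", {
  toy <- generate_toy_model(toy_model_spec(seed = 2))$model
  classes <- tibble::tibble(
    reaction_id = c("CORE1", "CORE2", "CCR", "ASSEMBLY", "COF"),
    class = factor(c("HIGH", "HIGH", "HIGH", "LOW", "LOW"))
  )
  scores <- vapply(c(1e-4, 1e-2, 1, 5), function(eps) {
    imat(toy, classes, fix = c(BIOMASS = 0.1), epsilon = eps)$score
  }, numeric(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("with everything MODERATE iMAT matches the pFBA census", {
  toy <- generate_toy_model(toy_model_spec(seed = 8))$model
  classes <- tibble::tibble(reaction_id = toy$reactions$id,
                            class = factor(rep("MODERATE", nrow(toy$reactions))))
  fix <- c(BIOMASS = 0.3, EX_product = 0.5)
  res <- imat(toy, classes, fix = fix)
  expect_equal(res$score, 0)
  m2 <- fix_flux(fix_flux(toy, "BIOMASS", 0.3), "EX_product", 0.5)
  ref <- pfba(m2, objective = "BIOMASS")
  expect_equal(census_active(res)$n_active,
               sum(abs(ref$fluxes) > FLUX_ZERO))
  # infeasible fixed rates raise an informative error
  expect_error(imat(toy, classes, fix = c(BIOMASS = 1.5)),
               class = "fluxscape_infeasible_error")
})

test_that("the activity census counts thresholded fluxes per subsystem", {
  fake <- list(fluxes = c(R1 = 0, R2 = 1e-9, R3 = 0.5))
  expect_equal(census_active(fake)$n_active, 1)
  expect_equal(census_active(list(fluxes = c(a = 0, b = 0)))$n_active, 0)
  toy <- generate_toy_model(toy_model_spec())$model
  res <- pfba(fix_flux(toy, "EX_product", 1), objective = "BIOMASS")
  cen <- census_active(res, model = toy)
  expect_equal(cen$subsystem[1], "(all)")
  expect_equal(sum(cen$n_active[-1]), cen$n_active[1])
  # four synthetic time points: census mean/sd by the direct formulas
  counts <- vapply(c(0.2, 0.5, 0.8, 1.2), function(q) {
    census_active(pfba(fix_flux(toy, "EX_product", q)))$n_active
  }, numeric(1))
  expect_equal(mean(counts), sum(counts) / 4)
  expect_equal(stats::sd(counts), sqrt(sum((counts - mean(counts))^2) / 3))
})
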