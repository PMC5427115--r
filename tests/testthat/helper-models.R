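# Small fixture models built in code.

# linear chain: EX_A (boundary, written as producing A), A -> B,
# B -> (biomass sink). Max flux through the chain is the EX_A cap.
chain_model <- function(cap = 10) {
  metabolic_model(
    tibble::tibble(
      id = c("EX_A", "A_to_B", "SINK_B"),
      stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
      lb = c(0, 0, 0), ub = c(cap, 1000, 1000),
      gpr = c("", "g1", "g2")
    ),
    objective = "SINK_B", name = "chain"
  )
}

# two routes from A to B: a direct step and a two-step detour, plus a
# reversible 2-cycle between B and C; used for pFBA behavior.
parallel_model <- function(cap = 10) {
  metabolic_model(
    tibble::tibble(
      id = c("EX_A", "DIRECT", "DETOUR1", "DETOUR2", "CYC_F", "CYC_R", "SINK_B"),
      stoich = list(
        c(A = 1), c(A = -1, B = 1), c(A = -1, D = 1), c(D = -1, B = 1),
        c(B = -1, C = 1), c(C = -1, B = 1), c(B = -1)
      ),
      lb = c(0, 0, 0, 0, -1000, -1000, 0),
      ub = c(cap, 1000, 1000, 1000, 1000, 1000, 1000)
    ),
    objective = "SINK_B", name = "parallel"
  )
}

# branched network with two routes of different yield competing for A:
# cheap route 1 A -> 1 B, costly route 2 A -> 3 B but capped.
branched_model <- function() {
  metabolic_model(
    tibble::tibble(
      id = c("EX_A", "CHEAP", "RICH", "SINK_B"),
      stoich = list(c(A = 1), c(A = -1, B = 1), c(A = -2, B = 3), c(B = -1)),
      lb = c(0, 0, 0, 0), ub = c(10, 1000, 4, 1000)
    ),
    objective = "SINK_B", name = "branched"
  )
}

# random small toy spec for the property/acceptance loops
random_toy_spec <- function(seed, minimal = FALSE) {
  withr::with_seed(seed, {
    n_prec <- if (minimal) 1L else sample(1:3, 1)
    prec <- stats::setNames(round(stats::runif(n_prec, 0.5, 2), 2),
                            paste0("prec", seq_len(n_prec)))
    toy_model_spec(
      n_core_reactions = if (minimal) 1L else sample(1:3, 1),
      uptake_capacity = round(stats::runif(1, 4, 20), 2),
      biomass_yield = round(stats::runif(1, 0.05, 0.5), 3),
      product_precursors = prec,
      product_capacity = round(stats::runif(1, 0.5, 4), 2),
      decoys = !minimal,
      cofactor_branch = !minimal,
      seed = seed
    )
  })
}
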