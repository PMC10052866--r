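test_that("state energy follows the pairwise Hamiltonian", {
  S2 <- maxent_model(c(1, 0), matrix(c(0, 2, 2, 0), 2))
  expect_equal(state_energy(c(1, 1), S2), -3)
  expect_equal(state_energy(c(0, 0), S2), 0)
  flat <- maxent_model(rep(0, 3), matrix(0, 3, 3))
  for (k in 1:8) expect_equal(state_energy(oracle_states(3)[k, ], flat), 0)
  expect_error(state_energy(c(1, 0, 1), S2), "length")
})

test_that("state probabilities match the enumeration oracle", {
  m1 <- maxent_model(0, matrix(0, 1, 1))
  expect_equal(state_probabilities(m1), c(0.5, 0.5))
  m2 <- maxent_model(c(0, 0), matrix(0, 2, 2))
  expect_equal(state_probabilities(m2), rep(0.25, 4))
  set.seed(3)
  for (i in 1:5) {
    gt <- random_ising(6)
    model <- maxent_model(gt$h, gt$J)
    p <- state_probabilities(model)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, oracle_state_probs(gt$h, gt$J), tolerance = 1e-10)
  }
})

test_that("binarization applies the occurrence window inclusively", {
  n <- 100
  tab <- abundance_table(dplyr::bind_rows(
    tibble::tibble(treatment = "t", replicate = "R1", day = 1:n,
                   taxon = "ubiquitous", abundance = c(rep(1, 99), 0)),
    tibble::tibble(treatment = "t", replicate = "R1", day = 1:n,
                   taxon = "boundary", abundance = c(rep(1, 2), rep(0, 98))),
    tibble::tibble(treatment = "t", replicate = "R1", day = 1:n,
                   taxon = "mid", abundance = rep(c(1, 0), 50)),
    tibble::tibble(treatment = "t", replicate = "R1", day = 1:n,
                   taxon = "tiny", abundance = c(rep(1e-9, 50), rep(0, 50)))))
  bc <- binarize(tab)
  expect_false("ubiquitous" %in% bc$taxa)      # 99% of samples: excluded
  expect_true("boundary" %in% bc$taxa)         # exactly 2%: retained
  expect_true("tiny" %in% bc$taxa)             # any positive value counts
  expect_equal(sum(bc$matrix[, "tiny"]), 50)
  expect_error(binarize(tab[tab$taxon == "ubiquitous", ]), "occurrence")
})

test_that("moment matching fits uniform data to a near-flat model", {
  set.seed(4)
  x <- matrix(rbinom(5000 * 5, 1, 0.5), 5000, 5)
  fit <- fit_maxent(x)
  expect_true(fit$diagnostics$converged)
  expect_lt(max(abs(fit$h)), 0.15)
  expect_lt(max(abs(fit$J)), 0.15)
  # at convergence model moments equal (regularized) empirical moments
  p <- state_probabilities(fit)
  st <- oracle_states(5)
  emp <- (colSums(x) + 0.5) / (nrow(x) + 1)
  expect_lt(max(abs(colSums(st * p) - emp)), 1e-3)
})

test_that("never co-occurring pairs stay finite via the pseudocount", {
  x <- cbind(rep(c(1, 0), 50), rep(c(0, 1), 50))   # perfectly exclusive
  fit <- fit_maxent(x, max_iter = 5000)
  expect_true(all(is.finite(fit$h)) && all(is.finite(fit$J)))
  expect_lt(fit$J[1, 2], 0)   # exclusion maps to negative coupling
})

test_that("stable states are exactly the strict minima of the landscape", {
  # uniform positive bias, no coupling: unique minimum at all-ones
  m <- maxent_model(rep(5, 4), matrix(0, 4, 4))
  mins <- find_stable_states(m)
  expect_equal(nrow(mins), 1)
  expect_equal(unname(mins[1, ]), rep(1L, 4))
  # flat landscape: every neighbor ties, no strict minima
  expect_equal(nrow(find_stable_states(maxent_model(rep(0, 3),
                                                    matrix(0, 3, 3)))), 0)
  # block model with two guilds: exactly the two guild states
  dw <- double_well_model()
  mins2 <- find_stable_states(dw)
  expect_equal(nrow(mins2), 2)
  idx <- sort(apply(mins2, 1, function(s) sum(s * 2^(0:3)) + 1))
  expect_equal(idx, sort(oracle_minima(dw$h, dw$J)))
})

test_that("steepest descent basins partition the state space", {
  dw <- double_well_model()
  expect_equal(basin_of(c(1, 1, 0, 0), dw), c(1, 1, 0, 0))  # minimum: itself
  expect_equal(basin_of(c(1, 0, 0, 0), dw), c(1, 1, 0, 0))  # one flip above
  set.seed(5)
  for (i in 1:3) {
    gt <- random_ising(8)
    model <- maxent_model(gt$h, gt$J)
    land <- enumerate_landscape(model)
    # every basin label is a minimum, and minima map to themselves
    expect_true(all(land$basin %in% land$state[land$is_minimum]))
    expect_true(all(land$basin[land$is_minimum] ==
                      land$state[land$is_minimum]))
    # spot-check the descent oracle on 20 random states
    for (k in sample.int(256, 20)) {
      expect_equal(land$basin[k],
                   land$state[oracle_descend(k, gt$h, gt$J)])
    }
  }
})

test_that("energy gaps are nonnegative deviations from the basin bottom", {
  dw <- double_well_model()
  expect_equal(energy_gap(c(1, 1, 0, 0), dw), 0)
  # one flip above a minimum: exactly the energy difference
  dH <- state_energy(c(1, 0, 0, 0), dw) - state_energy(c(1, 1, 0, 0), dw)
  expect_equal(energy_gap(c(1, 0, 0, 0), dw), dH)
  expect_gte(dH, 0)
  # every state's gap is nonnegative and matches the enumerated landscape
  land <- enumerate_landscape(dw)
  gaps <- land$energy - land$energy[match(land$basin, land$state)]
  states <- oracle_states(4)
  for (k in seq_len(16)) {
    expect_equal(energy_gap(states[k, ], dw), gaps[k])
    expect_gte(gaps[k], 0)
  }
})

test_that("stable-state entropy spans 0 to log(number of minima)", {
  single <- maxent_model(rep(5, 4), matrix(0, 4, 4))
  expect_equal(stable_state_entropy(c(0, 1, 0, 1), single, n_walks = 200,
                                    seed = 1), 0)
  dw <- double_well_model()
  # symmetric start between the wells: ln 2 within Monte-Carlo error
  e <- stable_state_entropy(c(0, 0, 0, 0), dw, n_walks = 1000, seed = 2)
  expect_lt(abs(e - log(2)), 0.01)
  expect_lte(e, log(2) + 1e-12)
  # deep inside one well at strong coupling: escape is effectively impossible
  deep <- double_well_model(strength = 8)
  expect_equal(stable_state_entropy(c(1, 1, 0, 0), deep, n_walks = 500,
                                    seed = 3), 0)
  nomin <- maxent_model(rep(0, 3), matrix(0, 3, 3))
  expect_error(stable_state_entropy(c(0, 0, 0), nomin), "minimum")
})

test_that("landscape JSON serialization round-trips the parameters", {
  dw <- double_well_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_maxent_model(dw, f)
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(js$h, dw$h)
  expect_equal(js$J_upper$value, dw$J[upper.tri(dw$J)])
})
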