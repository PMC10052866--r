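test_that("deterministic gLV with self-limitation converges to carrying capacity", {
  # zero off-diagonal interactions: each taxon follows a logistic map with
  # fixed point K_i = -r_i / a_ii
  r <- c(0.5, 0.3)
  a <- diag(c(-0.5, -0.6))
  p <- glv_params(2, r, a, noise_sd = 0, dilution_fraction = 0,
                  n_replicates = 1, n_days = 300, init = c(0.1, 0.1))
  m <- abundance_matrix(simulate_glv(p), "R1")
  K <- -r / diag(a)
  expect_equal(unname(m[300, ]), K, tolerance = 1e-8)
  # residual of dN/dt at the terminal state
  n <- m[300, ]
  expect_lt(max(abs(n * (r + a %*% n))), 1e-8)
})

test_that("identical seeds reproduce bit-identical simulations", {
  p <- glv_params(3, c(0.4, 0.5, 0.6), -0.4 * diag(3), noise_sd = 0.2,
                  n_replicates = 2, n_days = 30, seed = 42)
  expect_identical(simulate_glv(p), simulate_glv(p))
})

test_that("diverging trajectories fail loudly with taxon and day", {
  p <- glv_params(1, 5, matrix(0.1), noise_sd = 0, dilution_fraction = 0,
                  n_replicates = 1, n_days = 200, init = 1)
  expect_error(simulate_glv(p), "diverged.*T01.*day")
})

test_that("chaotic fixture is bounded with a positive Lyapunov exponent", {
  fx <- community_fixture("chaotic4")
  m <- abundance_matrix(fx$table, "R1")
  expect_true(all(is.finite(m)))
  expect_lt(max(m), 5)
  # two-trajectory divergence oracle on the deterministic skeleton
  par <- fx$params
  par$noise_sd <- 0
  par$n_replicates <- 2
  par$n_days <- 500
  i0 <- par$init[1, ]
  par$init <- rbind(i0, i0 * (1 + 1e-9))
  tb <- simulate_glv(par)
  d <- sqrt(rowSums((abundance_matrix(tb, "R1") -
                     abundance_matrix(tb, "R2"))^2))
  lyap <- log(d[400] / d[1]) / 400
  expect_gt(lyap, 0)
  # non-repeating: late-window variability persists
  expect_gt(mean(apply(abundance_matrix(tb, "R1")[400:500, ], 2, sd)), 0.01)
})

test_that("simulated read counts are exact multinomials over taxa and spikes", {
  fx <- community_fixture("stable", n_replicates = 2, n_days = 10)
  rd <- simulate_reads(fx$table, spike_in_set(), reads_per_sample = 5000,
                       seed = 9)
  tot <- dplyr::summarise(
    dplyr::group_by(
      dplyr::bind_rows(rd$reads[c("sample_id", "reads")],
                       rd$spikes[c("sample_id", "reads")]),
      sample_id),
    n = sum(reads), .groups = "drop")
  expect_true(all(tot$n == 5000))
  # zero depth gives empty counts
  rd0 <- simulate_reads(fx$table, spike_in_set(), reads_per_sample = 0)
  expect_true(all(rd0$reads$reads == 0) && all(rd0$spikes$reads == 0))
})

test_that("an all-zero community sample sends every read to the spikes", {
  empty <- abundance_table(tibble::tibble(
    treatment = "t", replicate = "R1", day = 1:2,
    taxon = "T01", abundance = 0))
  rd <- simulate_reads(empty, spike_in_set(), reads_per_sample = 1000)
  expect_true(all(rd$reads$reads == 0))
  expect_equal(sum(rd$spikes$reads), 2000)
})

test_that("spike read proportions follow the concentration gradient", {
  # one taxon at the top spike concentration: expected reads match spike #1
  one <- abundance_table(tibble::tibble(
    treatment = "t", replicate = "R1", day = 1, taxon = "T01",
    abundance = 0.1))
  rd <- simulate_reads(one, spike_in_set(), reads_per_sample = 1e6, seed = 3)
  expect_equal(rd$reads$reads[1], rd$spikes$reads[1], tolerance = 0.02)
  # five spikes alone: proportions within 3 binomial SE of the gradient
  rd2 <- simulate_reads(empty <- abundance_table(tibble::tibble(
    treatment = "t", replicate = "R1", day = 1, taxon = "T01",
    abundance = 0)), spike_in_set(), reads_per_sample = 1e6, seed = 4)
  conc <- c(0.1, 0.05, 0.02, 0.01, 0.005)
  expected <- conc / sum(conc)
  obs <- rd2$spikes$reads / 1e6
  se <- sqrt(expected * (1 - expected) / 1e6)
  expect_true(all(abs(obs - expected) <= 3 * se))
})

test_that("exact Ising sampling matches the enumeration oracle", {
  # flat model: all 8 states near-uniform
  spec <- ising_spec(rep(0, 3), matrix(0, 3, 3), n_samples = 16000, seed = 5)
  x <- sample_ising(spec)
  idx <- x %*% 2^(0:2) + 1
  freq <- tabulate(idx, 8) / 16000
  expect_true(all(abs(freq - 1 / 8) < 3 * sqrt(0.125 * 0.875 / 16000)))
  # strong positive bias: the all-ones state dominates
  spec2 <- ising_spec(rep(5, 3), matrix(0, 3, 3), n_samples = 2000, seed = 6)
  expect_gt(mean(rowSums(sample_ising(spec2)) == 3), 0.95)
  # random S = 6 model: sample moments within 3 SE of enumeration oracle
  set.seed(7)
  gt <- random_ising(6)
  spec3 <- ising_spec(gt$h, gt$J, n_samples = 50000, seed = 8)
  x3 <- sample_ising(spec3)
  pr <- oracle_state_probs(gt$h, gt$J)
  st <- oracle_states(6)
  exact_m1 <- colSums(st * pr)
  se <- sqrt(exact_m1 * (1 - exact_m1) / 50000)
  expect_true(all(abs(colMeans(x3) - exact_m1) <= 3 * se + 1e-12))
})

test_that("Gibbs sampling agrees with exact sampling on first moments", {
  set.seed(10)
  gt <- random_ising(5, scale_h = 0.5, scale_J = 0.5)
  spec <- ising_spec(gt$h, gt$J, n_samples = 4000, seed = 11)
  xg <- sample_ising(spec, method = "gibbs", burn_in = 100, thin = 2)
  pr <- oracle_state_probs(gt$h, gt$J)
  exact_m1 <- colSums(oracle_states(5) * pr)
  expect_true(all(abs(colMeans(xg) - exact_m1) < 0.05))
})

test_that("exact mode refuses oversized systems with guidance", {
  spec <- ising_spec(rep(0, 21), matrix(0, 21, 21), n_samples = 10)
  expect_error(sample_ising(spec), "gibbs")
})
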