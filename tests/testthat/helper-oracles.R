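# Independent oracles and shared fixtures for the test suite.
#
# The oracles deliberately use plain loops and their own arithmetic so that
# they share no code path with the package implementation they check.

# --- enumeration oracle for the pairwise maximum-entropy model ------------

# all 2^S presence/absence states, row k = bit pattern k-1, lowest bit first
oracle_states <- function(S) {
  out <- matrix(0L, 2^S, S)
  for (k in seq_len(2^S)) {
    v <- k - 1L
    for (i in seq_len(S)) {
      out[k, i] <- v %% 2L
      v <- v %/% 2L
    }
  }
  out
}

oracle_energy <- function(state, h, J) {
  e <- 0
  for (i in seq_along(h)) {
    e <- e - h[i] * state[i]
    if (i < length(h)) {
      for (j in (i + 1):length(h)) e <- e - J[i, j] * state[i] * state[j]
    }
  }
  e
}

oracle_state_probs <- function(h, J) {
  st <- oracle_states(length(h))
  e <- apply(st, 1, oracle_energy, h = h, J = J)
  w <- exp(-(e - min(e)))
  w / sum(w)
}

# strict minima by exhaustive neighbor comparison
oracle_minima <- function(h, J) {
  S <- length(h)
  st <- oracle_states(S)
  e <- apply(st, 1, oracle_energy, h = h, J = J)
  is_min <- logical(nrow(st))
  for (k in seq_len(nrow(st))) {
    ok <- TRUE
    for (i in seq_len(S)) {
      nb <- st[k, ]
      nb[i] <- 1L - nb[i]
      idx <- sum(nb * 2^(seq_len(S) - 1)) + 1L
      if (e[idx] <= e[k]) { ok <- FALSE; break }
    }
    is_min[k] <- ok
  }
  which(is_min)
}

# steepest descent with lowest-flipped-bit tie-break; returns state index
oracle_descend <- function(k, h, J) {
  S <- length(h)
  st <- oracle_states(S)
  e <- apply(st, 1, oracle_energy, h = h, J = J)
  repeat {
    nb_idx <- integer(S)
    for (i in seq_len(S)) {
      nb <- st[k, ]
      nb[i] <- 1L - nb[i]
      nb_idx[i] <- sum(nb * 2^(seq_len(S) - 1)) + 1L
    }
    best <- which.min(e[nb_idx])
    if (e[nb_idx[best]] < e[k]) k <- nb_idx[best] else return(k)
  }
}

# --- random model / composition generators --------------------------------

random_ising <- function(S, scale_h = 1, scale_J = 0.8) {
  h <- stats::rnorm(S, 0, scale_h)
  J <- matrix(0, S, S)
  J[upper.tri(J)] <- stats::rnorm(S * (S - 1) / 2, 0, scale_J)
  list(h = h, J = J + t(J))
}

random_composition <- function(n) {
  x <- stats::rgamma(n, shape = 0.8)
  x / sum(x)
}

# symmetric double-well model: two mutually facilitative pairs with
# cross-inhibition; minima at (1,1,0,0) and (0,0,1,1)
double_well_model <- function(strength = 3) {
  J <- matrix(0, 4, 4)
  J[1, 2] <- J[2, 1] <- strength
  J[3, 4] <- J[4, 3] <- strength
  J[1, 3] <- J[3, 1] <- J[1, 4] <- J[4, 1] <- -strength
  J[2, 3] <- J[3, 2] <- J[2, 4] <- J[4, 2] <- -strength
  maxent_model(rep(1, 4), J)
}

# --- cached expensive fixtures -------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# bistable fixture taken through reads + calibration (detection-limit
# flicker is part of the study conditions the landscape stage assumes)
bistable_calibrated <- function() {
  cached("bistable_cal", {
    fx <- community_fixture("bistable")
    rd <- simulate_reads(fx$table, spike_in_set(), reads_per_sample = 20000,
                         seed = 2)
    quality_filter(calibrate_table(rd$reads, rd$spikes))$abundance
  })
}

chaotic_table <- function() {
  cached("chaotic4", community_fixture("chaotic4", n_replicates = 4,
                                       n_days = 60)$table)
}
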