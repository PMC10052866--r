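#' Pairwise maximum-entropy model over binary community states
#'
#' The model assigns every presence/absence state sigma in \{0,1\}^S the
#' energy
#' \deqn{H(\sigma) = -\sum_i h_i \sigma_i - \sum_i \sum_{j>i} J_{ij} \sigma_i \sigma_j}
#' and the stationary probability p(sigma) = exp(-H(sigma))/Z. `h_i` is the
#' net effect of implicit abiotic factors on taxon i (positive favours
#' presence) and `J_ij` is the pairwise co-occurrence coupling.
#'
#' @param h numeric bias vector, one entry per taxon.
#' @param J symmetric coupling matrix with zero diagonal.
#' @param taxa optional taxon ids (default `h` names or `T01`, ...).
#' @param diagnostics optional list of fit diagnostics (see [fit_maxent()]).
#' @return object of class `maxent_model`.
#' @export
maxent_model <- function(h, J, taxa = NULL, diagnostics = NULL) {
  J <- as.matrix(J)
  S <- length(h)
  stopifnot(all(dim(J) == c(S, S)))
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-10))) {
    stop("J must be symmetric")
  }
  if (any(diag(J) != 0)) stop("J must have a zero diagonal")
  if (is.null(taxa)) taxa <- names(h) %||% sprintf("T%02d", seq_len(S))
  structure(list(h = as.numeric(h), J = J, S = S, taxa = taxa,
                 diagnostics = diagnostics),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("Pairwise maximum-entropy model over", x$S, "taxa\n")
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  fit: %d iterations, max |log moment ratio| %.3g\n",
                x$diagnostics$iterations, x$diagnostics$max_discrepancy))
  }
  invisible(x)
}

# all 2^S binary states as a matrix (row k = state with bit pattern k-1;
# column i is bit i, the lowest-order bit first)
all_states <- function(S) {
  if (S > 20) stop("state enumeration is limited to S <= 20")
  k <- 0:(2^S - 1)
  m <- matrix(0L, length(k), S)
  for (i in seq_len(S)) m[, i] <- bitwAnd(k, bitwShiftL(1L, i - 1L)) > 0L
  storage.mode(m) <- "integer"
  m
}

state_to_index <- function(state) {
  sum(bitwShiftL(1L, which(state > 0) - 1L)) + 1L
}

#' Energy of a community state
#'
#' @param state 0/1 vector of length S.
#' @param model a [maxent_model()].
#' @return scalar energy H(state).
#' @export
state_energy <- function(state, model) {
  stopifnot(inherits(model, "maxent_model"))
  if (length(state) != model$S) {
    stop("state has length ", length(state), ", model expects ", model$S)
  }
  s <- as.numeric(state)
  -sum(model$h * s) - 0.5 * sum(s * (model$J %*% s))
}

# energies of all 2^S states, vectorized
all_energies <- function(model, states = all_states(model$S)) {
  st <- states * 1.0
  as.numeric(-(st %*% model$h) - 0.5 * rowSums((st %*% model$J) * st))
}

#' Exact stationary distribution over all community states
#'
#' @param model a [maxent_model()] with S <= 20 taxa.
#' @return probability vector over the 2^S states in [all_states()] row
#'   order (state k has bit pattern k-1).
#' @export
state_probabilities <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  if (model$S > 20) stop("exact enumeration is limited to S <= 20 taxa")
  e <- all_energies(model)
  w <- exp(-(e - min(e)))
  w / sum(w)
}

#' Binarize a calibrated abundance table for energy-landscape analysis
#'
#' Presence is abundance strictly greater than `presence_threshold` (the
#' value 0 in the result does not necessarily mean complete absence — it may
#' reflect non-detection). Taxa observed in fewer than `lower` or more than
#' `upper` of the samples carry little landscape information and are dropped
#' (bounds inclusive).
#'
#' @param table calibrated abundance table.
#' @param lower,upper occurrence-frequency retention window (defaults 0.02
#'   and 0.98).
#' @param presence_threshold abundance above which a taxon counts as present.
#' @return object of class `binary_community`: list with `matrix`
#'   (samples x taxa 0/1), `taxa`, and `samples` (treatment, replicate, day).
#' @export
binarize <- function(table, lower = 0.02, upper = 0.98,
                     presence_threshold = 0) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(table)[c("treatment", "replicate", "day", "taxon",
                               "abundance")],
    names_from = "taxon", values_from = "abundance", values_fill = 0)
  info <- wide[c("treatment", "replicate", "day")]
  m <- as.matrix(wide[setdiff(names(wide), names(info))])
  b <- (m > presence_threshold) * 1L
  freq <- colMeans(b)
  keep <- freq >= lower & freq <= upper
  if (!any(keep)) stop("no taxa fall inside the occurrence window [",
                       lower, ", ", upper, "]")
  structure(list(matrix = b[, keep, drop = FALSE],
                 taxa = colnames(b)[keep], samples = info),
            class = "binary_community")
}

#' Fit the pairwise maximum-entropy model by iterative moment matching
#'
#' Gradient-descent updates
#' h_i <- h_i + alpha log(<sigma_i> / <sigma_i>*) and
#' J_ij <- J_ij + alpha log(<sigma_i sigma_j> / <sigma_i sigma_j>*), where
#' starred moments come from exact enumeration of the current model and
#' unstarred moments from the data. Empirical moments are regularized as
#' (count + 0.5)/(n + 1) so that never-(co)occurring pairs keep updates
#' finite.
#'
#' @param data a `binary_community` or a samples x taxa 0/1 matrix.
#' @param learning_rate update step alpha (default 0.1).
#' @param max_iter iteration cap (default 50000).
#' @param tol stop when max |log moment ratio| < tol (default 1e-4).
#' @return a [maxent_model()] with `diagnostics` (iterations,
#'   max_discrepancy, converged).
#' @export
fit_maxent <- function(data, learning_rate = 0.1, max_iter = 50000,
                       tol = 1e-4) {
  x <- if (inherits(data, "binary_community")) data$matrix else as.matrix(data)
  taxa <- colnames(x) %||% sprintf("T%02d", seq_len(ncol(x)))
  if (!all(x %in% c(0, 1))) stop("data must be binary")
  S <- ncol(x)
  if (S > 20) stop("fitting by exact enumeration is limited to S <= 20 taxa")
  n <- nrow(x)
  # regularized empirical first and second moments
  emp1 <- (colSums(x) + 0.5) / (n + 1)
  emp2 <- (crossprod(x) + 0.5) / (n + 1)
  states <- all_states(S)
  st <- states * 1.0
  h <- log(emp1 / (1 - emp1))   # independent-taxon start
  J <- matrix(0, S, S)
  upper <- upper.tri(J)
  iter <- 0L
  disc <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    e <- -(st %*% h) - 0.5 * rowSums((st %*% J) * st)
    w <- exp(-(e - min(e)))
    p <- as.numeric(w / sum(w))
    mod1 <- as.numeric(crossprod(st, p))
    mod2 <- crossprod(st * p, st)
    lr1 <- log(emp1 / mod1)
    lr2 <- log(emp2 / mod2)
    disc <- max(abs(lr1), abs(lr2[upper]))
    if (!is.finite(disc)) {
      stop("maxent fit diverged at iteration ", iter)
    }
    if (disc < tol) break
    h <- h + learning_rate * lr1
    step <- learning_rate * lr2
    J[upper] <- J[upper] + step[upper]
    J[lower.tri(J)] <- t(J)[lower.tri(J)]
    if (any(!is.finite(h)) || any(!is.finite(J))) {
      stop("maxent fit diverged at iteration ", iter)
    }
  }
  maxent_model(h, J, taxa = taxa,
               diagnostics = list(iterations = iter, max_discrepancy = disc,
                                  converged = disc < tol))
}

# indices of the S single-bit-flip neighbors of state index k (1-based)
flip_neighbors <- function(k, S) {
  bitwXor(k - 1L, bitwShiftL(1L, 0:(S - 1L))) + 1L
}

#' Stable states (energy minima) of the landscape
#'
#' A state is a stable state iff its energy is strictly lower than the energy
#' of all S single-taxon-flip neighbors on the assembly graph.
#'
#' @param model a [maxent_model()] with S <= 20.
#' @return integer matrix of minima (rows = states), possibly with 0 rows.
#' @export
find_stable_states <- function(model) {
  lE <- landscape_energies(model)
  all_states(model$S)[lE$is_minimum, , drop = FALSE]
}

# energies + strict-minimum flags for all states
landscape_energies <- function(model) {
  S <- model$S
  e <- all_energies(model)
  is_min <- rep(TRUE, length(e))
  for (i in seq_len(S)) {
    nb <- bitwXor(seq_along(e) - 1L, bitwShiftL(1L, i - 1L)) + 1L
    is_min <- is_min & (e < e[nb])
  }
  list(energy = e, is_minimum = is_min)
}

#' Steepest-descent basin of a community state
#'
#' Repeatedly moves to the single-flip neighbor with the lowest energy while
#' that energy is strictly lower than the current one; ties among equally
#' lowest neighbors are broken toward the lowest flipped-bit index.
#'
#' @param state 0/1 vector of length S.
#' @param model a [maxent_model()].
#' @return the terminal 0/1 state (the basin's minimum).
#' @export
basin_of <- function(state, model) {
  e <- all_energies(model)
  idx <- descend_index(state_to_index(state), e, model$S)
  all_states(model$S)[idx, ]
}

# steepest descent on precomputed energies; returns terminal state index
descend_index <- function(k, energies, S) {
  repeat {
    nb <- flip_neighbors(k, S)
    best <- which.min(energies[nb])   # which.min takes the first (lowest bit)
    if (energies[nb[best]] < energies[k]) k <- nb[best] else return(k)
  }
}

#' Full landscape summary: energies, minima, basin labels
#'
#' @param model a [maxent_model()] with S <= 20 (basin labelling intended for
#'   S <= 12).
#' @return tibble with one row per state: `state` (bitstring, taxon 1 first),
#'   `energy`, `is_minimum`, `basin` (bitstring of the basin's minimum).
#' @export
enumerate_landscape <- function(model) {
  S <- model$S
  lE <- landscape_energies(model)
  states <- all_states(S)
  basin_idx <- integer(length(lE$energy))
  for (k in seq_along(basin_idx)) {
    basin_idx[k] <- descend_index(k, lE$energy, S)
  }
  bits <- apply(states, 1, paste, collapse = "")
  tibble::tibble(state = bits, energy = lE$energy,
                 is_minimum = lE$is_minimum, basin = bits[basin_idx])
}

#' Energy gap of a community state
#'
#' The energy of the current state minus the energy of the minimum of its
#' basin of attraction: how far the community is "inflated" above its local
#' optimum. Always nonnegative.
#'
#' @inheritParams basin_of
#' @return nonnegative scalar.
#' @export
energy_gap <- function(state, model) {
  e <- all_energies(model)
  k <- state_to_index(state)
  e[k] - e[descend_index(k, e, model$S)]
}

#' Stable-state entropy of a community state
#'
#' Runs `n_walks` stochastic walks from the state: each step proposes a
#' uniformly random single-taxon flip and accepts it with Metropolis
#' probability min(1, exp(-deltaH)). A walk stops when it reaches a strict
#' energy minimum, or after `max_steps` steps (the terminal state is then
#' mapped to its basin minimum by steepest descent). The index is the Shannon
#' entropy (nats) of the distribution of destination minima: 0 when every
#' walk ends in the same basin, up to log(#minima) when the state sits on a
#' ridge between several basins.
#'
#' @inheritParams basin_of
#' @param n_walks number of walks (default 1000).
#' @param max_steps step cap per walk (default 1000).
#' @param seed integer seed.
#' @return nonnegative scalar entropy (nats).
#' @export
stable_state_entropy <- function(state, model, n_walks = 1000,
                                 max_steps = 1000, seed = 1) {
  stopifnot(n_walks >= 1)
  S <- model$S
  lE <- landscape_energies(model)
  if (!any(lE$is_minimum)) stop("landscape has no strict energy minimum")
  set.seed(as.integer(seed))
  e <- lE$energy
  start <- state_to_index(state)
  dest <- integer(n_walks)
  for (w in seq_len(n_walks)) {
    k <- start
    steps <- 0L
    while (!lE$is_minimum[k] && steps < max_steps) {
      i <- sample.int(S, 1L)
      nb <- bitwXor(k - 1L, bitwShiftL(1L, i - 1L)) + 1L
      dH <- e[nb] - e[k]
      if (dH <= 0 || stats::runif(1) < exp(-dH)) k <- nb
      steps <- steps + 1L
    }
    if (!lE$is_minimum[k]) k <- descend_index(k, e, S)
    dest[w] <- k
  }
  q <- tabulate(factor(dest)) / n_walks
  -sum(q * log(q))
}

#' Serialize a maxent model to JSON
#'
#' @param model a [maxent_model()].
#' @param path output file.
#' @export
write_maxent_model <- function(model, path) {
  ut <- which(upper.tri(model$J), arr.ind = TRUE)
  jsonlite::write_json(
    list(taxa = model$taxa, h = model$h,
         J_upper = data.frame(i = ut[, 1], j = ut[, 2],
                              value = model$J[ut]),
         diagnostics = model$diagnostics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
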