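#' Convergent cross-mapping screen for causal drivers
#'
#' Cross-maps from the target taxon's delay embedding to each candidate
#' taxon's contemporaneous values at increasing library sizes. A candidate
#' is accepted as causally coupled ("converged") when cross-map skill rho
#' increases with library size by at least `margin` and exceeds `min_rho` at
#' the largest library.
#'
#' @param table abundance table for one replicate (or a day-by-taxon
#'   matrix).
#' @param target target taxon id.
#' @param candidates candidate driver taxa (default: all others).
#' @param lib_sizes library sizes to evaluate (default: from E + 2 to the
#'   full series in 4 steps).
#' @param E embedding dimension of the target (default 2).
#' @param n_draws random library draws per size (default 30).
#' @param margin,min_rho convergence margin on rho and minimum final rho
#'   (defaults 0.1 and 0.2).
#' @param seed integer seed.
#' @return tibble (target, driver, rho_min, rho_max, converged), ranked by
#'   rho_max.
#' @export
ccm_screen <- function(table, target, candidates = NULL, lib_sizes = NULL,
                       E = 2, n_draws = 30, margin = 0.1, min_rho = 0.2,
                       seed = 1) {
  m <- if (is.matrix(table)) table else abundance_matrix(table)
  stopifnot(target %in% colnames(m))
  candidates <- candidates %||% setdiff(colnames(m), target)
  x <- zstandardize(m[, target])$z
  emb <- make_embedding(list(target = x), E)
  n_pts <- nrow(emb$points)
  lib_sizes <- lib_sizes %||%
    unique(round(seq(E + 2, n_pts, length.out = 4)))
  if (max(lib_sizes) > n_pts) {
    stop("largest library size ", max(lib_sizes), " exceeds the ", n_pts,
         " available embedding points")
  }
  set.seed(as.integer(seed))
  out <- list()
  for (cand in candidates) {
    y <- zstandardize(m[, cand])$z
    y_at <- y[emb$time]   # candidate values aligned to embedding points
    rho_by_L <- vapply(lib_sizes, function(L) {
      rhos <- vapply(seq_len(n_draws), function(dr) {
        lib <- sample.int(n_pts, L)
        pred <- vapply(seq_len(n_pts), function(i) {
          use <- setdiff(lib, i)
          if (length(use) < E + 1) return(NA_real_)
          d <- sqrt(colSums((t(emb$points[use, , drop = FALSE]) -
                             emb$points[i, ])^2))
          nn <- use[order(d)[seq_len(E + 1)]]
          dnn <- sort(d)[seq_len(E + 1)]
          if (dnn[1] == 0) return(mean(y_at[nn[dnn == 0]]))
          w <- exp(-dnn / dnn[1])
          sum(w * y_at[nn]) / sum(w)
        }, numeric(1))
        ok <- !is.na(pred) & !is.na(y_at)
        if (sum(ok) < 3 || stats::sd(y_at[ok]) == 0 ||
            stats::sd(pred[ok]) == 0) NA_real_
        else stats::cor(pred[ok], y_at[ok])
      }, numeric(1))
      mean(rhos, na.rm = TRUE)
    }, numeric(1))
    rho_min <- rho_by_L[1]
    rho_max <- rho_by_L[length(rho_by_L)]
    out[[cand]] <- tibble::tibble(
      target = target, driver = cand, rho_min = rho_min, rho_max = rho_max,
      converged = is.finite(rho_min) && is.finite(rho_max) &&
        (rho_max - rho_min >= margin) && rho_max > min_rho)
  }
  res <- dplyr::bind_rows(out)
  res[order(-res$rho_max), , drop = FALSE]
}

#' Per-time-point Jacobians by multivariate S-map
#'
#' For each target time t, fits for every taxon i a locally weighted linear
#' model of x_i(t+1) on the full state vector (x_1(t), ..., x_m(t)), with
#' S-map weights w(d) = exp(-theta d / dbar) centred on the state at time t.
#' Row i of the Jacobian J(t) is the fitted coefficient vector (intercept
#' excluded), estimating the partial derivatives dx_i(t+1)/dx_j(t).
#'
#' @param x multivariate series: a time x m numeric matrix (one replicate
#'   block), or a list of such matrices (reference blocks).
#' @param theta S-map nonlinearity (default 0: one global regression).
#' @param reference optional list of reference blocks; when NULL the rows of
#'   `x` other than the target time serve as reference (leave-one-out).
#' @return object of class `jacobian_series`: list with `J` (list of m x m
#'   matrices, one per usable time), `time` (target time indices), `taxa`,
#'   `theta`.
#' @export
multivariate_smap_jacobian <- function(x, theta = 0, reference = NULL) {
  x <- as.matrix(x)
  m <- ncol(x)
  taxa <- colnames(x) %||% sprintf("V%d", seq_len(m))
  blocks <- if (is.null(reference)) list(x) else reference
  # design rows: state at t' ; responses: states at t' + 1, per block
  states <- do.call(rbind, lapply(blocks, function(b) {
    b <- as.matrix(b)
    b[-nrow(b), , drop = FALSE]
  }))
  nexts <- do.call(rbind, lapply(blocks, function(b) {
    b <- as.matrix(b)
    b[-1, , drop = FALSE]
  }))
  self_ref <- is.null(reference)
  keep <- rowSums(is.na(cbind(states, nexts))) == 0
  times <- seq_len(nrow(x) - 1)
  Js <- list()
  kept_t <- integer()
  for (t in times) {
    tv <- x[t, ]
    if (any(is.na(tv)) || any(is.na(x[t + 1, ]))) next
    use <- keep
    if (self_ref) use[t] <- FALSE   # drop the target's own transition
    if (sum(use) < m + 2) next
    S <- states[use, , drop = FALSE]
    N <- nexts[use, , drop = FALSE]
    d <- sqrt(rowSums(sweep(S, 2, tv)^2))
    dbar <- mean(d)
    if (dbar == 0) next
    w <- exp(-theta * d / dbar)
    A <- cbind(w, S * w)
    J <- matrix(NA_real_, m, m, dimnames = list(taxa, taxa))
    for (i in seq_len(m)) {
      C <- svd_solve(A, w * N[, i])
      J[i, ] <- C[-1]
    }
    Js[[length(Js) + 1L]] <- J
    kept_t <- c(kept_t, t)
  }
  if (length(Js) == 0) stop("no usable time points: shrink the taxon set ",
                            "or supply longer reference series")
  structure(list(J = Js, time = kept_t, taxa = taxa, theta = theta),
            class = "jacobian_series")
}

#' Local Lyapunov stability of a Jacobian
#'
#' The absolute value of the dominant eigenvalue of the time-t Jacobian:
#' values below 1 mean locally converging trajectories, values above 1
#' locally diverging ones, making 1 the theoretical tipping value.
#'
#' @param J square numeric matrix (or one element of a `jacobian_series`).
#' @return nonnegative scalar.
#' @export
local_lyapunov_stability <- function(J) {
  J <- as.matrix(J)
  stopifnot(nrow(J) == ncol(J))
  if (any(!is.finite(J))) stop("Jacobian contains non-finite entries")
  max(Mod(eigen(J, only.values = TRUE)$values))
}

#' Local structural stability of a Jacobian
#'
#' The trace (sum of diagonal elements) of the time-t Jacobian, a
#' community-level summary of self-regulation strength.
#'
#' @inheritParams local_lyapunov_stability
#' @return scalar trace.
#' @export
local_structural_stability <- function(J) {
  J <- as.matrix(J)
  stopifnot(nrow(J) == ncol(J))
  if (any(!is.finite(J))) stop("Jacobian contains non-finite entries")
  sum(diag(J))
}

#' Per-day stability indices for every replicate of a treatment
#'
#' Selects the `m` most abundant taxa (by mean relative abundance), embeds
#' their z-standardized joint dynamics, and estimates per-day Jacobians by
#' multivariate S-map with reference databases drawn from the other
#' replicates (leave-one-replicate-out). Optionally the taxon set is first
#' intersected with CCM-converged interactions.
#'
#' @param table abundance table.
#' @param treatment treatment to analyse (default: the table's only one).
#' @param m number of taxa entering the Jacobian (default 8, capped at the
#'   available taxa).
#' @param theta S-map nonlinearity (default 0).
#' @param ccm_filter if TRUE, drop taxa with no CCM-converged link to any
#'   other selected taxon (default FALSE; the screen is expensive).
#' @param seed seed for the CCM screen.
#' @return tibble (treatment, replicate, day, lyapunov, structural, m,
#'   theta).
#' @export
stability_series <- function(table, treatment = NULL, m = 8, theta = 0,
                             ccm_filter = FALSE, seed = 1) {
  tab <- tibble::as_tibble(table)
  if (is.null(treatment)) {
    trts <- unique(tab$treatment)
    if (length(trts) > 1) stop("several treatments present; pass `treatment`")
    treatment <- trts
  }
  tab <- tab[tab$treatment == treatment, , drop = FALSE]
  reps <- sort(unique(tab$replicate))
  if (length(reps) < 2) stop("need >= 2 replicates for cross-replicate ",
                             "Jacobian references")
  mats <- split_replicates(tab)
  # taxon set: top-m by mean relative abundance across all samples
  rel <- do.call(rbind, lapply(mats, relative_composition))
  sel <- names(sort(colMeans(rel, na.rm = TRUE), decreasing = TRUE))
  sel <- sel[seq_len(min(m, length(sel)))]
  if (ccm_filter && length(sel) > 1) {
    keep <- vapply(sel, function(tx) {
      res <- ccm_screen(mats[[reps[1]]][, sel, drop = FALSE], tx, seed = seed)
      any(res$converged)
    }, logical(1))
    if (any(keep)) sel <- sel[keep]
  }
  zmats <- lapply(mats, function(mm) {
    zz <- vapply(sel, function(tx) zstandardize(mm[, tx])$z,
                 numeric(nrow(mm)))
    matrix(zz, ncol = length(sel), dimnames = list(rownames(mm), sel))
  })
  out <- list()
  for (target in reps) {
    refs <- zmats[setdiff(reps, target)]
    js <- multivariate_smap_jacobian(zmats[[target]], theta = theta,
                                     reference = refs)
    days <- as.integer(rownames(zmats[[target]]))[js$time]
    out[[target]] <- tibble::tibble(
      treatment = treatment, replicate = target, day = days,
      lyapunov = vapply(js$J, local_lyapunov_stability, numeric(1)),
      structural = vapply(js$J, local_structural_stability, numeric(1)),
      m = length(sel), theta = theta)
  }
  dplyr::bind_rows(out)
}
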