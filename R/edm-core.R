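#' z-standardize a series
#'
#' Variables are z-standardized (zero mean, unit variance) within each
#' (taxon, replicate) series before embedding. A constant series maps to
#' all zeros and is flagged; such series carry no dynamical information and
#' are excluded from embeddings by the orchestration layer.
#'
#' @param x numeric vector (may contain NA).
#' @return list with `z`, `mean`, `sd`, `constant` (logical flag).
#' @export
zstandardize <- function(x) {
  stopifnot(length(x) >= 2)
  mu <- mean(x, na.rm = TRUE)
  sdev <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(sdev) || sdev == 0) {
    return(list(z = ifelse(is.na(x), NA_real_, 0), mean = mu, sd = 0,
                constant = TRUE))
  }
  list(z = (x - mu) / sdev, mean = mu, sd = sdev, constant = FALSE)
}

#' Invert a z-transform
#'
#' @param z standardized values.
#' @param std a [zstandardize()] result.
#' @return values on the original scale.
#' @export
unstandardize <- function(z, std) {
  if (std$constant) rep(std$mean, length(z)) else z * std$sd + std$mean
}

#' Takens time-delay embedding of replicate series
#'
#' Builds E-dimensional delay vectors z(t) = (x(t), x(t-tau), ...,
#' x(t-(E-1)tau)) independently within each replicate series; no embedding
#' vector ever spans a replicate boundary.
#'
#' @param series named list of numeric vectors (one per replicate), indexed
#'   by consecutive time steps.
#' @param E embedding dimension.
#' @param tau time delay (default 1).
#' @return object of class `mb_embedding`: list with `E`, `tau`, `points`
#'   (n x E matrix), `replicate`, `time`, `series`.
#' @export
make_embedding <- function(series, E, tau = 1) {
  stopifnot(E >= 1, tau >= 1, is.list(series), !is.null(names(series)))
  pts <- list()
  reps <- character()
  times <- integer()
  for (r in names(series)) {
    x <- series[[r]]
    tt <- seq.int(1 + (E - 1) * tau, length(x))
    if (length(tt) == 0) next
    lagmat <- vapply(0:(E - 1), function(l) x[tt - l * tau], numeric(length(tt)))
    lagmat <- matrix(lagmat, ncol = E)
    ok <- rowSums(is.na(lagmat)) == 0
    if (!any(ok)) next
    pts[[r]] <- lagmat[ok, , drop = FALSE]
    reps <- c(reps, rep(r, sum(ok)))
    times <- c(times, tt[ok])
  }
  if (length(pts) == 0) stop("series too short for an E = ", E, " embedding")
  structure(list(E = E, tau = tau, points = do.call(rbind, pts),
                 replicate = reps, time = times, series = series),
            class = "mb_embedding")
}

# futures z1(t + p) for every embedding point; NA when unavailable
embedding_futures <- function(emb, p) {
  vapply(seq_along(emb$time), function(i) {
    x <- emb$series[[emb$replicate[i]]]
    t2 <- emb$time[i] + p
    if (t2 >= 1 && t2 <= length(x)) x[t2] else NA_real_
  }, numeric(1))
}

#' Simplex projection forecast of one target point
#'
#' Finds the E + 1 nearest reference points by Euclidean distance and
#' predicts the target's p-step future as their weighted average of p-step
#' futures, with weights w_i = exp(-d_i / d_min) where d_min is the distance
#' to the nearest neighbor. If the target coincides with reference points
#' (d_min = 0), those points share uniform weight and all others get zero.
#'
#' @param target numeric vector of length E (delay coordinates).
#' @param reference an [make_embedding()] object.
#' @param p forecast horizon in steps.
#' @param exclude optional logical vector marking reference points to omit
#'   (e.g. the target itself in leave-one-out evaluation).
#' @return predicted scalar.
#' @export
simplex_project <- function(target, reference, p, exclude = NULL) {
  stopifnot(inherits(reference, "mb_embedding"),
            length(target) == reference$E)
  fut <- embedding_futures(reference, p)
  ok <- !is.na(fut)
  if (!is.null(exclude)) ok <- ok & !exclude
  if (sum(ok) < reference$E + 1) {
    stop("need at least E + 1 = ", reference$E + 1,
         " reference points with available futures; have ", sum(ok))
  }
  pts <- reference$points[ok, , drop = FALSE]
  fut <- fut[ok]
  d <- sqrt(rowSums(sweep(pts, 2, target)^2))
  nn <- order(d)[seq_len(reference$E + 1)]
  dmin <- d[nn[1]]
  if (dmin == 0) {
    zero <- nn[d[nn] == 0]
    return(mean(fut[zero]))
  }
  w <- exp(-d[nn] / dmin)
  sum(w * fut[nn]) / sum(w)
}

#' S-map forecast of one target point
#'
#' Fits a locally weighted linear map predicting z1(t' + p) from the delay
#' coordinates z(t'), with weights w(d) = exp(-theta d / dbar), dbar the
#' mean distance from the target to all usable reference points. The
#' weighted design (with a constant column) is solved by SVD least squares;
#' theta = 0 gives every point weight one, i.e. a single global linear
#' regression.
#'
#' @inheritParams simplex_project
#' @param theta nonlinearity parameter (>= 0).
#' @return list with `prediction`, `coefficients` (C0, C1..CE), `weights`,
#'   `mean_distance`.
#' @export
smap_forecast <- function(target, reference, theta, p, exclude = NULL) {
  stopifnot(inherits(reference, "mb_embedding"),
            length(target) == reference$E, theta >= 0)
  fut <- embedding_futures(reference, p)
  ok <- !is.na(fut)
  if (!is.null(exclude)) ok <- ok & !exclude
  if (sum(ok) < reference$E + 2) {
    stop("too few reference points with available futures for S-map")
  }
  pts <- reference$points[ok, , drop = FALSE]
  fut <- fut[ok]
  d <- sqrt(rowSums(sweep(pts, 2, target)^2))
  dbar <- mean(d)
  if (dbar == 0) stop("degenerate reference: all points coincide with target")
  w <- exp(-theta * d / dbar)
  A <- cbind(w, pts * w)
  b <- w * fut
  C <- svd_solve(A, b)
  list(prediction = as.numeric(C[1] + sum(C[-1] * target)),
       coefficients = as.numeric(C), weights = w, mean_distance = dbar)
}

# minimum-norm least squares via SVD with relative tolerance on singular
# values (small singular directions are zeroed, as in a pseudoinverse)
svd_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  inv_d <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (inv_d * crossprod(sv$u, b))
}

# forecast every valid time point of one target series against a reference
# database; leave-one-out when the target is itself part of the reference
edm_forecast_series <- function(target_name, reference, p = 1,
                                method = c("simplex", "smap"), theta = 0) {
  method <- match.arg(method)
  x <- reference$series[[target_name]]
  if (is.null(x)) stop("target series ", target_name, " not in reference set")
  E <- reference$E
  own <- reference$replicate == target_name
  solo <- all(own)   # single-series case: leave-one-out point exclusion
  idx <- which(own)
  preds <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    t_star <- reference$time[i]
    if (t_star + p > length(x) || is.na(x[t_star + p])) next
    # cross-replicate design: the target replicate never serves as its own
    # reference; with a lone series fall back to leaving out the target point
    excl <- if (solo) own & (reference$time == t_star) else own
    pred <- tryCatch({
      if (method == "simplex") {
        simplex_project(reference$points[i, ], reference, p, exclude = excl)
      } else {
        smap_forecast(reference$points[i, ], reference, theta, p,
                      exclude = excl)$prediction
      }
    }, error = function(e) NA_real_)
    preds[k] <- pred
  }
  tibble::tibble(time = reference$time[idx],
                 predicted = preds,
                 observed = x[reference$time[idx] + p][
                   seq_along(idx)])
}

#' Select the embedding dimension by forecast skill
#'
#' Runs univariate forecasting of the target series for each candidate E and
#' returns the E with the smallest forecast RMSE (ties toward the smallest
#' E). When no external reference is given, the target series itself is used
#' with leave-one-out exclusion.
#'
#' @param series numeric target series (z-standardized).
#' @param reference optional named list of reference series.
#' @param E_range candidate dimensions (default 1:20).
#' @param p forecast horizon used in the pre-run (default 1).
#' @param method `"simplex"` (default) or `"smap"`.
#' @param theta S-map nonlinearity when `method = "smap"`.
#' @return selected E.
#' @export
select_embedding_dimension <- function(series, reference = NULL,
                                       E_range = 1:20, p = 1,
                                       method = "simplex", theta = 0) {
  refs <- reference %||% list()
  refs[["..target"]] <- series
  rmse <- rep(NA_real_, length(E_range))
  for (k in seq_along(E_range)) {
    E <- E_range[k]
    emb <- tryCatch(make_embedding(refs, E), error = function(e) NULL)
    if (is.null(emb)) next
    fc <- tryCatch(
      edm_forecast_series("..target", emb, p = p, method = method,
                          theta = theta),
      error = function(e) NULL)
    if (is.null(fc)) next
    err <- fc$predicted - fc$observed
    if (all(is.na(err))) next
    rmse[k] <- sqrt(mean(err^2, na.rm = TRUE))
  }
  if (all(is.na(rmse))) stop("series too short for any E in the range")
  # ties (including floating-point near-ties) break toward the smallest E
  best <- min(rmse, na.rm = TRUE)
  E_range[which(rmse <= best + 1e-10 * (1 + best))[1]]
}

#' Select the S-map nonlinearity parameter theta
#'
#' Evaluates forecast RMSE over a grid of theta values (default
#' 0, 0.001, 0.01, 0.05, 0.1, 0.2, 0.5, 1, 2, 4, 8) and returns the
#' minimizer; exact ties break toward the smaller theta (i.e. toward
#' linearity).
#'
#' @inheritParams select_embedding_dimension
#' @param E embedding dimension.
#' @param grid candidate theta values, ascending.
#' @return list with `theta` (selected value) and `rmse` (per grid point).
#' @export
optimize_theta <- function(series, reference = NULL, E = 2,
                           grid = c(0, 0.001, 0.01, 0.05, 0.1, 0.2, 0.5,
                                    1, 2, 4, 8),
                           p = 1) {
  refs <- reference %||% list()
  refs[["..target"]] <- series
  emb <- make_embedding(refs, E)
  rmse <- vapply(grid, function(th) {
    fc <- edm_forecast_series("..target", emb, p = p, method = "smap",
                              theta = th)
    err <- fc$predicted - fc$observed
    if (all(is.na(err))) return(NA_real_)
    sqrt(mean(err^2, na.rm = TRUE))
  }, numeric(1))
  if (all(is.na(rmse))) stop("S-map failed for every theta on this series")
  # ties (including floating-point near-ties) break toward linearity
  best <- min(rmse, na.rm = TRUE)
  list(theta = grid[which(rmse <= best + 1e-10 * (1 + best))[1]],
       rmse = rmse, grid = grid)
}

#' Fraction of populations with nonlinear dynamics
#'
#' @param thetas vector of optimized theta values (one per taxon and
#'   replicate).
#' @return proportion with theta > 0.
#' @export
nonlinearity_fraction <- function(thetas) {
  stopifnot(length(thetas) > 0)
  mean(thetas > 0)
}
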