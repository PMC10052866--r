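#' Leave-one-replicate-out population-level forecasting
#'
#' For every target replicate of a treatment, the reference state-space
#' database is built from the other replicates only; the future abundance of
#' every taxon at horizons `horizons` is then forecast by simplex
#' projection, S-map with optimized theta, S-map assuming linearity
#' (theta = 0), and/or a persistence null model that predicts no change.
#' Forecasts are made on the z-standardized scale and returned
#' de-standardized (original copy-concentration scale).
#'
#' @param table abundance table (calibrated, interpolated).
#' @param treatment treatment to analyse (default: the table's only one).
#' @param methods subset of `"simplex"`, `"smap_opt"`, `"smap_linear"`,
#'   `"null"`.
#' @param horizons forecast horizons in days (default 1:7).
#' @param E_range candidate embedding dimensions (default 1:20 in field use;
#'   trimmed in examples for speed).
#' @param theta_grid theta grid for `smap_opt`.
#' @param qc_exclude optional tibble (treatment, replicate, day) of
#'   QC-dropped samples; those days never enter skill statistics.
#' @return object of class `forecast_run`: tibble (treatment,
#'   target_replicate, taxon, day, p, method, theta, E, predicted, observed)
#'   with per-series standardization stored in `attr(, "standards")`.
#' @export
run_population_forecasts <- function(table, treatment = NULL,
                                     methods = c("simplex", "smap_opt",
                                                 "smap_linear", "null"),
                                     horizons = 1:7, E_range = 1:10,
                                     theta_grid = c(0, 0.001, 0.01, 0.05,
                                                    0.1, 0.2, 0.5, 1, 2, 4, 8),
                                     qc_exclude = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  tab <- tibble::as_tibble(table)
  if (is.null(treatment)) {
    trts <- unique(tab$treatment)
    if (length(trts) > 1) stop("several treatments present; pass `treatment`")
    treatment <- trts
  }
  tab <- tab[tab$treatment == treatment, , drop = FALSE]
  reps <- sort(unique(tab$replicate))
  if (length(reps) < 2) {
    stop("leave-one-replicate-out forecasting needs >= 2 replicates")
  }
  taxa <- sort(unique(tab$taxon))
  mats <- split_replicates(tab)
  # z-standardize each (taxon, replicate) series
  stds <- list()
  zser <- list()
  for (r in reps) {
    for (tx in taxa) {
      s <- zstandardize(mats[[r]][, tx])
      stds[[paste(r, tx)]] <- s
      zser[[paste(r, tx)]] <- s$z
    }
  }
  out <- list()
  for (target in reps) {
    others <- setdiff(reps, target)
    for (tx in taxa) {
      if (stds[[paste(target, tx)]]$constant) next
      refs <- lapply(stats::setNames(others, others),
                     function(r) zser[[paste(r, tx)]])
      refs <- refs[!vapply(refs, function(v) all(v == 0 | is.na(v)),
                           logical(1))]
      x <- zser[[paste(target, tx)]]
      days <- as.integer(rownames(mats[[target]]))
      std <- stds[[paste(target, tx)]]
      if (length(refs) == 0) next
      E <- tryCatch(
        select_embedding_dimension(x, refs, E_range = E_range, p = 1),
        error = function(e) NA_integer_)
      if (is.na(E)) next
      theta_opt <- if ("smap_opt" %in% methods) {
        tryCatch(optimize_theta(x, refs, E = E, grid = theta_grid, p = 1)$theta,
                 error = function(e) NA_real_)
      } else NA_real_
      refs_t <- c(refs, list(..target = x))
      emb <- make_embedding(refs_t, E)
      for (ph in horizons) {
        for (method in methods) {
          fc <- switch(method,
            null = {
              tt <- seq_len(length(x) - ph)
              tibble::tibble(time = tt, predicted = x[tt],
                             observed = x[tt + ph])
            },
            simplex = edm_forecast_series("..target", emb, p = ph,
                                          method = "simplex"),
            smap_opt = if (is.na(theta_opt)) NULL else
              edm_forecast_series("..target", emb, p = ph, method = "smap",
                                  theta = theta_opt),
            smap_linear = edm_forecast_series("..target", emb, p = ph,
                                              method = "smap", theta = 0))
          if (is.null(fc) || nrow(fc) == 0) next
          theta_used <- switch(method, smap_opt = theta_opt,
                               smap_linear = 0, NA_real_)
          E_used <- if (method == "null") NA_integer_ else E
          out[[length(out) + 1L]] <- tibble::tibble(
            treatment = treatment, target_replicate = target, taxon = tx,
            day = days[fc$time], p = ph, method = method,
            theta = theta_used,
            E = E_used,
            predicted = unstandardize(fc$predicted, std),
            observed = unstandardize(fc$observed, std))
        }
      }
    }
  }
  run <- dplyr::bind_rows(out)
  if (!is.null(qc_exclude)) {
    bad <- paste(qc_exclude$treatment, qc_exclude$replicate, qc_exclude$day)
    run <- run[!(paste(run$treatment, run$target_replicate,
                       run$day + run$p) %in% bad), , drop = FALSE]
  }
  structure(run, standards = stds, class = c("forecast_run", class(run)))
}

#' Forecast skill per taxon, replicate, method and horizon
#'
#' R^2 is the coefficient of determination 1 - SS_res / SS_tot of predicted
#' against observed abundance (it can be negative for forecasts worse than
#' the observed mean).
#'
#' @param run a [run_population_forecasts()] result.
#' @return tibble (treatment, target_replicate, taxon, method, p, n, r2).
#' @export
forecast_r2 <- function(run) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(run), .data$treatment,
                    .data$target_replicate, .data$taxon, .data$method,
                    .data$p),
    n = sum(!is.na(.data$predicted) & !is.na(.data$observed)),
    r2 = {
      ok <- !is.na(.data$predicted) & !is.na(.data$observed)
      sst <- sum((.data$observed[ok] - mean(.data$observed[ok]))^2)
      if (sum(ok) < 3 || sst == 0) NA_real_ else
        1 - sum((.data$observed[ok] - .data$predicted[ok])^2) / sst
    },
    .groups = "drop")
}

#' Assemble per-taxon forecasts into community-level predictions
#'
#' Per-taxon predicted copy concentrations are compiled per (target
#' replicate, day, horizon, method), floored at zero, and renormalized to a
#' predicted relative composition; the community-level error is the
#' Bray-Curtis dissimilarity between predicted and observed compositions.
#'
#' @param run a [run_population_forecasts()] result.
#' @return tibble (treatment, target_replicate, day, p, method, error,
#'   n_taxa, degenerate) where `day` is the forecast target day (t + p) and
#'   `degenerate` flags days whose predicted composition was all zero
#'   (error undefined, NA).
#' @export
assemble_community_forecast <- function(run) {
  tab <- tibble::as_tibble(run)
  tab$target_day <- tab$day + tab$p
  grp <- dplyr::group_by(tab, .data$treatment, .data$target_replicate,
                         .data$target_day, .data$p, .data$method)
  dplyr::rename(dplyr::summarise(grp, error = {
    pred <- pmax(.data$predicted, 0)
    obs <- pmax(.data$observed, 0)   # guard de-standardization round-off
    ok <- !is.na(pred) & !is.na(obs)
    if (sum(ok) == 0 || sum(pred[ok]) == 0 || sum(obs[ok]) == 0) NA_real_
    else bray_curtis(relative_composition(pred[ok]),
                     relative_composition(obs[ok]))
  },
  n_taxa = sum(!is.na(.data$predicted)),
  degenerate = sum(pmax(.data$predicted, 0), na.rm = TRUE) == 0,
  .groups = "drop"), day = "target_day")
}

#' Forecast skill as a function of reference-database size
#'
#' For each target replicate and each reference-set size k, evaluates S-map
#' forecast skill over all C(R-1, k) subsets of the other replicates.
#'
#' @param table abundance table.
#' @param treatment treatment to analyse.
#' @param sizes reference-set sizes (default 1:(R-1)).
#' @param targets optional subset of target replicates.
#' @param E embedding dimension (fixed across subsets for comparability).
#' @param theta S-map theta (default 0).
#' @param p forecast horizon (default 1).
#' @return tibble (treatment, target_replicate, taxon, k, subset, n, r2).
#' @export
reference_size_experiment <- function(table, treatment = NULL, sizes = NULL,
                                      targets = NULL, E = 3, theta = 0,
                                      p = 1) {
  tab <- tibble::as_tibble(table)
  if (!is.null(treatment)) tab <- tab[tab$treatment == treatment, ]
  treatment <- unique(tab$treatment)
  stopifnot(length(treatment) == 1)
  reps <- sort(unique(tab$replicate))
  if (length(reps) < 2) stop("need >= 2 replicates")
  sizes <- sizes %||% seq_len(length(reps) - 1)
  targets <- targets %||% reps
  taxa <- sort(unique(tab$taxon))
  mats <- split_replicates(tab)
  zser <- list()
  const <- list()
  for (r in reps) for (tx in taxa) {
    s <- zstandardize(mats[[r]][, tx])
    zser[[paste(r, tx)]] <- s$z
    const[[paste(r, tx)]] <- s$constant
  }
  out <- list()
  for (target in targets) {
    others <- setdiff(reps, target)
    for (k in sizes) {
      subsets <- utils::combn(others, k, simplify = FALSE)
      for (si in seq_along(subsets)) {
        for (tx in taxa) {
          if (const[[paste(target, tx)]]) next
          refs <- lapply(stats::setNames(subsets[[si]], subsets[[si]]),
                         function(r) zser[[paste(r, tx)]])
          refs[["..target"]] <- zser[[paste(target, tx)]]
          fc <- tryCatch({
            emb <- make_embedding(refs, E)
            edm_forecast_series("..target", emb, p = p, method = "smap",
                                theta = theta)
          }, error = function(e) NULL)
          if (is.null(fc)) next
          ok <- !is.na(fc$predicted) & !is.na(fc$observed)
          sst <- sum((fc$observed[ok] - mean(fc$observed[ok]))^2)
          out[[length(out) + 1L]] <- tibble::tibble(
            treatment = treatment, target_replicate = target, taxon = tx,
            k = k, subset = si, n = sum(ok),
            r2 = if (sum(ok) < 3 || sst == 0) NA_real_ else
              1 - sum((fc$observed[ok] - fc$predicted[ok])^2) / sst)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}
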