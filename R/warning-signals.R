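#' Pair warning indices with realized future abruptness
#'
#' Joins each per-day warning index value (energy gap, stable-state entropy,
#' local Lyapunov stability, local structural stability, ...) at day t with
#' the realized abruptness at horizon p starting at t, yielding the series
#' on which regressions and ROC analysis operate.
#'
#' @param indices tibble (treatment, replicate, day, <index columns>) in
#'   wide form: every column other than the key columns is treated as a
#'   warning index.
#' @param abrupt an [abruptness_series()] result.
#' @param p horizon to pair with (default 7).
#' @param qc_exclude optional tibble (treatment, replicate, day) of days to
#'   drop.
#' @return tibble (treatment, replicate, day, index, value, abruptness,
#'   is_abrupt), long over indices.
#' @export
build_signal_series <- function(indices, abrupt, p = 7, qc_exclude = NULL) {
  ab <- abrupt[abrupt$p == p, c("treatment", "replicate", "t", "abruptness",
                                "is_abrupt")]
  names(ab)[names(ab) == "t"] <- "day"
  idx_cols <- setdiff(names(indices), c("treatment", "replicate", "day"))
  if (length(idx_cols) == 0) stop("`indices` has no index columns")
  long <- tidyr::pivot_longer(indices, dplyr::all_of(idx_cols),
                              names_to = "index", values_to = "value")
  joined <- dplyr::inner_join(long, ab,
                              by = c("treatment", "replicate", "day"))
  if (!is.null(qc_exclude) && nrow(qc_exclude) > 0) {
    bad <- paste(qc_exclude$treatment, qc_exclude$replicate, qc_exclude$day)
    joined <- joined[!(paste(joined$treatment, joined$replicate,
                             joined$day) %in% bad), , drop = FALSE]
  }
  joined <- joined[!is.na(joined$value) & !is.na(joined$abruptness), ,
                   drop = FALSE]
  if (nrow(joined) == 0) stop("no days where indices and abruptness overlap")
  joined
}

#' Per-replicate regressions of abruptness on each warning index
#'
#' Ordinary least squares of abruptness ~ index within each (treatment,
#' replicate, index), with Benjamini-Hochberg false-discovery-rate
#' adjustment across all replicate x index regressions within each
#' treatment. A zero-variance index gives an undefined regression (NA).
#'
#' @param series a [build_signal_series()] result.
#' @param alpha FDR significance level (default 0.05).
#' @return tibble (treatment, replicate, index, n, slope, p_value, q_value,
#'   significant).
#' @export
regress_signal <- function(series, alpha = 0.05) {
  tab <- tibble::as_tibble(series)
  groups <- split(tab, paste(tab$treatment, tab$replicate, tab$index,
                             sep = "\r"))
  res <- dplyr::bind_rows(lapply(groups, function(g) {
    row <- tibble::tibble(treatment = g$treatment[1L],
                          replicate = g$replicate[1L], index = g$index[1L],
                          n = nrow(g), slope = NA_real_, p_value = NA_real_)
    if (nrow(g) >= 3 && stats::sd(g$value) > 0 &&
        stats::sd(g$abruptness) > 0) {
      # suppressWarnings: a perfect fit (index == abruptness) is legitimate
      fit <- suppressWarnings(
        summary(stats::lm(abruptness ~ value, data = g)))
      row$slope <- fit$coefficients[2, 1]
      row$p_value <- fit$coefficients[2, 4]
    } else if (nrow(g) >= 3 && stats::sd(g$value) > 0) {
      # perfect-fit degenerate case: constant response
      fit <- stats::lm(abruptness ~ value, data = g)
      row$slope <- stats::coef(fit)[2]
      row$p_value <- NA_real_
    }
    row
  }))
  res <- dplyr::mutate(dplyr::group_by(res, .data$treatment),
                       q_value = stats::p.adjust(.data$p_value, "BH"))
  dplyr::ungroup(dplyr::mutate(res, significant = .data$q_value < alpha))
}

#' ROC analysis of a warning index
#'
#' Sweeps thresholds over the score range with the convention "predict an
#' abrupt event when score >= threshold" (all indices signal instability
#' when high). Candidate thresholds are the midpoints between adjacent
#' distinct scores, plus one below the minimum and one above the maximum.
#' The AUC is computed by the trapezoidal rule and equals the normalized
#' Mann-Whitney U statistic P(score+ > score-) + P(tie)/2.
#'
#' @param scores numeric warning-index values.
#' @param labels logical (or 0/1) event labels; both classes must be
#'   present.
#' @return object of class `roc_curve`: list with `thresholds`,
#'   `sensitivity`, `fpr` (1 - specificity), `auc`, `youden_threshold`,
#'   `youden_j`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC analysis needs both classes; have ", n_pos, " positive and ",
         n_neg, " negative points")
  }
  u <- sort(unique(scores))
  gaps <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else numeric()
  thr <- c(u[1] - 1, gaps, u[length(u)] + 1)
  sens <- vapply(thr, function(th) sum(scores >= th & labels) / n_pos,
                 numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & !labels) / n_neg,
                numeric(1))
  ord <- order(fpr, sens)   # sweep from (0,0) to (1,1)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  j <- sens + (1 - fpr) - 1
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]   # ties -> lower threshold (sensitive)
  structure(list(thresholds = thr, sensitivity = sens, fpr = fpr, auc = auc,
                 youden_threshold = thr[best], youden_j = j[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Youden-optimal threshold of an ROC curve
#'
#' The threshold maximizing J = sensitivity + specificity - 1; exact ties
#' resolve toward the lower (more sensitive) threshold. Thresholds are
#' midpoints between adjacent distinct scores, so a perfectly separating
#' classifier returns the midpoint of the separating gap.
#'
#' @param curve a [roc_analysis()] result.
#' @return scalar threshold.
#' @export
youden_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  curve$youden_threshold
}

#' Pooled diagnostic threshold across treatments
#'
#' Concatenates all (score, label) pairs of the named treatments for one
#' warning index, then runs [roc_analysis()] and returns its Youden
#' threshold together with the pooled curve.
#'
#' @param series a [build_signal_series()] result.
#' @param index index name to threshold.
#' @param treatments treatments to pool (default: all in `series`).
#' @return list with `index`, `treatments`, `curve` (`roc_curve`),
#'   `threshold`, `auc`.
#' @export
pooled_threshold <- function(series, index, treatments = NULL) {
  treatments <- treatments %||% unique(series$treatment)
  sub <- series[series$index == index &
                series$treatment %in% treatments, , drop = FALSE]
  if (nrow(sub) == 0) stop("no data for index ", index)
  curve <- roc_analysis(sub$value, sub$is_abrupt)
  list(index = index, treatments = treatments, curve = curve,
       threshold = curve$youden_threshold, auc = curve$auc)
}
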