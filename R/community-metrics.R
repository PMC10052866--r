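#' Bray-Curtis dissimilarity between two community vectors
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed via
#' [vegan::vegdist()]. 0 for identical communities, 1 for disjoint supports.
#'
#' @param x,y nonnegative abundance vectors over the same taxon set.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (sum(x) == 0 && sum(y) == 0) {
    stop("Bray-Curtis is undefined for two all-zero communities")
  }
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Shannon diversity H' (nats)
#'
#' @param x nonnegative abundance vector, not all zero. Normalized
#'   internally.
#' @return H' = -sum p_i log p_i over p_i > 0, natural log.
#' @export
shannon_diversity <- function(x) {
  stopifnot(all(x >= 0))
  if (sum(x) == 0) stop("Shannon diversity is undefined for an all-zero sample")
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' Windowed abruptness of community change
#'
#' The abruptness of a replicate community at day `t`, horizon `p`, is the
#' Bray-Curtis dissimilarity between the mean relative composition over the
#' 5-day window before `t` (days t-4..t) and the mean relative composition
#' over the 5-day window starting `p` days later (days t+p..t+p+4).
#' Averaging over the windows removes minor day-to-day fluctuations so that
#' only fundamental compositional turnover is scored; a value above 0.5
#' flags turnover of more than half the community.
#'
#' @param series single-replicate abundance table (long) or a day-by-taxon
#'   matrix with day rownames.
#' @param t focal day.
#' @param p forecast horizon in days (>= 1).
#' @param window window length in days (default 5).
#' @return abruptness in [0, 1].
#' @export
abruptness <- function(series, t, p, window = 5) {
  m <- if (is.matrix(series)) series else abundance_matrix(series)
  days <- as.integer(rownames(m))
  before <- (t - window + 1):t
  after <- (t + p):(t + p + window - 1)
  missing <- setdiff(c(before, after), days)
  if (length(missing) > 0) {
    stop("abruptness window out of range at t = ", t, ", p = ", p,
         ": missing days ", paste(missing, collapse = ", "))
  }
  rel <- relative_composition(m)
  mb <- colMeans(rel[match(before, days), , drop = FALSE])
  ma <- colMeans(rel[match(after, days), , drop = FALSE])
  bray_curtis(mb, ma)
}

#' Abruptness series for every replicate and valid day
#'
#' @param table abundance table (one or more treatments/replicates).
#' @param p forecast horizon(s) in days.
#' @param window window length (default 5).
#' @param flag_threshold label a day abrupt when abruptness exceeds this
#'   (strictly; default 0.5).
#' @return tibble (treatment, replicate, t, p, abruptness, is_abrupt).
#' @export
abruptness_series <- function(table, p = 7, window = 5,
                              flag_threshold = 0.5) {
  out <- list()
  for (grp in split(tibble::as_tibble(table),
                    paste(table$treatment, table$replicate, sep = "\r"))) {
    m <- abundance_matrix(grp)
    days <- as.integer(rownames(m))
    rel <- relative_composition(m)
    for (ph in p) {
      ts <- days[days - window + 1 >= min(days) &
                 days + ph + window - 1 <= max(days)]
      ts <- ts[vapply(ts, function(t)
        all(c((t - window + 1):t, (t + ph):(t + ph + window - 1)) %in% days),
        logical(1))]
      if (length(ts) == 0) next
      vals <- vapply(ts, function(t) {
        mb <- colMeans(rel[match((t - window + 1):t, days), , drop = FALSE])
        ma <- colMeans(rel[match((t + ph):(t + ph + window - 1), days), ,
                           drop = FALSE])
        bray_curtis(mb, ma)
      }, numeric(1))
      out[[length(out) + 1L]] <- tibble::tibble(
        treatment = grp$treatment[1L], replicate = grp$replicate[1L],
        t = ts, p = ph, abruptness = vals,
        is_abrupt = vals > flag_threshold)
    }
  }
  dplyr::bind_rows(out)
}
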