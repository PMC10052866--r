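#' Long-format abundance tables
#'
#' Throughout mbshift a community time series is represented as a long-format
#' tibble with one row per (treatment, replicate, day, taxon) and a numeric
#' `abundance` column holding 16S rRNA copy concentrations (nM) or any other
#' nonnegative abundance measure. `abundance_table()` validates and classes
#' such a tibble; most downstream functions accept any data frame with the
#' required columns.
#'
#' @param x data frame with columns `treatment`, `replicate`, `day`, `taxon`,
#'   `abundance`.
#' @return `x` as a tibble with class `mb_abundance`, rows ordered by
#'   treatment, replicate, day, taxon.
#' @export
abundance_table <- function(x) {
  need <- c("treatment", "replicate", "day", "taxon", "abundance")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("abundance table is missing columns: ", paste(miss, collapse = ", "))
  }
  x <- tibble::as_tibble(x)
  if (!is.numeric(x$abundance)) stop("`abundance` must be numeric")
  if (any(x$abundance < 0, na.rm = TRUE)) stop("`abundance` must be nonnegative")
  key <- paste(x$treatment, x$replicate, x$day, x$taxon)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (treatment, replicate, day, taxon) rows, e.g. row ",
         dup[1L], ": ", key[dup[1L]])
  }
  x <- x[order(x$treatment, x$replicate, x$day, x$taxon), , drop = FALSE]
  class(x) <- unique(c("mb_abundance", class(x)))
  x
}

#' Wide day-by-taxon matrix for one replicate
#'
#' @param table abundance table (long format).
#' @param replicate replicate id to extract; may be omitted when the table
#'   holds a single replicate.
#' @param value column to spread (default `"abundance"`).
#' @return numeric matrix, rows = days (sorted, rownames = day), columns =
#'   taxa (sorted taxon ids). Missing (replicate, day, taxon) combinations
#'   become `NA`.
#' @export
abundance_matrix <- function(table, replicate = NULL, value = "abundance") {
  if (!is.null(replicate)) {
    table <- table[table$replicate == replicate, , drop = FALSE]
  } else if (length(unique(table$replicate)) > 1L) {
    stop("table holds several replicates; pass `replicate`")
  }
  if (nrow(table) == 0L) stop("no rows for the requested replicate")
  days <- sort(unique(table$day))
  taxa <- sort(unique(table$taxon))
  m <- matrix(NA_real_, length(days), length(taxa),
              dimnames = list(as.character(days), taxa))
  m[cbind(match(table$day, days), match(table$taxon, taxa))] <- table[[value]]
  m
}

#' Relative composition of a nonnegative vector or matrix
#'
#' Rows of a matrix (samples) are scaled to sum to one; all-zero rows are kept
#' all-zero.
#'
#' @param x nonnegative vector or matrix (rows = samples).
#' @return rescaled object of the same shape.
#' @export
relative_composition <- function(x) {
  if (is.matrix(x)) {
    s <- rowSums(x)
    s[s == 0] <- 1
    sweep(x, 1, s, "/")
  } else {
    s <- sum(x)
    if (s == 0) x else x / s
  }
}

# internal: split a table into per-replicate day-sorted matrices
split_replicates <- function(table, value = "abundance") {
  reps <- sort(unique(table$replicate))
  out <- lapply(reps, function(r) abundance_matrix(table, r, value = value))
  names(out) <- reps
  out
}
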