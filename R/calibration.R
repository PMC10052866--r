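#' Fit a spike-in standard curve for one sample
#'
#' Regresses spike read counts on known copy concentrations by least squares
#' through the origin (zero copies implies zero expected reads). The Pearson
#' correlation of the two vectors doubles as the per-sample calibration
#' quality score; it is defined as 0 when either vector is constant.
#'
#' @param spike_reads read counts of the spike-in standards.
#' @param spike_nM known copy concentrations (nM), same length.
#' @return object of class `standard_curve`: list with `slope` (reads per
#'   nM), `pearson_r`, `n_points`.
#' @export
fit_standard_curve <- function(spike_reads, spike_nM) {
  stopifnot(length(spike_reads) == length(spike_nM),
            length(spike_nM) >= 2, all(spike_nM > 0))
  if (all(spike_reads == 0)) {
    stop("all spike reads are zero: sample cannot be calibrated")
  }
  slope <- sum(spike_reads * spike_nM) / sum(spike_nM^2)
  r <- if (stats::sd(spike_reads) == 0 || stats::sd(spike_nM) == 0) {
    0
  } else {
    stats::cor(spike_reads, spike_nM)
  }
  structure(list(slope = slope, pearson_r = r,
                 n_points = length(spike_nM)),
            class = "standard_curve")
}

#' Convert taxon reads to copy concentrations with a standard curve
#'
#' @param taxon_reads vector of read counts.
#' @param curve a [fit_standard_curve()] result.
#' @return vector of copy concentrations (nM): reads / slope.
#' @export
calibrate_sample <- function(taxon_reads, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope <= 0) stop("standard curve slope must be positive")
  taxon_reads / curve$slope
}

#' Calibrate a full read table against its spike-in table
#'
#' Fits a standard curve per sample and converts taxon reads to copy
#' concentrations. Samples whose spikes are all zero are dropped with a
#' warning (uncalibratable).
#'
#' @param reads long read table (sample_id, treatment, replicate, day,
#'   taxon, reads) as produced by [simulate_reads()].
#' @param spikes spike read table (sample_id, spike_id, reads, known_nM).
#' @return list with `abundance` (an [abundance_table()] of concentrations),
#'   and `samples` (per-sample tibble: sample_id, treatment, replicate, day,
#'   slope, pearson_r, total_reads).
#' @export
calibrate_table <- function(reads, spikes) {
  ids <- unique(reads$sample_id)
  rows <- vector("list", length(ids))
  meta <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rsub <- reads[reads$sample_id == ids[i], , drop = FALSE]
    ssub <- spikes[spikes$sample_id == ids[i], , drop = FALSE]
    if (all(ssub$reads == 0)) {
      warning("sample ", ids[i], " has zero spike reads; dropped")
      next
    }
    curve <- fit_standard_curve(ssub$reads, ssub$known_nM)
    rows[[i]] <- tibble::tibble(
      treatment = rsub$treatment, replicate = rsub$replicate,
      day = rsub$day, taxon = rsub$taxon,
      abundance = calibrate_sample(rsub$reads, curve))
    meta[[i]] <- tibble::tibble(
      sample_id = ids[i], treatment = rsub$treatment[1L],
      replicate = rsub$replicate[1L], day = rsub$day[1L],
      slope = curve$slope, pearson_r = curve$pearson_r,
      total_reads = sum(rsub$reads))
  }
  list(abundance = abundance_table(dplyr::bind_rows(rows)),
       samples = dplyr::bind_rows(meta))
}

#' Drop unreliably calibrated and shallowly sequenced samples
#'
#' Samples whose calibration-curve Pearson correlation is less than `min_r`
#' or whose total taxon read count is less than `min_reads` are removed
#' (strict inequalities: boundary values are kept).
#'
#' @param calibrated a [calibrate_table()] result.
#' @param min_r minimum calibration correlation (default 0.7).
#' @param min_reads minimum total taxon reads per sample (default 350).
#' @return list with filtered `abundance`, `samples`, and `qc` (lists
#'   `dropped_low_r` and `dropped_low_reads` of sample ids).
#' @export
quality_filter <- function(calibrated, min_r = 0.7, min_reads = 350) {
  s <- calibrated$samples
  low_r <- s$sample_id[s$pearson_r < min_r]
  low_reads <- s$sample_id[s$total_reads < min_reads]
  drop <- union(low_r, low_reads)
  keep <- !(s$sample_id %in% drop)
  ab <- calibrated$abundance
  key <- paste(ab$treatment, ab$replicate, ab$day)
  skey <- paste(s$treatment, s$replicate, s$day)
  ab <- ab[key %in% skey[keep], , drop = FALSE]
  list(abundance = abundance_table(ab), samples = s[keep, , drop = FALSE],
       qc = list(dropped_low_r = low_r, dropped_low_reads = low_reads))
}

#' Fill missing days of each taxon series by interpolation
#'
#' Some downstream analyses (notably state-space embedding) do not tolerate
#' missing values. Single interior gaps are filled with the mean of the
#' flanking days; runs of consecutive missing days are filled by linear
#' interpolation between the flanks; missing days at the series ends copy
#' the nearest observed value. Observed values are never altered.
#'
#' @param table abundance table, possibly with missing (replicate, day)
#'   samples.
#' @param days optional full day grid (default `min(day):max(day)` per
#'   replicate).
#' @return list with `abundance` (completed table) and `interpolated`
#'   (tibble of treatment, replicate, day flags).
#' @export
interpolate_missing <- function(table, days = NULL) {
  out <- list()
  flags <- list()
  for (grp in split(
         tibble::as_tibble(table),
         paste(table$treatment, table$replicate, sep = "\r"))) {
    grid <- days %||% (min(grp$day):max(grp$day))
    taxa <- sort(unique(grp$taxon))
    m <- matrix(NA_real_, length(grid), length(taxa),
                dimnames = list(as.character(grid), taxa))
    m[cbind(match(grp$day, grid), match(grp$taxon, taxa))] <- grp$abundance
    missing_days <- grid[rowSums(is.na(m)) > 0]
    filled <- apply(m, 2, function(v) zoo::na.approx(v, na.rm = FALSE,
                                                     rule = 2))
    out[[length(out) + 1L]] <- tibble::tibble(
      treatment = grp$treatment[1L], replicate = grp$replicate[1L],
      day = rep(grid, times = length(taxa)),
      taxon = rep(taxa, each = length(grid)),
      abundance = as.numeric(filled))
    if (length(missing_days) > 0) {
      flags[[length(flags) + 1L]] <- tibble::tibble(
        treatment = grp$treatment[1L], replicate = grp$replicate[1L],
        day = missing_days)
    }
  }
  list(abundance = abundance_table(dplyr::bind_rows(out)),
       interpolated = if (length(flags)) dplyr::bind_rows(flags) else
         tibble::tibble(treatment = character(), replicate = character(),
                        day = integer()))
}

#' Retain taxa by per-replicate prevalence
#'
#' A taxon is kept iff there is at least one replicate community in which it
#' is present (abundance > 0) in `min_presence` or more samples. The rule is
#' per replicate, not on the pooled total.
#'
#' @param table abundance table.
#' @param min_presence minimum presences within a single replicate
#'   (default 5).
#' @return filtered abundance table.
#' @export
prevalence_filter <- function(table, min_presence = 5) {
  tab <- tibble::as_tibble(table)
  pres <- dplyr::summarise(
    dplyr::group_by(tab, .data$taxon, .data$treatment, .data$replicate),
    n_present = sum(.data$abundance > 0), .groups = "drop")
  keep <- unique(pres$taxon[pres$n_present >= min_presence])
  abundance_table(tab[tab$taxon %in% keep, , drop = FALSE])
}
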