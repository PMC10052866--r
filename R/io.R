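#' Read a long-format abundance table and its metadata
#'
#' The on-disk schema is a TSV with columns sample_id, replicate, day,
#' taxon_id, value plus a metadata TSV with columns sample_id, treatment,
#' replicate, day. Every abundance sample must appear in the metadata;
#' duplicate (replicate, day, taxon) rows are rejected.
#'
#' @param path abundance TSV.
#' @param metadata_path metadata TSV.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, metadata_path) {
  ab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  md <- utils::read.delim(metadata_path, sep = "\t", stringsAsFactors = FALSE)
  need_ab <- c("sample_id", "replicate", "day", "taxon_id", "value")
  need_md <- c("sample_id", "treatment", "replicate", "day")
  if (!all(need_ab %in% names(ab))) {
    stop("abundance TSV must have columns ", paste(need_ab, collapse = ", "))
  }
  if (!all(need_md %in% names(md))) {
    stop("metadata TSV must have columns ", paste(need_md, collapse = ", "))
  }
  missing <- setdiff(unique(ab$sample_id), md$sample_id)
  if (length(missing) > 0) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  }
  merged <- merge(ab, md[c("sample_id", "treatment")], by = "sample_id")
  abundance_table(tibble::tibble(
    treatment = merged$treatment, replicate = as.character(merged$replicate),
    day = as.integer(merged$day), taxon = merged$taxon_id,
    abundance = as.numeric(merged$value)))
}

#' Write an abundance table and metadata to TSV
#'
#' @param table an [abundance_table()].
#' @param path abundance TSV path.
#' @param metadata_path metadata TSV path.
#' @return invisibly, the two paths.
#' @export
write_abundance_table <- function(table, path, metadata_path) {
  tab <- tibble::as_tibble(table)
  sample_id <- sprintf("%s_%s_d%03d", tab$treatment, tab$replicate, tab$day)
  utils::write.table(
    data.frame(sample_id = sample_id, replicate = tab$replicate,
               day = tab$day, taxon_id = tab$taxon, value = tab$abundance),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  md <- unique(data.frame(sample_id = sample_id, treatment = tab$treatment,
                          replicate = tab$replicate, day = tab$day))
  utils::write.table(md, metadata_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(path, metadata_path))
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis pipeline; all randomness
#' flows from the seeds recorded here, so a fixed config reproduces
#' byte-identical artifacts.
#'
#' @param fixture simulation fixture name (see [community_fixture()]).
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_replicates,n_days fixture overrides (NULL = fixture defaults).
#' @param reads_per_sample sequencing depth for read simulation.
#' @param horizons forecast horizons (default 1:7).
#' @param p_signal horizon used for warning-signal pairing (default 7).
#' @param window abruptness window (default 5 days).
#' @param E_range embedding-dimension range.
#' @param theta_grid S-map theta grid.
#' @param methods forecast methods to run.
#' @param m_stability taxa entering Jacobians (default 8).
#' @param n_walks stable-state-entropy walks (default 1000).
#' @param landscape_stride fit landscape indices every this many days
#'   (default 1 = every day).
#' @param stages stages to execute, a subset of `"simulate"`, `"calibrate"`,
#'   `"metrics"`, `"landscape"`, `"forecast"`, `"stability"`, `"signals"`.
#' @return object of class `mb_config` (a named list).
#' @export
run_config <- function(fixture = "bistable", out_dir = tempfile("mbshift_"),
                       seed = 1, n_replicates = NULL, n_days = NULL,
                       reads_per_sample = 20000, horizons = 1:7,
                       p_signal = 7, window = 5, E_range = 1:5,
                       theta_grid = c(0, 0.001, 0.01, 0.05, 0.1, 0.2, 0.5,
                                      1, 2, 4, 8),
                       methods = c("simplex", "smap_linear", "null"),
                       m_stability = 8, n_walks = 1000,
                       landscape_stride = 1,
                       stages = c("simulate", "calibrate", "metrics",
                                  "landscape", "forecast", "stability",
                                  "signals")) {
  cfg <- list(fixture = fixture, out_dir = out_dir, seed = as.integer(seed),
              n_replicates = n_replicates, n_days = n_days,
              reads_per_sample = reads_per_sample, horizons = horizons,
              p_signal = p_signal, window = window, E_range = E_range,
              theta_grid = theta_grid, methods = methods,
              m_stability = m_stability, n_walks = n_walks,
              landscape_stride = landscape_stride, stages = stages)
  class(cfg) <- "mb_config"
  cfg
}

#' Run the full analysis pipeline on a simulation fixture
#'
#' Executes simulate -> calibrate -> metrics -> landscape -> forecast ->
#' stability -> signals, writing each stage's artifact as TSV/JSON into
#' `config$out_dir`. Stages can be subset via `config$stages`; later stages
#' re-read the artifacts of earlier ones from the output directory, so a
#' cached directory can be extended.
#'
#' @param config a [run_config()].
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mb_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  log_stage <- function(stage, n) {
    message(sprintf("[mbshift] %-10s %6d records", stage, n))
  }
  tsv <- function(x, f) utils::write.table(x, out(f), sep = "\t",
                                           row.names = FALSE, quote = FALSE)
  read_tsv <- function(f) tibble::as_tibble(
    utils::read.delim(out(f), sep = "\t", stringsAsFactors = FALSE))
  has <- function(stage) stage %in% config$stages

  if (has("simulate")) {
    fx <- community_fixture(config$fixture,
                            n_replicates = config$n_replicates,
                            n_days = config$n_days, seed = config$seed)
    spikes <- spike_in_set()
    rd <- simulate_reads(fx$table, spikes,
                         reads_per_sample = config$reads_per_sample,
                         seed = config$seed + 1L)
    write_abundance_table(fx$table, out("true_abundance.tsv"),
                          out("metadata.tsv"))
    tsv(rd$reads, "reads.tsv")
    tsv(rd$spikes, "spike_reads.tsv")
    log_stage("simulate", nrow(rd$reads))
  }
  if (has("calibrate")) {
    reads <- read_tsv("reads.tsv")
    spikes <- read_tsv("spike_reads.tsv")
    cal <- calibrate_table(reads, spikes)
    filt <- quality_filter(cal)
    interp <- interpolate_missing(filt$abundance)
    final <- prevalence_filter(interp$abundance)
    write_abundance_table(final, out("calibrated_abundance.tsv"),
                          out("calibrated_metadata.tsv"))
    jsonlite::write_json(
      list(dropped_low_r = filt$qc$dropped_low_r,
           dropped_low_reads = filt$qc$dropped_low_reads,
           interpolated = interp$interpolated,
           retained_taxa = sort(unique(final$taxon))),
      out("qc_report.json"), auto_unbox = TRUE, digits = NA)
    log_stage("calibrate", nrow(final))
  }
  downstream <- c("metrics", "landscape", "forecast", "stability", "signals")
  if (!any(downstream %in% config$stages)) return(invisible(config$out_dir))
  table <- read_abundance_table(out("calibrated_abundance.tsv"),
                                out("calibrated_metadata.tsv"))
  if (has("metrics")) {
    ab <- abruptness_series(table, p = config$horizons,
                            window = config$window)
    tsv(ab, "abruptness.tsv")
    div <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(table), .data$treatment,
                      .data$replicate, .data$day),
      shannon = if (sum(.data$abundance) > 0)
        shannon_diversity(.data$abundance) else NA_real_,
      total = sum(.data$abundance), .groups = "drop")
    tsv(div, "diversity.tsv")
    log_stage("metrics", nrow(ab))
  }
  if (has("landscape")) {
    sig <- landscape_signals(table, n_walks = config$n_walks,
                             stride = config$landscape_stride,
                             seed = config$seed + 2L)
    tsv(sig, "landscape_signals.tsv")
    log_stage("landscape", nrow(sig))
  }
  if (has("forecast")) {
    run <- run_population_forecasts(table, methods = config$methods,
                                    horizons = config$horizons,
                                    E_range = config$E_range,
                                    theta_grid = config$theta_grid)
    tsv(tibble::as_tibble(run), "population_forecasts.tsv")
    tsv(forecast_r2(run), "forecast_r2.tsv")
    tsv(assemble_community_forecast(run), "community_forecast.tsv")
    log_stage("forecast", nrow(run))
  }
  if (has("stability")) {
    st <- stability_series(table, m = config$m_stability)
    tsv(st, "stability.tsv")
    log_stage("stability", nrow(st))
  }
  if (has("signals")) {
    ab <- read_tsv("abruptness.tsv")
    idx <- read_tsv("landscape_signals.tsv")
    st <- read_tsv("stability.tsv")
    wide <- dplyr::inner_join(
      idx[c("treatment", "replicate", "day", "energy_gap",
            "stable_state_entropy")],
      st[c("treatment", "replicate", "day", "lyapunov", "structural")],
      by = c("treatment", "replicate", "day"))
    series <- build_signal_series(wide, ab, p = config$p_signal)
    tsv(series, "signal_series.tsv")
    tsv(regress_signal(series), "signal_regressions.tsv")
    thresholds <- list()
    for (ix in unique(series$index)) {
      th <- tryCatch(pooled_threshold(series, ix), error = function(e) NULL)
      if (!is.null(th)) {
        thresholds[[ix]] <- list(threshold = th$threshold, auc = th$auc)
      }
    }
    jsonlite::write_json(thresholds, out("thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("signals", nrow(series))
  }
  invisible(config$out_dir)
}

#' Leave-one-replicate-out landscape warning indices
#'
#' For each replicate, fits the pairwise maximum-entropy model on the
#' binarized samples of the *other* replicates of the same treatment, then
#' scores every day of the target replicate with the energy gap and
#' stable-state entropy of its observed community state.
#'
#' @param table abundance table for one treatment.
#' @param lower,upper occurrence window for [binarize()].
#' @param n_walks,max_steps stable-state-entropy walk parameters.
#' @param stride score every `stride`-th day (default 1).
#' @param max_iter,tol maxent fit controls.
#' @param seed integer seed.
#' @return tibble (treatment, replicate, day, energy_gap,
#'   stable_state_entropy).
#' @export
landscape_signals <- function(table, lower = 0.02, upper = 0.98,
                              n_walks = 1000, max_steps = 1000, stride = 1,
                              max_iter = 50000, tol = 1e-4, seed = 1) {
  tab <- tibble::as_tibble(table)
  stopifnot(length(unique(tab$treatment)) == 1)
  reps <- sort(unique(tab$replicate))
  if (length(reps) < 2) stop("need >= 2 replicates for leave-one-out fits")
  out <- list()
  for (target in reps) {
    train <- tab[tab$replicate != target, , drop = FALSE]
    bc <- binarize(train, lower = lower, upper = upper)
    if (ncol(bc$matrix) > 14) {
      # keep exact enumeration cheap: top-prevalence taxa
      keep <- order(colMeans(bc$matrix), decreasing = TRUE)[1:14]
      bc$matrix <- bc$matrix[, sort(keep), drop = FALSE]
      bc$taxa <- colnames(bc$matrix)
    }
    model <- fit_maxent(bc, max_iter = max_iter, tol = tol)
    tmat <- abundance_matrix(tab[tab$replicate == target, , drop = FALSE])
    days <- as.integer(rownames(tmat))
    days <- days[seq(1, length(days), by = stride)]
    gaps <- numeric(length(days))
    sse <- numeric(length(days))
    for (i in seq_along(days)) {
      row <- tmat[as.character(days[i]), ]
      state <- stats::setNames(rep(0L, model$S), model$taxa)
      present <- intersect(names(row)[!is.na(row) & row > 0], model$taxa)
      state[present] <- 1L
      gaps[i] <- energy_gap(state, model)
      sse[i] <- stable_state_entropy(state, model, n_walks = n_walks,
                                     max_steps = max_steps,
                                     seed = seed + i)
    }
    out[[target]] <- tibble::tibble(
      treatment = tab$treatment[1L], replicate = target, day = days,
      energy_gap = gaps, stable_state_entropy = sse)
  }
  dplyr::bind_rows(out)
}
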