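test_that("standard curves recover slope and correlation", {
  conc <- c(0.1, 0.05, 0.02, 0.01, 0.005)
  cv <- fit_standard_curve(c(20000, 10000, 4000, 2000, 1000), conc)
  expect_equal(cv$slope, 200000)
  expect_equal(cv$pearson_r, 1.0)
  # constant reads: correlation defined as 0
  expect_equal(fit_standard_curve(rep(5, 5), conc)$pearson_r, 0)
  # a shuffled assignment destroys the correlation
  shuffled <- fit_standard_curve(c(2000, 20000, 1000, 10000, 4000), conc)
  expect_lt(shuffled$pearson_r, 0.7)
  expect_error(fit_standard_curve(rep(0, 5), conc), "calibrated")
})

test_that("calibration is read count over slope", {
  cv <- fit_standard_curve(c(20000, 10000, 4000, 2000, 1000),
                           c(0.1, 0.05, 0.02, 0.01, 0.005))
  expect_equal(calibrate_sample(5000, cv), 0.025)
  expect_equal(calibrate_sample(0, cv), 0)
  bad <- structure(list(slope = -1, pearson_r = 1, n_points = 5),
                   class = "standard_curve")
  expect_error(calibrate_sample(10, bad), "positive")
})

test_that("quality filter applies strict thresholds and is idempotent", {
  mk <- function(id, r, reads) tibble::tibble(
    sample_id = id, treatment = "t", replicate = "R1",
    day = match(id, c("a", "b", "c", "d")), slope = 1000,
    pearson_r = r, total_reads = reads)
  samples <- dplyr::bind_rows(mk("a", 0.69, 1000), mk("b", 0.70, 1000),
                              mk("c", 0.90, 349), mk("d", 0.90, 350))
  ab <- abundance_table(tibble::tibble(
    treatment = "t", replicate = "R1", day = 1:4, taxon = "T01",
    abundance = 1))
  cal <- list(abundance = ab, samples = samples)
  flt <- quality_filter(cal)
  expect_equal(flt$qc$dropped_low_r, "a")       # r = 0.69 < 0.7 dropped
  expect_equal(flt$qc$dropped_low_reads, "c")   # 349 < 350 dropped
  expect_setequal(flt$samples$sample_id, c("b", "d"))  # boundaries kept
  # idempotent
  flt2 <- quality_filter(flt)
  expect_equal(flt2$abundance, flt$abundance)
  expect_length(flt2$qc$dropped_low_r, 0)
  # all passing: empty drop lists
  ok <- quality_filter(list(abundance = ab,
                            samples = dplyr::mutate(samples,
                                                    pearson_r = 0.9,
                                                    total_reads = 1000)))
  expect_length(ok$qc$dropped_low_r, 0)
  expect_length(ok$qc$dropped_low_reads, 0)
})

test_that("missing days are interpolated without touching observations", {
  tab <- abundance_table(tibble::tibble(
    treatment = "t", replicate = "R1",
    day = c(1, 3, 4, 8), taxon = "T01",
    abundance = c(2, 4, 5, 9)))
  res <- interpolate_missing(tab)
  m <- abundance_matrix(res$abundance, "R1")
  expect_equal(unname(m[, "T01"]), c(2, 3, 4, 5, 6, 7, 8, 9))
  expect_setequal(res$interpolated$day, c(2, 5, 6, 7))
  # single interior gap is the mean of its flanks
  tab2 <- abundance_table(tibble::tibble(
    treatment = "t", replicate = "R1", day = c(1, 3), taxon = "T01",
    abundance = c(2, 4)))
  expect_equal(unname(abundance_matrix(
    interpolate_missing(tab2)$abundance)[, 1]), c(2, 3, 4))
  # an edge gap copies the nearest observed value
  tab3 <- abundance_table(tibble::tibble(
    treatment = "t", replicate = "R1", day = c(2, 3), taxon = "T01",
    abundance = c(5, 6)))
  res3 <- interpolate_missing(tab3, days = 1:3)
  expect_equal(unname(abundance_matrix(res3$abundance)[, 1]), c(5, 5, 6))
})

test_that("prevalence filtering is per replicate, not pooled", {
  # present 5 times in one replicate: kept
  keep <- tibble::tibble(treatment = "t", replicate = "R1", day = 1:10,
                         taxon = "keep", abundance = rep(c(1, 0), each = 5))
  # present 4 times in each of 2 replicates (8 total): dropped
  drop <- dplyr::bind_rows(lapply(c("R1", "R2"), function(r)
    tibble::tibble(treatment = "t", replicate = r, day = 1:10,
                   taxon = "drop", abundance = rep(c(1, 0), c(4, 6)))))
  # never present: dropped
  absent <- tibble::tibble(treatment = "t", replicate = "R1", day = 1:10,
                           taxon = "absent", abundance = 0)
  tab <- abundance_table(dplyr::bind_rows(keep, drop, absent))
  out <- prevalence_filter(tab)
  expect_setequal(unique(out$taxon), "keep")
})

test_that("calibration round-trip error shrinks with sequencing depth", {
  fx <- community_fixture("stable", n_replicates = 2, n_days = 15)
  err <- vapply(c(1e4, 1e6), function(depth) {
    rd <- simulate_reads(fx$table, spike_in_set(), reads_per_sample = depth,
                         seed = 21)
    cal <- calibrate_table(rd$reads, rd$spikes)
    mrg <- dplyr::inner_join(cal$abundance, fx$table,
                             by = c("treatment", "replicate", "day", "taxon"))
    big <- mrg$abundance.y > 0.01   # taxa comfortably above detection
    mean(abs(mrg$abundance.x[big] - mrg$abundance.y[big]) /
           mrg$abundance.y[big])
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)
})
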