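#' Parameters for the generalized Lotka-Volterra microcosm simulator
#'
#' The simulator emulates batch-transfer microcosms sampled once a day: each
#' day one Euler-Maruyama step of the generalized Lotka-Volterra (gLV) system
#' dN_i/dt = N_i (r_i + sum_j a_ij N_j) is taken, multiplicative lognormal
#' process noise is applied, and all abundances are multiplied by
#' `1 - dilution_fraction` to mimic replacement of a fixed fraction of the
#' culture volume with fresh medium.
#'
#' @param n_taxa number of taxa.
#' @param growth_rates per-capita growth rates r (1/day), length `n_taxa`.
#' @param interactions square matrix `a` of per-capita interaction effects of
#'   taxon j on taxon i (1/(abundance x day)); the diagonal holds
#'   self-limitation.
#' @param noise_sd standard deviation of the lognormal process noise applied
#'   to log abundance each day (0 = deterministic).
#' @param dilution_fraction fraction of the culture replaced daily, in [0, 1].
#' @param n_replicates,n_days replicate communities and sampling days.
#' @param init initial abundances: a vector (shared by replicates) or an
#'   `n_replicates` x `n_taxa` matrix. Default 0.1 for every taxon.
#' @param seed integer seed; identical seeds give identical simulations.
#' @param treatment treatment label stamped on the output table.
#' @return object of class `glv_params`.
#' @export
glv_params <- function(n_taxa, growth_rates, interactions, noise_sd = 0,
                       dilution_fraction = 0.2, n_replicates = 8,
                       n_days = 110, init = NULL, seed = 1,
                       treatment = "synthetic") {
  interactions <- as.matrix(interactions)
  stopifnot(length(growth_rates) == n_taxa,
            all(dim(interactions) == c(n_taxa, n_taxa)),
            dilution_fraction >= 0, dilution_fraction <= 1,
            noise_sd >= 0, n_replicates >= 1, n_days >= 1)
  if (is.null(init)) init <- rep(0.1, n_taxa)
  if (is.matrix(init)) {
    stopifnot(all(dim(init) == c(n_replicates, n_taxa)))
  } else {
    stopifnot(length(init) == n_taxa)
    init <- matrix(init, n_replicates, n_taxa, byrow = TRUE)
  }
  if (any(init < 0)) stop("initial abundances must be nonnegative")
  structure(
    list(n_taxa = n_taxa, growth_rates = as.numeric(growth_rates),
         interactions = interactions, noise_sd = noise_sd,
         dilution_fraction = dilution_fraction, n_replicates = n_replicates,
         n_days = n_days, init = init, seed = as.integer(seed),
         treatment = treatment),
    class = "glv_params")
}

# abundances below this are genuine absences (avoids denormal drift and
# supplies zeros for presence/absence binarization)
.EXTINCTION_FLOOR <- 1e-10

#' Simulate gLV community time series
#'
#' @param params a [glv_params()] object.
#' @return an [abundance_table()] with taxa `T01`, `T02`, ... and replicates
#'   `R1`, `R2`, ...
#' @export
simulate_glv <- function(params) {
  stopifnot(inherits(params, "glv_params"))
  p <- params
  taxa <- sprintf("T%02d", seq_len(p$n_taxa))
  reps <- paste0("R", seq_len(p$n_replicates))
  out <- vector("list", p$n_replicates)
  set.seed(p$seed)
  for (r in seq_len(p$n_replicates)) {
    n <- p$init[r, ]
    traj <- matrix(NA_real_, p$n_days, p$n_taxa)
    for (d in seq_len(p$n_days)) {
      growth <- n * (p$growth_rates + as.numeric(p$interactions %*% n))
      n <- n + growth
      if (p$noise_sd > 0) n <- n * exp(stats::rnorm(p$n_taxa, 0, p$noise_sd))
      n <- pmax(n, 0)
      n <- n * (1 - p$dilution_fraction)
      n[n < .EXTINCTION_FLOOR] <- 0
      if (any(!is.finite(n))) {
        bad <- which(!is.finite(n))[1L]
        stop("gLV trajectory diverged for taxon ", taxa[bad],
             " in replicate ", reps[r], " on day ", d)
      }
      traj[d, ] <- n
    }
    out[[r]] <- tibble::tibble(
      treatment = p$treatment,
      replicate = reps[r],
      day = rep(seq_len(p$n_days), times = p$n_taxa),
      taxon = rep(taxa, each = p$n_days),
      abundance = as.numeric(traj))
  }
  abundance_table(dplyr::bind_rows(out))
}

#' Spike-in standard set
#'
#' Five artificial 16S standards spanning a 20-fold concentration gradient
#' (0.1, 0.05, 0.02, 0.01 and 0.005 nM) are the default, matching common
#' quantitative amplicon sequencing practice.
#'
#' @param concentrations strictly positive copy concentrations (nM), in
#'   decreasing order.
#' @param labels spike identifiers.
#' @return object of class `spike_set`.
#' @export
spike_in_set <- function(concentrations = c(0.1, 0.05, 0.02, 0.01, 0.005),
                         labels = sprintf("STD%d", seq_along(concentrations))) {
  stopifnot(all(concentrations > 0),
            length(labels) == length(concentrations))
  if (is.unsorted(rev(concentrations), strictly = TRUE)) {
    stop("spike concentrations must be strictly decreasing")
  }
  structure(list(concentrations = as.numeric(concentrations),
                 labels = as.character(labels)),
            class = "spike_set")
}

#' Simulate multinomial sequencing reads with spike-in standards
#'
#' Per sample, `reads_per_sample` reads are drawn multinomially with weights
#' proportional to taxon copy concentrations and to spike concentrations
#' scaled by `copies_per_read_unit`. An all-zero community sample is valid:
#' every read is then assigned to the spikes.
#'
#' @param abundance abundance table of true copy concentrations (nM).
#' @param spikes a [spike_in_set()].
#' @param reads_per_sample sequencing depth per sample.
#' @param copies_per_read_unit relative amplification weight of spike
#'   concentration units against taxon concentration units (default 1:
#'   both in nM).
#' @param seed integer seed.
#' @return list with `reads` (sample_id, treatment, replicate, day, taxon,
#'   reads) and `spikes` (sample_id, spike_id, reads, known_nM) tibbles.
#' @export
simulate_reads <- function(abundance, spikes, reads_per_sample = 20000,
                           copies_per_read_unit = 1, seed = 1) {
  stopifnot(inherits(spikes, "spike_set"), reads_per_sample >= 0)
  set.seed(as.integer(seed))
  taxa <- sort(unique(abundance$taxon))
  keys <- unique(abundance[c("treatment", "replicate", "day")])
  keys$sample_id <- sprintf("%s_%s_d%03d", keys$treatment, keys$replicate,
                            keys$day)
  n_spike <- length(spikes$concentrations)
  read_rows <- vector("list", nrow(keys))
  spike_rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- abundance[abundance$treatment == keys$treatment[i] &
                     abundance$replicate == keys$replicate[i] &
                     abundance$day == keys$day[i], , drop = FALSE]
    conc <- stats::setNames(rep(0, length(taxa)), taxa)
    conc[sub$taxon] <- sub$abundance
    w <- c(conc, spikes$concentrations * copies_per_read_unit)
    counts <- if (reads_per_sample == 0) {
      rep(0L, length(w))
    } else {
      as.integer(stats::rmultinom(1, reads_per_sample, prob = w))
    }
    read_rows[[i]] <- tibble::tibble(
      sample_id = keys$sample_id[i], treatment = keys$treatment[i],
      replicate = keys$replicate[i], day = keys$day[i],
      taxon = taxa, reads = counts[seq_along(taxa)])
    spike_rows[[i]] <- tibble::tibble(
      sample_id = keys$sample_id[i], treatment = keys$treatment[i],
      replicate = keys$replicate[i], day = keys$day[i],
      spike_id = spikes$labels,
      reads = counts[length(taxa) + seq_len(n_spike)],
      known_nM = spikes$concentrations)
  }
  list(reads = dplyr::bind_rows(read_rows),
       spikes = dplyr::bind_rows(spike_rows))
}

#' Specification of a pairwise maximum-entropy (Ising-type) ground truth
#'
#' @param h bias per taxon (positive favours presence).
#' @param J symmetric coupling matrix with zero diagonal.
#' @param n_samples number of community states to draw.
#' @param seed integer seed.
#' @return object of class `ising_spec`.
#' @export
ising_spec <- function(h, J, n_samples, seed = 1) {
  J <- as.matrix(J)
  S <- length(h)
  stopifnot(all(dim(J) == c(S, S)), isTRUE(all.equal(J, t(J))),
            all(diag(J) == 0), n_samples >= 1)
  structure(list(h = as.numeric(h), J = J, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "ising_spec")
}

#' Draw binary community states from a pairwise maximum-entropy model
#'
#' Exact mode enumerates all 2^S states and draws i.i.d. samples from
#' p(sigma) = exp(-H(sigma))/Z; it is limited to S <= 20 taxa. Gibbs mode
#' runs single-site heat-bath sweeps with burn-in and thinning, for larger
#' systems.
#'
#' @param spec an [ising_spec()].
#' @param method `"exact"` (default, S <= 20) or `"gibbs"`.
#' @param burn_in,thin Gibbs-only: full sweeps discarded before sampling and
#'   sweeps between retained samples.
#' @return integer matrix `n_samples` x S of 0/1 states.
#' @export
sample_ising <- function(spec, method = c("exact", "gibbs"),
                         burn_in = 200, thin = 5) {
  stopifnot(inherits(spec, "ising_spec"))
  method <- match.arg(method)
  S <- length(spec$h)
  set.seed(spec$seed)
  if (method == "exact") {
    if (S > 20) {
      stop("exact enumeration is limited to S <= 20 taxa; ",
           "use method = \"gibbs\" for larger systems")
    }
    model <- maxent_model(spec$h, spec$J)
    p <- state_probabilities(model)
    idx <- sample.int(length(p), spec$n_samples, replace = TRUE, prob = p)
    return(all_states(S)[idx, , drop = FALSE])
  }
  # heat-bath Gibbs sampling
  sigma <- as.integer(stats::runif(S) < 0.5)
  out <- matrix(0L, spec$n_samples, S)
  kept <- 0L
  sweep_no <- 0L
  while (kept < spec$n_samples) {
    for (i in seq_len(S)) {
      field <- spec$h[i] + sum(spec$J[i, ] * sigma)
      sigma[i] <- as.integer(stats::runif(1) < 1 / (1 + exp(-field)))
    }
    sweep_no <- sweep_no + 1L
    if (sweep_no > burn_in && (sweep_no - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- sigma
    }
  }
  out
}

#' Named simulation fixtures
#'
#' Three frozen microcosm parameterizations exercising the dynamical regimes
#' the analysis distinguishes:
#' \describe{
#'   \item{bistable}{two mutually inhibiting three-taxon guilds; replicates
#'     settle into alternative stable states and noise induces abrupt shifts
#'     between them.}
#'   \item{chaotic4}{four competing taxa (Vano-type parameterization) with
#'     bounded, non-repeating chaotic fluctuations.}
#'   \item{stable}{six weakly interacting taxa relaxing to a single stable
#'     equilibrium.}
#' }
#'
#' @param name fixture name.
#' @param n_replicates,n_days,seed optional overrides of the frozen defaults.
#' @return list with `params` ([glv_params()]) and `table` (simulated
#'   [abundance_table()]).
#' @export
community_fixture <- function(name = c("bistable", "chaotic4", "stable"),
                              n_replicates = NULL, n_days = NULL,
                              seed = NULL) {
  name <- match.arg(name)
  par <- switch(name,
    bistable = {
      # guild A (taxa 1:3) starts dominant; guild B (4:6) invades slowly and,
      # once established, excludes A — an abrupt shift between two
      # alternative community states whose timing varies among replicates
      # (noise-driven); some replicates never shift within the series
      r <- c(rep(0.8, 3), rep(0.85, 3))
      a <- matrix(0, 6, 6)
      a[1:3, 1:3] <- -0.05
      a[4:6, 4:6] <- -0.05
      a[4:6, 1:3] <- -0.25   # A suppresses B weakly: slow invasion
      a[1:3, 4:6] <- -0.5    # B suppresses A strongly: exclusion after shift
      # heterogeneous self-limitation: guild A spans dominant to rare
      # (the rare taxon sits near the sequencing detection limit, so its
      # presence flickers increasingly as the invasion erodes the guild)
      diag(a) <- c(-0.25, -2.75, -1100, rep(-0.5, 3))
      init <- matrix(c(2.2, 0.2, 5e-4, rep(0.01, 3)), 8, 6, byrow = TRUE)
      glv_params(6, r, a, noise_sd = 0.25, dilution_fraction = 0.2,
                 n_replicates = 8, n_days = 110, init = init, seed = 20230329,
                 treatment = "bistable")
    },
    chaotic4 = {
      # Vano et al. (2006) chaotic 4-species competitive LV, time-rescaled
      # so a single Euler step per day stays bounded
      r <- c(1, 0.72, 1.53, 1.27)
      m <- rbind(c(1, 1.09, 1.52, 0),
                 c(0, 1, 0.44, 1.36),
                 c(2.33, 0, 1, 0.47),
                 c(1.21, 0.51, 0.35, 1))
      ts <- 0.8
      # start on the chaotic attractor; small per-replicate jitter
      i0 <- c(0.3013, 0.4586, 0.1307, 0.3557)
      set.seed(4242)
      init <- matrix(rep(i0, each = 8), 8, 4) *
        (1 + stats::runif(32, -0.05, 0.05))
      glv_params(4, ts * r, -ts * r * m, noise_sd = 0.02,
                 dilution_fraction = 0, n_replicates = 8, n_days = 110,
                 init = init, seed = 4242, treatment = "chaotic4")
    },
    stable = {
      r <- c(0.4, 0.35, 0.3, 0.45, 0.38, 0.33)
      a <- matrix(-0.02, 6, 6)
      diag(a) <- -0.4
      glv_params(6, r, a, noise_sd = 0.05, dilution_fraction = 0.2,
                 n_replicates = 8, n_days = 110, seed = 7, treatment = "stable")
    })
  if (!is.null(n_replicates) || !is.null(n_days) || !is.null(seed)) {
    par$n_replicates <- n_replicates %||% par$n_replicates
    par$n_days <- n_days %||% par$n_days
    par$seed <- as.integer(seed %||% par$seed)
    if (nrow(par$init) != par$n_replicates) {
      par$init <- matrix(par$init[1, ], par$n_replicates, par$n_taxa,
                         byrow = TRUE)
    }
  }
  list(params = par, table = simulate_glv(par))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
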