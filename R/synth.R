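#' Noise specification for the synthetic-data generator
#'
#' Measurement-noise model emulating the study's assays: immunoblot band
#' intensities get multiplicative lognormal noise (intensities are positive
#' and right-skewed), loading controls likewise; qPCR cycle thresholds get
#' additive Gaussian noise in cycle units; per-cell nuclear:cytoplasmic
#' ratios scatter lognormally around the model ratio. Replicate and cell
#' counts default to the study's scale (4-6 independent experiments, 30-40
#' cells per time point).
#'
#' @param blot_cv lognormal coefficient of variation per band.
#' @param loading_cv loading-control coefficient of variation.
#' @param lane_gain_sd log-scale spread of the per-replicate lane gain
#'   (cancelled by the normalization chain).
#' @param ct_sd additive Ct noise (cycles).
#' @param cell_ratio_cv per-cell RSNC coefficient of variation.
#' @param n_replicates independent experiments per series (>= 2).
#' @param n_cells analyzed cells per time point (>= 2).
#' @param sem_floor lower bound applied to SEMs of the assembled dataset, in
#'   normalized units; set to 0 to forbid zero-variance series instead
#'   (noiseless generation then errors).
#' @param seed RNG seed for the generator.
#' @return object of class `stat1_noise` (list).
#' @export
noise_spec <- function(blot_cv = 0.2, loading_cv = 0.1, lane_gain_sd = 0.4,
                       ct_sd = 0.15, cell_ratio_cv = 0.2, n_replicates = 4L,
                       n_cells = 35L, sem_floor = 0.05, seed = 1L) {
  ns <- list(blot_cv = blot_cv, loading_cv = loading_cv,
             lane_gain_sd = lane_gain_sd, ct_sd = ct_sd,
             cell_ratio_cv = cell_ratio_cv,
             n_replicates = as.integer(n_replicates),
             n_cells = as.integer(n_cells), sem_floor = sem_floor,
             seed = as.integer(seed))
  if (any(c(blot_cv, loading_cv, lane_gain_sd, ct_sd, cell_ratio_cv,
            sem_floor) < 0)) {
    stop("noise magnitudes must be >= 0")
  }
  if (ns$n_replicates < 2 || ns$n_cells < 2) {
    stop("n_replicates and n_cells must be >= 2")
  }
  class(ns) <- "stat1_noise"
  ns
}

#' Packaged demonstration ground truth
#'
#' The default parameter set of [stat1_parameters()] together with the study
#' conditions: IFN-gamma doses 10 and 100 ng/ml and a 0-720 min sampling
#' grid. Its simulation exhibits the qualitative signatures of the measured
#' system: a biphasic phospho-STAT1 rise at 100 ng/ml (rapid initial
#' phosphorylation, then a slow long-lasting further increase), a slower
#' rise at 10 ng/ml, a late increase of total STAT1 protein, a near-constant
#' nuclear:cytoplasmic STAT1 ratio, and a maximal nuclear phospho-STAT1
#' fraction of about 1/500 of total STAT1.
#'
#' @return list with `params` ([stat1_parameters()]), `doses` (ng/ml) and
#'   `times` (min).
#' @export
demo_truth <- function() {
  list(params = stat1_parameters(),
       doses = c(10, 100),
       times = c(0, 15, 30, 60, 120, 180, 360, 540, 720))
}

# mean-1 lognormal multipliers with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

BLOT_OBSERVABLES <- names(OBSERVABLE_SCALING)

# loading control / cellular fraction per blotted observable
BLOT_FRACTION <- c(STAT1P_total = "total", STAT1_total = "total",
                   STAT1P_cyt = "cytosolic", STAT1_cyt = "cytosolic",
                   STAT1P_nuc = "nuclear", STAT1_nuc = "nuclear")

#' Generate a synthetic multi-dose dataset from known ground truth
#'
#' Simulates the pathway at the ground-truth parameters for each dose,
#' fabricates raw assay tables with the noise structure of [noise_spec()] --
#' per-replicate immunoblot bands with loading controls, SOCS1 qPCR cycle
#' thresholds (two technical replicates; the unstimulated time point is
#' omitted, as basal SOCS1 expression is below detection), and per-cell
#' confocal intensities -- and pushes them through the package's own
#' preprocessing ([blot_normalize()], [qpcr_normalize()],
#' [rsnc_from_cells()], [summarize_replicates()]) to assemble the
#' mean +/- SEM dataset exactly as the experimental pipeline would.
#'
#' @param truth list with elements `params`, `doses`, `times` (see
#'   [demo_truth()]).
#' @param noise a [noise_spec()].
#' @return list of class `stat1_synth`: `dataset` (data frame with columns
#'   `observable`, `dose_ng_ml`, `time_min`, `mean`, `sem`, `n`), `raw`
#'   (list of the blot/qPCR/cell tables), `implied_scalings` (per-dose WB
#'   factors under which the noiseless dataset is reproduced exactly),
#'   `truth`, `noise`.
#' @export
generate_dataset <- function(truth = demo_truth(), noise = noise_spec()) {
  stopifnot(inherits(noise, "stat1_noise"))
  if (length(truth$times) < 2) stop("need at least 2 time points")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(noise$seed)

  times <- sort(unique(truth$times))
  blots <- list(); qpcrs <- list(); cells <- list()
  implied <- list()
  for (dose in truth$doses) {
    traj <- simulate_pathway(truth$params, dose, times)
    combos <- observable_combos(traj$states)

    # immunoblots: lane gain per replicate cancels in the normalization chain
    for (obs in BLOT_OBSERVABLES) {
      for (r in seq_len(noise$n_replicates)) {
        gain <- stats::rlnorm(1, 0, noise$lane_gain_sd)
        blots[[length(blots) + 1L]] <- data.frame(
          observable = obs, dose_ng_ml = dose, replicate = r,
          fraction = BLOT_FRACTION[[obs]], time_min = times,
          target_signal = gain * combos[, obs] *
            rlnorm_cv(length(times), noise$blot_cv),
          loading_signal = gain * rlnorm_cv(length(times), noise$loading_cv))
      }
    }
    implied[[as.character(dose)]] <- setNames(
      vapply(BLOT_OBSERVABLES, function(obs) 1 / mean(combos[, obs]),
             numeric(1)),
      unname(OBSERVABLE_SCALING[BLOT_OBSERVABLES]))

    # SOCS1 qPCR: expression proportional to model mRNA; t = 0 undetectable
    qt <- times[times > 0]
    expr <- 10 * combos[match(qt, times), "SOCS1_mRNA"]
    for (r in seq_len(noise$n_replicates)) {
      for (tech in 1:2) {
        ct_h <- 20 + stats::rnorm(length(qt), 0, noise$ct_sd)
        qpcrs[[length(qpcrs) + 1L]] <- data.frame(
          gene = "SOCS1", dose_ng_ml = dose, replicate = r, tech_rep = tech,
          time_min = qt,
          ct_target = ct_h - log2(expr) +
            stats::rnorm(length(qt), 0, noise$ct_sd),
          ct_hprt = ct_h)
      }
    }

    # confocal per-cell intensities scattered around the model RSNC
    for (i in seq_along(times)) {
      n <- noise$n_cells
      cyt_area <- round(stats::runif(n, 300, 600))
      nuc_area <- round(stats::runif(n, 200, 400))
      cyt_conc <- stats::rlnorm(n, log(50), 0.3)
      ratio <- combos[i, "RSNC"] * rlnorm_cv(n, noise$cell_ratio_cv)
      cells[[length(cells) + 1L]] <- data.frame(
        dose_ng_ml = dose, time_min = times[i],
        image = 1L + (seq_len(n) - 1L) %/% 10L, cell = seq_len(n),
        nuc_sum = ratio * cyt_conc * nuc_area, nuc_area = nuc_area,
        cyt_sum = cyt_conc * cyt_area, cyt_area = cyt_area)
    }
  }
  blots <- do.call(rbind, blots)
  qpcrs <- do.call(rbind, qpcrs)
  cells <- do.call(rbind, cells)

  dataset <- assemble_dataset(blots, qpcrs, cells,
                              sem_floor = noise$sem_floor)
  structure(list(dataset = dataset,
                 raw = list(blots = blots, qpcr = qpcrs, cells = cells),
                 implied_scalings = implied,
                 truth = truth, noise = noise),
            class = "stat1_synth")
}

#' Assemble a fit-ready dataset from raw assay tables
#'
#' Runs the full preprocessing chain on raw blot, qPCR and confocal tables
#' and binds the per-observable mean +/- SEM series into the tidy dataset
#' format consumed by [chi_squared()] and [fit_pathway()].
#'
#' @param blots raw immunoblot table (see [blot_normalize()]); may be `NULL`.
#' @param qpcr raw qPCR table (see [qpcr_normalize()]); may be `NULL`.
#' @param cells raw per-cell confocal table with `dose_ng_ml` and `time_min`
#'   columns (see [rsnc_from_cells()]); may be `NULL`.
#' @param sem_floor lower bound applied to all SEMs (normalized units); with
#'   `sem_floor = 0`, zero SEMs are rejected.
#' @return data frame with columns `observable`, `dose_ng_ml`, `time_min`,
#'   `mean`, `sem`, `n`.
#' @export
assemble_dataset <- function(blots = NULL, qpcr = NULL, cells = NULL,
                             sem_floor = 0.05) {
  parts <- list()
  if (!is.null(blots)) {
    norm <- blot_normalize(blots)
    parts$blot <- summarize_replicates(norm)
  }
  if (!is.null(qpcr)) {
    norm <- qpcr_normalize(qpcr)
    norm$observable <- paste0(norm$gene, "_mRNA")
    parts$qpcr <- summarize_replicates(norm)
  }
  if (!is.null(cells)) {
    key <- interaction(cells$dose_ng_ml, cells$time_min, drop = TRUE)
    rs <- lapply(split(cells, key), function(g) {
      r <- rsnc_from_cells(g)
      data.frame(observable = "RSNC", dose_ng_ml = g$dose_ng_ml[1],
                 time_min = g$time_min[1], mean = r$mean, sem = r$sem,
                 n_replicates = r$n_cells)
    })
    parts$rsnc <- do.call(rbind, rs)
  }
  if (length(parts) == 0) stop("no raw tables supplied")
  ds <- do.call(rbind, lapply(parts, function(p) {
    data.frame(observable = p$observable, dose_ng_ml = p$dose_ng_ml,
               time_min = p$time_min, mean = p$mean, sem = p$sem,
               n = p$n_replicates)
  }))
  # radix ordering is locale-independent, keeping the row order (and with it
  # floating-point summation order downstream) identical across sessions
  ds <- ds[order(ds$observable, ds$dose_ng_ml, ds$time_min,
                 method = "radix"), ]
  rownames(ds) <- NULL
  if (sem_floor > 0) {
    ds$sem <- pmax(ds$sem, sem_floor)
  } else if (any(ds$sem <= 0)) {
    stop("zero SEM in dataset and no sem_floor configured")
  }
  ds
}
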