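#' Immunoblot scaling factors
#'
#' Band intensities on an immunoblot are in arbitrary units, so each blotted
#' series is related to the model by a free positive gain ("WB" factor): one
#' each for cytosolic total STAT1, nuclear total STAT1, total phospho-STAT1,
#' cytosolic phospho-STAT1, nuclear phospho-STAT1, and total-lysate STAT1.
#' mRNA observables and the nuclear:cytoplasmic ratio RSNC carry no factor:
#' mRNA series are compared after time-average normalization (which removes
#' any gain, making a factor redundant) and RSNC is a ratio of concentrations
#' measured in the same units.
#'
#' @param WB_STAT1c,WB_STAT1n,WB_STAT1D,WB_STAT1Dc,WB_STAT1Dn,WB_STAT1
#'   positive multipliers (1/a.u.).
#' @return object of class `stat1_scaling` (named numeric vector).
#' @export
scaling_factors <- function(WB_STAT1c = 1, WB_STAT1n = 1, WB_STAT1D = 1,
                            WB_STAT1Dc = 1, WB_STAT1Dn = 1, WB_STAT1 = 1) {
  sf <- c(WB_STAT1c = WB_STAT1c, WB_STAT1n = WB_STAT1n, WB_STAT1D = WB_STAT1D,
          WB_STAT1Dc = WB_STAT1Dc, WB_STAT1Dn = WB_STAT1Dn,
          WB_STAT1 = WB_STAT1)
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("scaling factors must be positive and finite")
  }
  class(sf) <- "stat1_scaling"
  sf
}

SCALING_NAMES <- c("WB_STAT1c", "WB_STAT1n", "WB_STAT1D", "WB_STAT1Dc",
                   "WB_STAT1Dn", "WB_STAT1")

OBSERVABLE_NAMES <- c("STAT1P_total", "STAT1_total", "STAT1P_cyt",
                      "STAT1_cyt", "STAT1P_nuc", "STAT1_nuc",
                      "SOCS1_mRNA", "STAT1_mRNA", "RSNC")

# Which scaling factor multiplies which blotted observable.
OBSERVABLE_SCALING <- c(STAT1P_total = "WB_STAT1D", STAT1_total = "WB_STAT1",
                        STAT1P_cyt = "WB_STAT1Dc", STAT1_cyt = "WB_STAT1c",
                        STAT1P_nuc = "WB_STAT1Dn", STAT1_nuc = "WB_STAT1n")

# Unscaled species combinations behind each observable, in monomer
# equivalents (each dimer contributes two monomers to a band).
observable_combos <- function(states) {
  SUc <- states[, "SUc"]; SUn <- states[, "SUn"]; SDc <- states[, "SDc"]
  SDn <- states[, "SDn"]; SDnd <- states[, "SDnd"]
  cyt_total <- SUc + 2 * SDc
  nuc_total <- SUn + 2 * (SDn + SDnd)
  cbind(STAT1P_total = 2 * (SDc + SDn + SDnd),
        STAT1_total  = SUc + SUn + 2 * (SDc + SDn + SDnd),
        STAT1P_cyt   = 2 * SDc,
        STAT1_cyt    = cyt_total,
        STAT1P_nuc   = 2 * (SDn + SDnd),
        STAT1_nuc    = nuc_total,
        SOCS1_mRNA   = states[, "mSOCS1"],
        STAT1_mRNA   = states[, "mSTAT1"],
        RSNC         = nuc_total / cyt_total)
}

#' Map a model trajectory to the measured observables
#'
#' Applies the algebraic observation map: blotted observables are the species
#' combinations in monomer equivalents times their WB scaling factor; the two
#' mRNA observables are the model transcript levels unscaled; RSNC is the
#' ratio of nuclear to cytoplasmic STAT1 concentration, scaling-free because
#' nuclear and cytoplasmic areas are taken as equal.
#'
#' @param traj a `stat1_trajectory` from [simulate_pathway()].
#' @param sf a [scaling_factors()] object.
#' @return tidy data frame with columns `observable`, `time_min`, `value`,
#'   `dose_ng_ml`.
#' @export
observe <- function(traj, sf = scaling_factors()) {
  stopifnot(inherits(traj, "stat1_trajectory"), inherits(sf, "stat1_scaling"))
  combos <- observable_combos(traj$states)
  cyt <- combos[, "STAT1_cyt"]
  if (any(cyt <= 0)) {
    stop("RSNC undefined: cytoplasmic STAT1 is zero at t = ",
         traj$times[which(cyt <= 0)[1]], " min")
  }
  vals <- combos
  for (obs in names(OBSERVABLE_SCALING)) {
    vals[, obs] <- unclass(sf)[[OBSERVABLE_SCALING[[obs]]]] * combos[, obs]
  }
  data.frame(
    observable = rep(colnames(vals), each = length(traj$times)),
    time_min = rep(traj$times, times = ncol(vals)),
    value = as.vector(vals),
    dose_ng_ml = traj$dose,
    row.names = NULL
  )
}

#' Normalize a time series to its average value over time
#'
#' The study's convention for immunoblot and qPCR time courses: each series
#' is divided by its arithmetic mean over the sampled time points, so the
#' normalized series has mean exactly 1 and the ratio between any two time
#' points is preserved.
#'
#' @param values numeric series (one value per time point), non-empty with a
#'   positive mean.
#' @return the normalized series.
#' @export
time_average_normalize <- function(values) {
  if (length(values) == 0) stop("empty series")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("series mean must be positive, got ", m)
  values / m
}

#' Fraction of total STAT1 present as nuclear phospho-STAT1
#'
#' Per time point, the free nuclear phospho-dimer pool in monomer
#' equivalents, `2 * SDn`, divided by total STAT1 monomer equivalents at the
#' same time. With `include_dna_bound = TRUE` the numerator is
#' `2 * (SDn + SDnd)`, counting DNA-bound dimers as well; the default
#' excludes them because the upper-bound argument concerns the free nuclear
#' dimer pool.
#'
#' @param traj a `stat1_trajectory`.
#' @param include_dna_bound count DNA-bound dimers in the numerator?
#' @return list with `times`, `fraction` (per time point) and `max`.
#' @export
nuclear_phospho_fraction <- function(traj, include_dna_bound = FALSE) {
  stopifnot(inherits(traj, "stat1_trajectory"))
  if (length(traj$times) == 0) stop("empty trajectory")
  s <- traj$states
  total <- s[, "SUc"] + s[, "SUn"] +
    2 * (s[, "SDc"] + s[, "SDn"] + s[, "SDnd"])
  if (any(total <= 0)) stop("total STAT1 must be positive at every time")
  num <- if (include_dna_bound) 2 * (s[, "SDn"] + s[, "SDnd"]) else
    2 * s[, "SDn"]
  frac <- num / total
  list(times = traj$times, fraction = unname(frac), max = max(frac))
}
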