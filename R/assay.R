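#' Normalize immunoblot band intensities
#'
#' Implements the two-step immunoblot normalization used for the STAT1 time
#' courses: each band is first divided by its loading control on the same
#' lane (ERK1/2 for total lysate, GAPDH for the cytosolic fraction, lamin A/C
#' for nuclear extracts), then each per-replicate time series is divided by
#' its average value over time (see [time_average_normalize()]).
#'
#' @param blots data frame with columns `target_signal`, `loading_signal`,
#'   `time_min`, `replicate`, and any further grouping columns (e.g.
#'   `observable`, `dose_ng_ml`, `fraction`); one row per band. Each
#'   replicate series (unique combination of the grouping columns and
#'   `replicate`) needs at least 2 time points.
#' @return the input with a `value` column (normalized intensity) replacing
#'   the two signal columns.
#' @export
blot_normalize <- function(blots) {
  need <- c("target_signal", "loading_signal", "time_min", "replicate")
  miss <- setdiff(need, names(blots))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(blots$target_signal < 0)) stop("negative band intensity")
  bad <- blots$loading_signal <= 0
  if (any(bad)) {
    stop("non-positive loading control at time_min = ",
         paste(unique(blots$time_min[bad]), collapse = ", "))
  }
  ratio <- blots$target_signal / blots$loading_signal
  group_cols <- setdiff(names(blots), c("target_signal", "loading_signal",
                                        "time_min"))
  key <- interaction(blots[group_cols], drop = TRUE)
  if (any(tabulate(key) < 2)) stop("each replicate series needs >= 2 time points")
  out <- blots[setdiff(names(blots), c("target_signal", "loading_signal"))]
  out$value <- unsplit(lapply(split(ratio, key), time_average_normalize), key)
  out
}

#' Summarize replicate series as mean and SEM per time point
#'
#' @param df data frame with a `value` column and one row per replicate
#'   measurement.
#' @param by grouping columns identifying a time point of one series
#'   (default: observable, dose and time).
#' @return data frame with the grouping columns plus `mean`, `sem`
#'   (sample standard deviation over replicates divided by sqrt(n)) and
#'   `n_replicates`. Errors if any time point has fewer than 2 replicates.
#' @export
summarize_replicates <- function(df, by = intersect(c("observable",
                                                      "dose_ng_ml",
                                                      "time_min"),
                                                    names(df))) {
  stopifnot("value" %in% names(df), length(by) > 0)
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  n <- tabulate(key)
  if (any(n < 2)) {
    stop("SEM undefined: time point(s) with < 2 replicates")
  }
  groups <- split(df$value, key)
  first <- !duplicated(key)
  out <- df[first, by, drop = FALSE]
  out <- out[order(interaction(out[by], lex.order = TRUE)), , drop = FALSE]
  out$mean <- vapply(groups, mean, numeric(1))
  out$sem <- vapply(groups, function(v) stats::sd(v) / sqrt(length(v)),
                    numeric(1))
  out$n_replicates <- lengths(groups)
  rownames(out) <- NULL
  out
}

#' qPCR relative expression from cycle thresholds
#'
#' Relative mRNA abundance compared with the housekeeping gene HPRT:
#' `2^-(Ct_target - Ct_HPRT)`. Technical replicates, when present, are
#' averaged on the Ct scale before exponentiation (default) or on the linear
#' scale after it.
#'
#' @param ct_target,ct_hprt finite cycle-threshold values (vectorized).
#' @return relative expression values.
#' @export
qpcr_relative_expression <- function(ct_target, ct_hprt) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_hprt))) {
    stop("Ct values must be finite")
  }
  2^(-(ct_target - ct_hprt))
}

#' Preprocess a raw qPCR table into normalized replicate series
#'
#' Converts Ct pairs to relative expression, averages technical replicates,
#' and applies the per-replicate time-average normalization of the study's
#' time-course convention.
#'
#' @param qpcr data frame with columns `ct_target`, `ct_hprt`, `time_min`,
#'   `replicate`, plus grouping columns (`gene`, `dose_ng_ml`, ...); multiple
#'   rows per (replicate, time) are treated as technical replicates.
#' @param technical `"ct"` (average delta-Ct, then exponentiate; default) or
#'   `"linear"` (exponentiate, then average).
#' @return data frame with one row per replicate and time point and a
#'   normalized `value` column.
#' @export
qpcr_normalize <- function(qpcr, technical = c("ct", "linear")) {
  technical <- match.arg(technical)
  need <- c("ct_target", "ct_hprt", "time_min", "replicate")
  miss <- setdiff(need, names(qpcr))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  dct <- qpcr$ct_target - qpcr$ct_hprt
  if (any(!is.finite(dct))) stop("Ct values must be finite")
  group_cols <- setdiff(names(qpcr), c("ct_target", "ct_hprt"))
  key <- interaction(qpcr[group_cols], drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  out <- qpcr[first, group_cols, drop = FALSE]
  out <- out[order(interaction(out[group_cols], lex.order = TRUE)), ,
             drop = FALSE]
  out$value <- if (technical == "ct") {
    2^(-vapply(split(dct, key), mean, numeric(1)))
  } else {
    vapply(split(2^(-dct), key), mean, numeric(1))
  }
  series_cols <- setdiff(group_cols, "time_min")
  skey <- interaction(out[series_cols], drop = TRUE)
  out$value <- unsplit(lapply(split(out$value, skey), time_average_normalize),
                       skey)
  rownames(out) <- NULL
  out
}

#' Nuclear:cytoplasmic STAT1 ratio from per-cell confocal intensities
#'
#' Per cell, concentration is summed pixel intensity divided by area; RSNC is
#' the nuclear concentration over the cytoplasmic concentration, averaged
#' over the analyzed cells (typically 30-40 cells from 3-4 images per time
#' point).
#'
#' @param cells data frame with columns `nuc_sum`, `nuc_area`, `cyt_sum`,
#'   `cyt_area`, one row per cell.
#' @return list with `ratios` (per cell), `mean`, `sem`, `n_cells`.
#' @export
rsnc_from_cells <- function(cells) {
  need <- c("nuc_sum", "nuc_area", "cyt_sum", "cyt_area")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(cells) < 1) stop("need at least one cell")
  if (any(cells$nuc_area <= 0) || any(cells$cyt_area <= 0)) {
    stop("cell areas must be positive")
  }
  if (any(cells$cyt_sum <= 0)) {
    stop("zero cytoplasmic signal in cell(s) ",
         paste(which(cells$cyt_sum <= 0), collapse = ", "))
  }
  r <- (cells$nuc_sum / cells$nuc_area) / (cells$cyt_sum / cells$cyt_area)
  n <- length(r)
  list(ratios = r, mean = mean(r),
       sem = if (n > 1) stats::sd(r) / sqrt(n) else NA_real_,
       n_cells = n)
}

#' Ellipsoid-approximation tumor volume from caliper readings
#'
#' `V = width^2 * length * 0.52`, the standard ellipsoid approximation for
#' subcutaneous flank tumors. Width is the smaller caliper reading; readings
#' supplied in the wrong order are swapped with a warning.
#'
#' @param width,length caliper readings (mm), > 0 (vectorized).
#' @return volume in mm^3.
#' @export
tumor_volume <- function(width, length) {
  if (any(width <= 0) || any(length <= 0)) {
    stop("tumor dimensions must be positive")
  }
  swap <- width > length
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " record(s); swapping so that width is the smaller reading")
    tmp <- width[swap]
    width[swap] <- length[swap]
    length[swap] <- tmp
  }
  width^2 * length * 0.52
}
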