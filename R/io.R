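#' Read and write fit-ready datasets
#'
#' The dataset contract is a plain CSV with columns `observable`,
#' `dose_ng_ml`, `time_min`, `mean`, `sem` (an `n` column is kept when
#' present). Reading validates the schema: known observable names, positive
#' SEMs, unique (observable, dose, time) keys; offending rows are named.
#'
#' @param path file path.
#' @return `read_dataset_csv`: the validated data frame.
#' @export
read_dataset_csv <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(ds)
  ds
}

#' @param dataset data frame to write.
#' @rdname read_dataset_csv
#' @export
write_dataset_csv <- function(dataset, path) {
  validate_dataset(dataset)
  utils::write.csv(format(dataset, digits = 17, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory as tidy CSV
#'
#' Columns `time_min`, `species`, `value`, `dose_ng_ml`, one row per species
#' and time point; values are written at full precision so read-back is
#' exact.
#'
#' @param traj a `stat1_trajectory`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "stat1_trajectory"))
  df <- data.frame(
    time_min = rep(traj$times, times = ncol(traj$states)),
    species = rep(colnames(traj$states), each = length(traj$times)),
    value = as.vector(traj$states),
    dose_ng_ml = traj$dose)
  utils::write.csv(format(df, digits = 17, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read model parameters as a YAML config
#'
#' Sections `kinetics`, `delays`, `initial_conditions`, `structure` and
#' `scopes`, with keys named exactly as in [stat1_parameters()]. Unknown
#' keys are rejected on read.
#'
#' @param params a [stat1_parameters()] object.
#' @param path file path.
#' @return `read_parameters_yaml`: the reconstructed [stat1_parameters()].
#' @export
write_parameters_yaml <- function(params, path) {
  stopifnot(inherits(params, "stat1_parameters"))
  kin <- c("k_act", "k_phos", "k_inh", "k_imp", "k_bind", "k_unbind",
           "k_deph", "k_shut", "k_txS", "k_degS", "k_txT", "k_degT",
           "k_transl")
  obj <- list(kinetics = params[kin],
              delays = params[c("tau_socs", "tau_stat1", "tau_fb")],
              structure = list(n_chain = params$n_chain,
                               I_total = params$I_total),
              initial_conditions = params[c("init_SUc", "init_SUn",
                                            "init_SDc")],
              scopes = as.list(attr(params, "scopes")))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_parameters_yaml
#' @export
read_parameters_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  need <- c("kinetics", "delays", "structure", "initial_conditions")
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0) stop("config lacks section(s): ",
                             paste(miss, collapse = ", "))
  vals <- c(obj$kinetics, obj$delays, obj$structure, obj$initial_conditions)
  bad <- setdiff(names(vals), PARAM_ORDER)
  if (length(bad) > 0) stop("unknown key(s) in config: ",
                            paste(bad, collapse = ", "))
  scopes <- if (!is.null(obj$scopes)) unlist(obj$scopes)
  do.call(stat1_parameters, c(vals, list(scopes = scopes)))
}

#' Write a fit report as JSON
#'
#' Records the estimated parameters (including the per-dose scaling
#' factors), the chi-squared, data size, optimizer settings and seed.
#'
#' @param fit a `stat1_fit`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "stat1_fit"))
  rep <- list(theta_hat = as.list(fit$theta_hat),
              scalings = lapply(fit$scalings, as.list),
              chi2 = fit$chi2, n_data = fit$n_data,
              chi2_per_point = fit$chi2 / fit$n_data,
              n_penalized = fit$n_failures,
              settings = unclass(fit$settings), seed = fit$seed,
              doses_ng_ml = fit$doses)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
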