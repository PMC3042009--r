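#' Parameter search space for multi-dose fitting
#'
#' One row per model parameter or immunoblot scaling factor: bounds, search
#' scale (log10 or linear), scope (`"global"` = shared across doses,
#' `"local"` = one value per dose) and an optional fixed value. Defaults:
#' all rate constants and delay times are free, global, searched on a log
#' scale within `span`-fold of the packaged reference values; the free
#' initial conditions `init_SUc`/`init_SUn` are free within `ic_span`-fold;
#' `init_SDc` starts at its reference value fixed (zero in the packaged
#' set); `n_chain` and `I_total` are structural/fixed (the receptor total is
#' tied to initial total STAT1); the six WB scaling factors are free and
#' local, because each dose's immunoblot series is normalized to its own
#' time average, so gains are per dose.
#'
#' Free scaling factors are estimated by analytic profiling inside
#' [chi_squared()] (conditional on the kinetics, the optimal gain of each
#' blotted series is a weighted least-squares scalar), so they do not appear
#' in the stochastic search vector; fixing one (as the plateau sweep does)
#' removes it from profiling.
#'
#' The model carries an exact concentration-scale symmetry (all pools times
#' a constant, with compensating rate constants, leaves every observable
#' unchanged), so absolute concentrations are not identifiable from
#' normalized data. The default space removes it with the study's
#' convention: initial total STAT1 is fixed at `total_stat1` (1 a.u., the
#' value behind `I_total = 0.1`), `init_SUc` is searched as a share of that
#' total and `init_SUn` is derived as the remainder. Set
#' `total_stat1 = NA` to search both pools freely instead.
#'
#' @param params reference [stat1_parameters()] supplying central values.
#' @param span fold-range of the kinetic bounds around the reference.
#' @param ic_span fold-range for the free initial conditions when the total
#'   constraint is disabled.
#' @param total_stat1 initial total STAT1 in monomer equivalents
#'   (`init_SUc + init_SUn + 2 * init_SDc`), or `NA` for no constraint.
#' @return data frame of class `stat1_space` with columns `name`, `lower`,
#'   `upper`, `scale`, `scope`, `fixed`, `value`; the constraint is carried
#'   in the `total_stat1` attribute.
#' @export
parameter_space <- function(params = stat1_parameters(), span = 30,
                            ic_span = 5, total_stat1 = 1) {
  kin <- c("k_act", "k_phos", "k_inh", "k_imp", "k_bind", "k_unbind",
           "k_deph", "k_shut", "k_txS", "k_degS", "k_txT", "k_degT",
           "k_transl", "tau_socs", "tau_stat1", "tau_fb")
  rows <- lapply(kin, function(nm) {
    v <- params[[nm]]
    data.frame(name = nm, lower = v / span, upper = v * span, scale = "log",
               scope = "global", fixed = FALSE, value = v)
  })
  if (!is.na(total_stat1)) {
    ics <- list(data.frame(name = "init_SUc", lower = 0.05 * total_stat1,
                           upper = 0.95 * total_stat1, scale = "linear",
                           scope = "global", fixed = FALSE,
                           value = params$init_SUc),
                data.frame(name = "init_SUn", lower = NA_real_,
                           upper = NA_real_, scale = "linear",
                           scope = "global", fixed = TRUE,
                           value = NA_real_))  # derived from the total
  } else {
    ics <- lapply(c("init_SUc", "init_SUn"), function(nm) {
      v <- params[[nm]]
      data.frame(name = nm, lower = v / ic_span, upper = v * ic_span,
                 scale = "log", scope = "global", fixed = FALSE, value = v)
    })
  }
  fixed <- data.frame(name = c("init_SDc", "n_chain", "I_total"),
                      lower = NA_real_, upper = NA_real_, scale = "linear",
                      scope = "global", fixed = TRUE,
                      value = c(params$init_SDc, params$n_chain,
                                params$I_total))
  wb <- data.frame(name = SCALING_NAMES, lower = 1e-4, upper = 1e6,
                   scale = "log", scope = "local", fixed = FALSE, value = 1)
  space <- do.call(rbind, c(rows, ics, list(fixed, wb)))
  rownames(space) <- NULL
  attr(space, "total_stat1") <- total_stat1
  class(space) <- c("stat1_space", "data.frame")
  space
}

#' Fix a parameter in a search space
#'
#' @param space a [parameter_space()].
#' @param name parameter name.
#' @param value value to fix it at.
#' @return the modified space.
#' @export
fix_parameter <- function(space, name, value) {
  i <- match(name, space$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  space$fixed[i] <- TRUE
  space$value[i] <- value
  space
}

validate_space <- function(space) {
  need <- c("name", "lower", "upper", "scale", "scope", "fixed", "value")
  miss <- setdiff(need, names(space))
  if (length(miss) > 0) stop("space lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(space$name)) stop("duplicated parameter names in space")
  known <- c(PARAM_ORDER, SCALING_NAMES)
  bad <- setdiff(space$name, known)
  if (length(bad) > 0) stop("unknown parameter name(s): ",
                            paste(bad, collapse = ", "))
  free <- !space$fixed
  logsc <- space$scale == "log"
  if (any(free & logsc & (space$lower <= 0 | !is.finite(space$upper)))) {
    stop("log-scale parameters need positive finite bounds")
  }
  invisible(space)
}

validate_dataset <- function(dataset) {
  need <- c("observable", "dose_ng_ml", "time_min", "mean", "sem")
  miss <- setdiff(need, names(dataset))
  if (length(miss) > 0) stop("dataset lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (nrow(dataset) == 0) stop("empty dataset")
  bad <- setdiff(unique(dataset$observable), OBSERVABLE_NAMES)
  if (length(bad) > 0) stop("unknown observable(s): ",
                            paste(bad, collapse = ", "))
  if (any(dataset$sem <= 0)) {
    stop("sem must be > 0 for every entry; state an explicit noise floor ",
         "instead of zero SEMs (rows ",
         paste(which(dataset$sem <= 0), collapse = ", "), ")")
  }
  key <- with(dataset, paste(observable, dose_ng_ml, time_min))
  if (anyDuplicated(key)) stop("duplicate (observable, dose, time) entries")
  invisible(dataset)
}

# Search-vector bookkeeping: one entry per free non-scaling parameter,
# replicated per dose for local scope. Entry names are "name" (global) or
# "name@dose" (local).
space_entries <- function(space, doses) {
  validate_space(space)
  rows <- space[!space$fixed & !(space$name %in% SCALING_NAMES), ,
                drop = FALSE]
  ent <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (r$scope == "global") {
      data.frame(entry = r$name, name = r$name, dose = NA_real_,
                 lower = r$lower, upper = r$upper, scale = r$scale,
                 init = r$value)
    } else {
      data.frame(entry = paste0(r$name, "@", doses), name = r$name,
                 dose = doses, lower = r$lower, upper = r$upper,
                 scale = r$scale, init = r$value)
    }
  }))
  rownames(ent) <- NULL
  ent
}

to_search <- function(v, scale) ifelse(scale == "log", log10(v), v)
from_search <- function(u, scale) ifelse(scale == "log", 10^u, u)

# Kinetic parameter set for one dose, given a natural-scale named theta.
params_for_dose <- function(theta, space, dose, base) {
  p <- unclass(base)
  for (i in seq_len(nrow(space))) {
    nm <- space$name[i]
    if (nm %in% SCALING_NAMES) next
    if (space$fixed[i]) {
      p[[nm]] <- space$value[i]
    } else if (space$scope[i] == "global") {
      p[[nm]] <- theta[[nm]]
    } else {
      p[[nm]] <- theta[[paste0(nm, "@", dose)]]
    }
  }
  total <- attr(space, "total_stat1")
  if (!is.null(total) && !is.na(total)) {
    p$init_SUn <- total - p$init_SUc - 2 * p$init_SDc
    if (p$init_SUn < 0) stop("initial pools exceed the fixed STAT1 total")
  }
  p$n_chain <- as.integer(p$n_chain)
  class(p) <- "stat1_parameters"
  p
}

# Cost returned when the integrator fails inside a stochastic search.
PENALTY_COST <- 1e10

#' SEM-weighted chi-squared cost of a parameter vector
#'
#' Simulates each dose present in the dataset with that dose's parameter
#' set (globals shared, locals per dose), maps the trajectory to the
#' measured observables, and returns the sum over observables and time
#' points of squared SEM-weighted residuals. Blotted observables are scaled
#' by their WB factor: fixed factors are applied as given, free factors are
#' profiled analytically (per observable and dose, the gain minimizing the
#' weighted sum of squares). mRNA observables are compared after
#' time-average normalization of the model series over the data's time
#' points (any gain is redundant); RSNC is compared directly.
#'
#' @param theta named numeric vector of free parameter values on the natural
#'   scale; local entries are named `"name@dose"`.
#' @param dataset data frame with columns `observable`, `dose_ng_ml`,
#'   `time_min`, `mean`, `sem` (all `sem` > 0).
#' @param space a [parameter_space()].
#' @param base_params baseline [stat1_parameters()] supplying values not
#'   covered by `space`.
#' @param detail return the decomposition instead of the scalar?
#' @param penalize on simulation failure, return the documented finite
#'   penalty cost (`1e10`; default) rather than signalling the error, so a
#'   stochastic search can continue.
#' @return the chi-squared value, or (with `detail = TRUE`) a list with
#'   `chi2`, `fitted` (data frame with a `y_mod` column), and `scalings`
#'   (per-dose WB factors actually applied).
#' @export
chi_squared <- function(theta, dataset, space = parameter_space(),
                        base_params = stat1_parameters(), detail = FALSE,
                        penalize = !detail) {
  validate_dataset(dataset)
  doses <- sort(unique(dataset$dose_ng_ml))
  chi2 <- 0
  fitted <- list()
  scalings <- list()
  for (dose in doses) {
    dd <- dataset[dataset$dose_ng_ml == dose, , drop = FALSE]
    dtimes <- sort(unique(dd$time_min))
    stimes <- union(0, dtimes)
    traj <- tryCatch({
      pd <- params_for_dose(theta, space, dose, base_params)
      suppressWarnings(simulate_pathway(pd, dose, stimes))
    }, error = function(e) e)
    if (inherits(traj, "error")) {
      if (penalize) return(PENALTY_COST)
      stop("simulation failed at dose ", dose, ": ",
           conditionMessage(traj))
    }
    combos <- observable_combos(traj$states)
    idx_t <- match(dd$time_min, traj$times)
    sf_dose <- c()
    dd$y_mod <- NA_real_
    for (obs in unique(dd$observable)) {
      sel <- dd$observable == obs
      m <- combos[idx_t[sel], obs]
      y <- dd$mean[sel]; s <- dd$sem[sel]
      if (obs %in% names(OBSERVABLE_SCALING)) {
        fname <- OBSERVABLE_SCALING[[obs]]
        i <- match(fname, space$name)
        if (!is.na(i) && space$fixed[i]) {
          w <- space$value[i]
        } else {
          den <- sum(m^2 / s^2)
          w <- if (den > 0) sum(y * m / s^2) / den else 0
        }
        sf_dose[fname] <- w
        ym <- w * m
      } else if (obs %in% c("SOCS1_mRNA", "STAT1_mRNA")) {
        mu <- mean(m)
        ym <- if (mu > 0) m / mu else rep(0, length(m))
      } else {              # RSNC
        ym <- m
      }
      dd$y_mod[sel] <- ym
      chi2 <- chi2 + sum(((y - ym) / s)^2)
    }
    fitted[[as.character(dose)]] <- dd
    scalings[[as.character(dose)]] <- sf_dose
  }
  if (detail) {
    list(chi2 = chi2, fitted = do.call(rbind, c(fitted, make.row.names = FALSE)),
         scalings = scalings)
  } else {
    chi2
  }
}

#' Optimizer settings for the hybrid fit
#'
#' The global stage runs `n_restarts` independent simulated-annealing chains
#' over the transformed search vector (log10 coordinates for log-scale
#' parameters): single-coordinate Gaussian proposals clipped to the bounds,
#' Metropolis acceptance, geometric cooling by `sa_cooling_rate` every
#' `sa_temperature_length` iterations. The best visited point is then
#' refined by a bounded quasi-Newton local search (`stats::nlminb`).
#'
#' @param sa_iterations annealing iterations per restart.
#' @param sa_initial_temperature starting temperature (chi-squared units).
#' @param sa_cooling_rate geometric cooling factor in (0, 1).
#' @param sa_step_scale proposal standard deviation as a fraction of each
#'   coordinate's transformed bound range (shrinks with temperature).
#' @param sa_temperature_length iterations between cooling steps.
#' @param local_max_iterations iteration cap of the local refinement.
#' @param local_tolerance relative convergence tolerance of the local stage.
#' @param n_restarts number of annealing chains.
#' @param seed RNG seed; the whole fit is reproducible given the seed.
#' @return object of class `stat1_optimizer_settings`.
#' @export
optimizer_settings <- function(sa_iterations = 2000,
                               sa_initial_temperature = 1000,
                               sa_cooling_rate = 0.97,
                               sa_step_scale = 0.08,
                               sa_temperature_length = 20,
                               local_max_iterations = 300,
                               local_tolerance = 1e-10,
                               n_restarts = 5, seed = 1L) {
  s <- list(sa_iterations = as.integer(sa_iterations),
            sa_initial_temperature = sa_initial_temperature,
            sa_cooling_rate = sa_cooling_rate,
            sa_step_scale = sa_step_scale,
            sa_temperature_length = as.integer(sa_temperature_length),
            local_max_iterations = as.integer(local_max_iterations),
            local_tolerance = local_tolerance,
            n_restarts = as.integer(n_restarts), seed = as.integer(seed))
  if (any(unlist(s[1:8]) <= 0)) stop("all optimizer settings must be positive")
  if (s$sa_cooling_rate >= 1) stop("sa_cooling_rate must be in (0, 1)")
  class(s) <- "stat1_optimizer_settings"
  s
}

#' Fit the pathway model to a multi-dose dataset
#'
#' Hybrid global/local estimation of the model parameters by minimizing
#' [chi_squared()]: seeded simulated-annealing chains explore the bounded
#' search space, and the best visited point is refined with a bounded local
#' quasi-Newton minimization. Integration failures inside the search are
#' penalized with a large finite cost rather than aborting the chain.
#'
#' @param dataset data frame with columns `observable`, `dose_ng_ml`,
#'   `time_min`, `mean`, `sem`.
#' @param space a [parameter_space()].
#' @param settings an [optimizer_settings()].
#' @param base_params baseline [stat1_parameters()].
#' @param start optional named natural-scale theta used as the starting
#'   point of the first annealing chain (e.g. a warm start from a previous
#'   fit); remaining chains start from seeded uniform draws in the
#'   transformed bounds.
#' @return object of class `stat1_fit`: `theta_hat` (named, natural scale),
#'   `scalings` (per-dose WB factors, profiled or fixed), `chi2`, `n_data`,
#'   `fitted` (dataset with a `y_mod` column), `trace` (per-iteration
#'   best-so-far costs), `n_failures` (penalized integrations), `settings`,
#'   `seed`.
#' @export
fit_pathway <- function(dataset, space = parameter_space(),
                        settings = optimizer_settings(),
                        base_params = stat1_parameters(), start = NULL) {
  validate_dataset(dataset)
  validate_space(space)
  doses <- sort(unique(dataset$dose_ng_ml))
  ent <- space_entries(space, doses)
  d <- nrow(ent)
  if (d == 0) stop("no free parameters to fit")
  lo <- to_search(ent$lower, ent$scale)
  hi <- to_search(ent$upper, ent$scale)
  rng <- hi - lo

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(settings$seed)

  failures <- 0L
  obj <- function(u) {
    theta <- setNames(from_search(u, ent$scale), ent$entry)
    cost <- chi_squared(theta, dataset, space, base_params)
    if (cost >= PENALTY_COST) failures <<- failures + 1L
    cost
  }

  best_u <- NULL
  best_cost <- Inf
  trace <- vector("list", settings$n_restarts)
  for (r in seq_len(settings$n_restarts)) {
    if (r == 1 && !is.null(start)) {
      u <- to_search(unname(start[ent$entry]), ent$scale)
      u <- pmin(pmax(u, lo), hi)
    } else {
      u <- lo + stats::runif(d) * rng
    }
    cost <- obj(u)
    temp <- settings$sa_initial_temperature
    best_r <- cost
    costs <- numeric(settings$sa_iterations)
    bests <- numeric(settings$sa_iterations)
    for (it in seq_len(settings$sa_iterations)) {
      j <- sample.int(d, 1)
      u2 <- u
      sd_j <- settings$sa_step_scale * rng[j] *
        max(temp / settings$sa_initial_temperature, 0.1)
      u2[j] <- min(max(u2[j] + stats::rnorm(1, 0, sd_j), lo[j]), hi[j])
      cost2 <- obj(u2)
      if (cost2 <= cost ||
          stats::runif(1) < exp(-(cost2 - cost) / temp)) {
        u <- u2
        cost <- cost2
      }
      if (cost < best_r) best_r <- cost
      if (cost < best_cost) {
        best_cost <- cost
        best_u <- u
      }
      costs[it] <- cost
      bests[it] <- best_r
      if (it %% settings$sa_temperature_length == 0) {
        temp <- temp * settings$sa_cooling_rate
      }
    }
    trace[[r]] <- data.frame(restart = r,
                             iteration = seq_len(settings$sa_iterations),
                             cost = costs, best = bests)
  }

  # Local refinement alternates a bounded quasi-Newton stage with a
  # derivative-free simplex stage: finite-difference gradients sit on top of
  # the integrator's truncation noise and stall at the percent level, which
  # the simplex then works through; the pair is iterated until it stalls.
  obj_clip <- function(u) obj(pmin(pmax(u, lo), hi))
  for (round in 1:4) {
    before <- best_cost
    loc <- stats::nlminb(best_u, obj, lower = lo, upper = hi,
                         control = list(
                           iter.max = settings$local_max_iterations,
                           eval.max = 50 * settings$local_max_iterations,
                           rel.tol = settings$local_tolerance))
    if (is.finite(loc$objective) && loc$objective <= best_cost) {
      best_u <- loc$par
      best_cost <- loc$objective
    }
    nm <- stats::optim(best_u, obj_clip, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    if (is.finite(nm$value) && nm$value <= best_cost) {
      best_u <- pmin(pmax(nm$par, lo), hi)
      best_cost <- nm$value
    }
    if (before - best_cost <= 1e-4 * max(best_cost, 1)) break
  }

  theta_hat <- setNames(from_search(best_u, ent$scale), ent$entry)
  det <- chi_squared(theta_hat, dataset, space, base_params, detail = TRUE)
  structure(list(theta_hat = theta_hat, scalings = det$scalings,
                 chi2 = det$chi2, n_data = nrow(dataset),
                 fitted = det$fitted, trace = do.call(rbind, trace),
                 n_failures = failures, settings = settings,
                 seed = settings$seed, doses = doses, space = space,
                 base_params = base_params),
            class = "stat1_fit")
}

#' @export
print.stat1_fit <- function(x, ...) {
  cat(sprintf("stat1_fit: chi2 = %.4g over %d data points (chi2/n = %.3g)\n",
              x$chi2, x$n_data, x$chi2 / x$n_data))
  cat("doses (ng/ml):", paste(x$doses, collapse = ", "),
      "| penalized integrations:", x$n_failures, "\n")
  invisible(x)
}

#' Simulated trajectory at a fitted parameter set
#'
#' @param fit a `stat1_fit`.
#' @param dose one of the fitted doses.
#' @param times output times (min), default a fine 0-720 grid.
#' @return a `stat1_trajectory`.
#' @export
fitted_trajectory <- function(fit, dose, times = seq(0, 720, by = 5)) {
  stopifnot(inherits(fit, "stat1_fit"))
  pd <- params_for_dose(fit$theta_hat, fit$space, dose, fit$base_params)
  simulate_pathway(pd, dose, times)
}
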