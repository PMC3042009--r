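#' @useDynLib stat1dyn
#' @importFrom stats setNames
NULL

# Canonical state ordering of the core species; linear-chain auxiliaries follow.
CORE_SPECIES <- c("IIr", "SUc", "SDc", "SDn", "SDnd", "SUn", "mSOCS1", "mSTAT1")

# Parameter ordering shared with the compiled right-hand side (src/stat1_rhs.c).
PARAM_ORDER <- c("k_act", "k_phos", "k_inh", "k_imp", "k_bind", "k_unbind",
                 "k_deph", "k_shut", "k_txS", "k_degS", "k_txT", "k_degT",
                 "k_transl", "tau_socs", "tau_stat1", "tau_fb", "n_chain",
                 "I_total", "init_SUc", "init_SUn", "init_SDc")

#' Kinetic parameters of the IFN-gamma/STAT1 pathway model
#'
#' Builds a validated parameter set for the distributed-delay ODE model of
#' IFN-gamma receptor activation, STAT1 phosphorylation, nucleocytoplasmic
#' shuttling and SOCS1 negative feedback. Concentrations are in arbitrary
#' units (a.u.), time in minutes. The defaults are the packaged demonstration
#' set (see [demo_truth()]): initial total STAT1 is normalized to 1, and the
#' total receptor pool `I_total` defaults to 1/10 of that initial total
#' STAT1. Initial values of the active receptor `IIr` and of the nuclear
#' phospho-dimer pools `SDn`, `SDnd` are structurally zero and are not
#' parameters.
#'
#' @param k_act receptor activation rate constant (per (ng/ml * min)); the
#'   activation flux is `k_act * dose * (I_total - IIr)`, receptor
#'   deactivation and ligand degradation are neglected.
#' @param k_phos STAT1 phosphorylation rate constant (per (a.u. * min)),
#'   acting as `k_phos * IIr * SUc` attenuated by SOCS1 feedback.
#' @param k_inh SOCS1 feedback strength (per a.u.); the phosphorylation flux
#'   is divided by `1 + k_inh * z_fb` where `z_fb` is the delayed SOCS1
#'   mRNA signal.
#' @param k_imp nuclear import rate of the cytoplasmic phospho-dimer (per min).
#' @param k_bind,k_unbind DNA binding/unbinding rates of the nuclear
#'   phospho-dimer (per min).
#' @param k_deph dephosphorylation-and-dissociation rate of the free nuclear
#'   dimer (per min); only free nuclear dimers are dephosphorylated.
#' @param k_shut first-order nucleocytoplasmic exchange rate of
#'   unphosphorylated STAT1 (per min); symmetric because nuclear and
#'   cytoplasmic areas are taken as equal and shuttling is free diffusion.
#' @param k_txS,k_degS SOCS1 mRNA production (per min, driven by the delayed
#'   DNA-bound dimer signal) and degradation (per min) rates.
#' @param k_txT,k_degT,k_transl STAT1 mRNA production, degradation and
#'   translation rates (per min).
#' @param tau_socs,tau_stat1,tau_fb mean delay times (min) of the three
#'   delayed processes: SOCS1 transcription, STAT1 transcription, and SOCS1
#'   feedback (the feedback delay absorbs SOCS1 translation).
#' @param n_chain order of the linear chain realizing each distributed delay
#'   (integer >= 1); the transit-time kernel is a gamma density with shape
#'   `n_chain` and mean `tau`.
#' @param I_total total receptor concentration (a.u.).
#' @param init_SUc,init_SUn,init_SDc free initial conditions of the
#'   unphosphorylated cytoplasmic/nuclear pools and the cytoplasmic dimer
#'   (a.u.).
#' @param scopes named character vector tagging parameters as `"global"`
#'   (shared across IFN-gamma doses) or `"local"` (per dose). Defaults to all
#'   global: the dose enters the equations explicitly.
#'
#' @return An object of class `stat1_parameters` (named list).
#' @export
stat1_parameters <- function(k_act = 0.002, k_phos = 0.01, k_inh = 50,
                             k_imp = 1, k_bind = 0.2, k_unbind = 0.1,
                             k_deph = 0.25, k_shut = 0.1,
                             k_txS = 0.1, k_degS = 0.05,
                             k_txT = 0.01, k_degT = 0.01, k_transl = 0.5,
                             tau_socs = 30, tau_stat1 = 120, tau_fb = 30,
                             n_chain = 3L, I_total = 0.1,
                             init_SUc = 0.5, init_SUn = 0.5, init_SDc = 0,
                             scopes = NULL) {
  p <- list(k_act = k_act, k_phos = k_phos, k_inh = k_inh, k_imp = k_imp,
            k_bind = k_bind, k_unbind = k_unbind, k_deph = k_deph,
            k_shut = k_shut, k_txS = k_txS, k_degS = k_degS, k_txT = k_txT,
            k_degT = k_degT, k_transl = k_transl, tau_socs = tau_socs,
            tau_stat1 = tau_stat1, tau_fb = tau_fb, n_chain = n_chain,
            I_total = I_total, init_SUc = init_SUc, init_SUn = init_SUn,
            init_SDc = init_SDc)
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    stop("non-finite parameter value(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (any(vals < 0)) {
    stop("negative parameter value(s): ",
         paste(names(vals)[vals < 0], collapse = ", "))
  }
  if (p$n_chain < 1 || p$n_chain != round(p$n_chain)) {
    stop("n_chain must be an integer >= 1, got ", p$n_chain)
  }
  p$n_chain <- as.integer(p$n_chain)
  if (is.null(scopes)) {
    scopes <- setNames(rep("global", length(PARAM_ORDER)), PARAM_ORDER)
  }
  bad <- setdiff(names(scopes), PARAM_ORDER)
  if (length(bad) > 0) stop("unknown parameter(s) in scopes: ",
                            paste(bad, collapse = ", "))
  if (!all(scopes %in% c("global", "local"))) {
    stop("scopes must be 'global' or 'local'")
  }
  attr(p, "scopes") <- scopes
  class(p) <- "stat1_parameters"
  p
}

#' @export
print.stat1_parameters <- function(x, ...) {
  cat("IFN-gamma/STAT1 pathway parameters (a.u., minutes)\n")
  v <- unlist(x[PARAM_ORDER])
  print(signif(v, 4))
  invisible(x)
}

# Number of state variables for a given chain order.
n_states <- function(n_chain) 8L + 3L * as.integer(n_chain)

state_names <- function(n_chain) {
  c(CORE_SPECIES,
    paste0("chain_socs", seq_len(n_chain)),
    paste0("chain_stat1", seq_len(n_chain)),
    paste0("chain_fb", seq_len(n_chain)))
}

#' Initial state of the pathway model
#'
#' Active receptor (`IIr`), nuclear phospho-dimer pools (`SDn`, `SDnd`),
#' both mRNAs and all delay-chain stages start at zero; the unphosphorylated
#' pools and the cytoplasmic dimer start at their configured initial values.
#'
#' @param params a [stat1_parameters()] object.
#' @return named numeric state vector.
#' @export
stat1_initial_state <- function(params) {
  stopifnot(inherits(params, "stat1_parameters"))
  y <- setNames(numeric(n_states(params$n_chain)), state_names(params$n_chain))
  y["SUc"] <- params$init_SUc
  y["SUn"] <- params$init_SUn
  y["SDc"] <- params$init_SDc
  y
}

# Flatten parameters + dose into the numeric vector the compiled RHS expects.
pack_parms <- function(params, dose) {
  c(unlist(params[PARAM_ORDER[1:18]]), dose = dose)
}

#' Time derivatives of the pathway state
#'
#' Pure-R evaluation of the model right-hand side, exposed for inspection and
#' testing; [simulate_pathway()] integrates a compiled translation of the
#' same equations. Reaction terms, one per network arrow:
#' receptor activation `k_act * dose * (I_total - IIr)` (no deactivation, the
#' inactive receptor `Ir = I_total - IIr` is implicit); phosphorylation flux
#' `v = k_phos * IIr * SUc / (1 + k_inh * z_fb)` with `z_fb` the delayed
#' SOCS1 signal; dimerization halves the flux into `SDc` (two monomers per
#' dimer); irreversible import `k_imp * SDc`; reversible DNA binding
#' `k_bind`/`k_unbind`; dephosphorylation of free nuclear dimers only,
#' returning two monomers to `SUn`; symmetric shuttling
#' `k_shut * (SUn - SUc)`; delayed transcription of SOCS1 and STAT1 mRNA
#' driven by the DNA-bound dimer; delayed feedback driven by SOCS1 mRNA;
#' first-order translation of STAT1 mRNA into `SUc`.
#'
#' @param state named non-negative state vector, as from
#'   [stat1_initial_state()].
#' @param t time (min); the system is autonomous, `t` is accepted for
#'   integrator compatibility.
#' @param params a [stat1_parameters()] object.
#' @param dose IFN-gamma concentration (ng/ml), >= 0.
#' @return named list with one element, the derivative vector (deSolve
#'   convention).
#' @export
stat1_derivatives <- function(state, t, params, dose) {
  if (any(state < 0)) {
    stop("negative state component: ",
         paste(names(state)[state < 0], collapse = ", "))
  }
  if (dose < 0) stop("negative dose: ", dose)
  rhs_eval(state, params, dose)
}

# Unchecked right-hand side; lsoda may probe marginally negative states.
rhs_eval <- function(state, params, dose) {
  n <- params$n_chain
  y <- unname(state)
  IIr <- y[1]; SUc <- y[2]; SDc <- y[3]; SDn <- y[4]; SDnd <- y[5]
  SUn <- y[6]; mSOCS1 <- y[7]; mSTAT1 <- y[8]
  c_socs  <- y[8 + seq_len(n)]
  c_stat1 <- y[8 + n + seq_len(n)]
  c_fb    <- y[8 + 2 * n + seq_len(n)]

  z_fb <- c_fb[n]
  v <- params$k_phos * IIr * SUc / (1 + params$k_inh * z_fb)
  shuttle <- params$k_shut * (SUn - SUc)

  dcore <- c(
    IIr    = params$k_act * dose * (params$I_total - IIr),
    SUc    = -v + shuttle + params$k_transl * mSTAT1,
    SDc    = v / 2 - params$k_imp * SDc,
    SDn    = params$k_imp * SDc - params$k_bind * SDn +
             params$k_unbind * SDnd - params$k_deph * SDn,
    SDnd   = params$k_bind * SDn - params$k_unbind * SDnd,
    SUn    = 2 * params$k_deph * SDn - shuttle,
    mSOCS1 = params$k_txS * c_socs[n] - params$k_degS * mSOCS1,
    mSTAT1 = params$k_txT * c_stat1[n] - params$k_degT * mSTAT1
  )
  chain_d <- function(cvec, tau, source) {
    r <- n / tau
    r * (c(source, cvec[-n]) - cvec)
  }
  dy <- c(dcore,
          chain_d(c_socs, params$tau_socs, SDnd),
          chain_d(c_stat1, params$tau_stat1, SDnd),
          chain_d(c_fb, params$tau_fb, mSOCS1))
  names(dy) <- state_names(n)
  list(dy)
}

# deSolve-compatible wrapper around the R right-hand side.
rhs_r <- function(t, y, parms) {
  rhs_eval(y, parms$params, parms$dose)
}

#' Simulate the pathway model
#'
#' Integrates the distributed-delay ODE system from the configured initial
#' state with `deSolve::lsoda` and returns the state at the requested times.
#' The default engine uses the compiled right-hand side; `engine = "R"`
#' integrates the pure-R [stat1_derivatives()] (identical equations, used for
#' cross-checking). Species trajectories are clipped at zero when integrator
#' undershoot is below `neg_tol` in magnitude; larger negative excursions are
#' an error.
#'
#' @param params a [stat1_parameters()] object.
#' @param dose IFN-gamma concentration (ng/ml), >= 0.
#' @param times output times (min), starting at 0, strictly increasing.
#' @param engine `"compiled"` (default) or `"R"`.
#' @param rtol,atol relative/absolute integrator tolerances.
#' @param neg_tol magnitude below which negative values are treated as
#'   integrator noise and clipped to zero (with a warning).
#' @return object of class `stat1_trajectory`: list with `times`, `states`
#'   (matrix, one row per time, named columns), and `dose`.
#' @export
simulate_pathway <- function(params, dose, times,
                             engine = c("compiled", "R"),
                             rtol = 1e-8, atol = 1e-10, neg_tol = 1e-9) {
  stopifnot(inherits(params, "stat1_parameters"))
  engine <- match.arg(engine)
  if (length(times) < 1 || times[1] != 0) {
    stop("times must start at 0")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (dose < 0) stop("negative dose: ", dose)

  y0 <- stat1_initial_state(params)
  if (length(times) == 1) {
    return(structure(list(times = times,
                          states = matrix(y0, 1, length(y0),
                                          dimnames = list(NULL, names(y0))),
                          dose = dose),
                     class = "stat1_trajectory"))
  }
  if (engine == "compiled") {
    out <- deSolve::lsoda(y = y0, times = times, func = "stat1_derivs",
                          parms = pack_parms(params, dose),
                          dllname = "stat1dyn", initfunc = "stat1_initmod",
                          rtol = rtol, atol = atol)
  } else {
    out <- deSolve::lsoda(y = y0, times = times, func = rhs_r,
                          parms = list(params = params, dose = dose),
                          rtol = rtol, atol = atol)
  }
  if (nrow(out) < length(times)) {
    stop("integration failed at t = ", out[nrow(out), "time"], " min")
  }
  states <- out[, -1, drop = FALSE]
  neg <- states < 0
  if (any(neg)) {
    worst <- min(states[neg])
    if (-worst > neg_tol) {
      stop("negative species value ", worst, " exceeds tolerance ", neg_tol)
    }
    warning("clipping ", sum(neg), " value(s) >= ", worst, " to zero")
    states[neg] <- 0
  }
  structure(list(times = times, states = states, dose = dose),
            class = "stat1_trajectory")
}

#' @export
print.stat1_trajectory <- function(x, ...) {
  cat(sprintf("stat1_trajectory: %d time points, 0-%g min, dose %g ng/ml\n",
              length(x$times), max(x$times), x$dose))
  invisible(x)
}

#' Impulse response of a distributed-delay linear chain
#'
#' The delayed processes of the model are realized as a cascade of `n_chain`
#' identical first-order stages with per-stage rate `n_chain / tau`. The
#' transit-time distribution of such a chain is a gamma density with shape
#' `n_chain`, rate `n_chain / tau`: mean `tau`, variance `tau^2 / n_chain`.
#' This function evaluates that normalized impulse response.
#'
#' @param tau mean delay time (min), > 0.
#' @param n_chain chain order, integer >= 1.
#' @param times evaluation times (min), >= 0.
#' @return numeric vector of the density at `times` (integrates to 1 over
#'   the half-line).
#' @export
delay_chain_response <- function(tau, n_chain, times) {
  if (tau <= 0) stop("tau must be > 0, got ", tau)
  if (n_chain < 1 || n_chain != round(n_chain)) {
    stop("n_chain must be an integer >= 1, got ", n_chain)
  }
  if (any(times < 0)) stop("times must be >= 0")
  stats::dgamma(times, shape = n_chain, rate = n_chain / tau)
}
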