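# Shared fixtures: small parameter sets and hand-built trajectories.

toy_params <- function(...) stat1_parameters(...)

# Wrap a bare state matrix as a trajectory object for observable-level tests.
make_traj <- function(states, times = seq_len(nrow(states)) - 1, dose = 100) {
  structure(list(times = times, states = states, dose = dose),
            class = "stat1_trajectory")
}

# One-row state matrix with every species settable by name.
single_state <- function(n_chain = 3, ...) {
  vals <- list(...)
  y <- matrix(0, 1, 8 + 3 * n_chain)
  colnames(y) <- c("IIr", "SUc", "SDc", "SDn", "SDnd", "SUn",
                   "mSOCS1", "mSTAT1",
                   paste0("chain_socs", seq_len(n_chain)),
                   paste0("chain_stat1", seq_len(n_chain)),
                   paste0("chain_fb", seq_len(n_chain)))
  for (nm in names(vals)) y[, nm] <- vals[[nm]]
  y
}

# Independent flux-enumeration oracle: walks the reaction arrows of the
# network one by one and adds stoichiometric contributions. Kept deliberately
# separate from the package's vectorized right-hand side.
flux_oracle <- function(state, params, dose) {
  n <- params$n_chain
  d <- setNames(numeric(length(state)), names(state))
  add <- function(species, amount) d[species] <<- d[species] + amount

  # arrow 1: IFN-gamma activates free receptor Ir = I_total - IIr
  add("IIr", params$k_act * dose * (params$I_total - state[["IIr"]]))
  # arrow 2: active receptor phosphorylates SUc, inhibited by delayed SOCS1;
  # two monomers make one cytoplasmic dimer
  z_fb <- state[[paste0("chain_fb", n)]]
  v <- params$k_phos * state[["IIr"]] * state[["SUc"]] /
    (1 + params$k_inh * z_fb)
  add("SUc", -v)
  add("SDc", v / 2)
  # arrow 3: dimer import
  add("SDc", -params$k_imp * state[["SDc"]])
  add("SDn", params$k_imp * state[["SDc"]])
  # arrow 4: reversible DNA binding
  add("SDn", -params$k_bind * state[["SDn"]] +
        params$k_unbind * state[["SDnd"]])
  add("SDnd", params$k_bind * state[["SDn"]] -
        params$k_unbind * state[["SDnd"]])
  # arrow 5: dephosphorylation of free nuclear dimers -> 2 nuclear monomers
  add("SDn", -params$k_deph * state[["SDn"]])
  add("SUn", 2 * params$k_deph * state[["SDn"]])
  # arrow 6: bidirectional shuttling of unphosphorylated STAT1
  add("SUc", params$k_shut * (state[["SUn"]] - state[["SUc"]]))
  add("SUn", -params$k_shut * (state[["SUn"]] - state[["SUc"]]))
  # arrow 7: delayed SOCS1 transcription, first-order mRNA decay
  add("mSOCS1", params$k_txS * state[[paste0("chain_socs", n)]] -
        params$k_degS * state[["mSOCS1"]])
  # arrow 8: delayed STAT1 transcription and decay
  add("mSTAT1", params$k_txT * state[[paste0("chain_stat1", n)]] -
        params$k_degT * state[["mSTAT1"]])
  # arrow 9: translation of STAT1 mRNA into cytoplasmic monomers
  add("SUc", params$k_transl * state[["mSTAT1"]])
  # delay chains: stage cascades driven by SDnd (transcription) and mSOCS1
  for (chain in list(c("chain_socs", "SDnd", params$tau_socs),
                     c("chain_stat1", "SDnd", params$tau_stat1),
                     c("chain_fb", "mSOCS1", params$tau_fb))) {
    r <- n / as.numeric(chain[3])
    prev <- state[[chain[2]]]
    for (j in seq_len(n)) {
      nm <- paste0(chain[1], j)
      add(nm, r * (prev - state[[nm]]))
      prev <- state[[nm]]
    }
  }
  d
}

# Random non-negative model state, for property-style loops.
random_state <- function(params) {
  y <- stat1_initial_state(params)
  y[] <- stats::runif(length(y), 0, 0.5)
  y["IIr"] <- stats::runif(1, 0, params$I_total)
  y
}
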