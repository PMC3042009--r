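truth_theta <- function(space, doses) {
  ent <- stat1dyn:::space_entries(space, doses)
  setNames(ent$init, ent$entry)
}

test_that("chi-squared vanishes at the generating truth on noiseless data", {
  syn <- generate_dataset(noise = noise_spec(blot_cv = 0, loading_cv = 0,
                                             ct_sd = 0, cell_ratio_cv = 0))
  sp <- parameter_space()
  c2 <- chi_squared(truth_theta(sp, c(10, 100)), syn$dataset, sp)
  expect_lt(c2, 1e-10)
})

test_that("a single residual of two SEMs costs exactly four", {
  # RSNC is compared unscaled, so the model value at t = 0 is the initial
  # pool ratio: 1 for the default parameters
  ds <- data.frame(observable = "RSNC", dose_ng_ml = 100, time_min = 0,
                   mean = 1.2, sem = 0.1)
  sp <- parameter_space()
  c2 <- chi_squared(truth_theta(sp, 100), ds, sp)
  expect_equal(c2, 4, tolerance = 1e-9)
})

test_that("chi-squared equals a flat-loop oracle over the fitted table", {
  syn <- generate_dataset(noise = noise_spec(seed = 8))
  sp <- parameter_space()
  theta <- truth_theta(sp, c(10, 100))
  det <- chi_squared(theta, syn$dataset, sp, detail = TRUE)
  acc <- 0
  for (i in seq_len(nrow(det$fitted))) {
    r <- det$fitted[i, ]
    acc <- acc + ((r$mean - r$y_mod) / r$sem)^2
  }
  expect_equal(det$chi2, acc, tolerance = 1e-12)
  expect_equal(det$chi2, chi_squared(theta, syn$dataset, sp),
               tolerance = 1e-12)
})

test_that("chi-squared is invariant under permutation of dataset rows", {
  syn <- generate_dataset(noise = noise_spec(seed = 8))
  sp <- parameter_space()
  theta <- truth_theta(sp, c(10, 100))
  set.seed(1)
  shuffled <- syn$dataset[sample(nrow(syn$dataset)), ]
  expect_equal(chi_squared(theta, shuffled, sp),
               chi_squared(theta, syn$dataset, sp), tolerance = 1e-12)
})

test_that("local parameters equal across doses reproduce the global cost", {
  syn <- generate_dataset(noise = noise_spec(seed = 8))
  sp <- parameter_space()
  sp$scope[sp$name == "k_act"] <- "local"
  theta_g <- truth_theta(parameter_space(), c(10, 100))
  theta_l <- truth_theta(sp, c(10, 100))
  expect_true(all(c("k_act@10", "k_act@100") %in% names(theta_l)))
  expect_equal(chi_squared(theta_l, syn$dataset, sp),
               chi_squared(theta_g, syn$dataset, parameter_space()),
               tolerance = 1e-12)
})

test_that("dataset and space contracts are enforced before any simulation", {
  syn <- generate_dataset(noise = noise_spec(seed = 8))
  bad <- syn$dataset
  bad$sem[3] <- 0
  expect_error(chi_squared(truth_theta(parameter_space(), c(10, 100)),
                           bad, parameter_space()), "rows 3")
  bad2 <- syn$dataset
  bad2$observable[1] <- "mystery"
  expect_error(stat1dyn:::validate_dataset(bad2), "mystery")
  expect_error(fit_pathway(syn$dataset[0, ]), "empty")
  sp <- parameter_space()
  sp$name[1] <- "k_bogus"
  expect_error(stat1dyn:::validate_space(sp), "k_bogus")
})

test_that("simulation failure inside the search yields the finite penalty", {
  ds <- data.frame(observable = "RSNC", dose_ng_ml = 100, time_min = 0,
                   mean = 1, sem = 0.1)
  sp <- parameter_space()
  theta <- truth_theta(sp, 100)
  theta["init_SUc"] <- 2     # exceeds the fixed STAT1 total
  expect_equal(chi_squared(theta, ds, sp), stat1dyn:::PENALTY_COST)
  expect_error(chi_squared(theta, ds, sp, penalize = FALSE), "total")
})

test_that("the annealing core recovers a convex optimum", {
  # quadratic surrogate with a known minimizer, no simulation involved
  opt <- c(0.3, -1.2, 2.0)
  obj <- function(u) sum((u - opt)^2)
  lo <- rep(-5, 3); hi <- rep(5, 3)
  set.seed(2)
  st <- optimizer_settings(sa_iterations = 3000, n_restarts = 1,
                           sa_initial_temperature = 1)
  best_u <- lo + stats::runif(3) * (hi - lo)
  best_c <- obj(best_u)
  u <- best_u; cost <- best_c
  temp <- st$sa_initial_temperature
  for (it in seq_len(st$sa_iterations)) {
    j <- sample.int(3, 1)
    u2 <- u
    u2[j] <- min(max(u2[j] + stats::rnorm(1, 0, 0.4), lo[j]), hi[j])
    c2 <- obj(u2)
    if (c2 <= cost || stats::runif(1) < exp(-(c2 - cost) / temp)) {
      u <- u2; cost <- c2
    }
    if (cost < best_c) { best_c <- cost; best_u <- u }
    if (it %% st$sa_temperature_length == 0) temp <- temp * st$sa_cooling_rate
  }
  ref <- stats::nlminb(best_u, obj, lower = lo, upper = hi)
  expect_lt(sum((ref$par - opt)^2), 1e-10)
})

test_that("hybrid fitting is deterministic and monotone in its best trace", {
  syn <- generate_dataset(noise = noise_spec(seed = 8))
  ds <- syn$dataset[syn$dataset$dose_ng_ml == 100, ]
  sp <- parameter_space()
  # shrink the problem: free only four parameters
  for (nm in c("k_inh", "k_bind", "k_unbind", "k_txS", "k_degS", "k_txT",
               "k_degT", "k_transl", "tau_socs", "tau_stat1", "tau_fb",
               "k_shut", "init_SUc")) {
    sp <- fix_parameter(sp, nm, stat1_parameters()[[nm]])
  }
  st <- optimizer_settings(sa_iterations = 150, n_restarts = 2,
                           local_max_iterations = 40, seed = 42)
  f1 <- fit_pathway(ds, sp, st)
  f2 <- fit_pathway(ds, sp, st)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$chi2, f2$chi2)
  # best-so-far is non-increasing within each restart
  for (r in unique(f1$trace$restart)) {
    expect_true(all(diff(f1$trace$best[f1$trace$restart == r]) <= 0))
  }
  # the returned optimum beats every accepted annealing state
  expect_lte(f1$chi2, min(f1$trace$cost) + 1e-12)
  # different seed explores differently
  f3 <- fit_pathway(ds, sp, optimizer_settings(sa_iterations = 150,
                                               n_restarts = 2,
                                               local_max_iterations = 40,
                                               seed = 43))
  expect_false(identical(f3$trace, f1$trace))
})

test_that("fitting a reduced problem recovers the generating trajectories", {
  syn <- generate_dataset(noise = noise_spec(seed = 8))
  ds <- syn$dataset[syn$dataset$dose_ng_ml == 100, ]
  sp <- parameter_space()
  for (nm in c("k_inh", "k_bind", "k_unbind", "k_txS", "k_degS", "k_txT",
               "k_degT", "k_transl", "tau_socs", "tau_stat1", "tau_fb",
               "k_shut", "init_SUc")) {
    sp <- fix_parameter(sp, nm, stat1_parameters()[[nm]])
  }
  f <- fit_pathway(ds, sp, optimizer_settings(sa_iterations = 400,
                                              n_restarts = 2,
                                              local_max_iterations = 150,
                                              seed = 5))
  expect_lt(f$chi2 / f$n_data, 3)
  # fitted curves track the data within twice their SEM almost everywhere
  cover <- abs(f$fitted$y_mod - f$fitted$mean) <= 2 * f$fitted$sem
  expect_gt(mean(cover), 0.85)
})
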