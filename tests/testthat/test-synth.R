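noiseless <- function(seed = 1) {
  noise_spec(blot_cv = 0, loading_cv = 0, ct_sd = 0, cell_ratio_cv = 0,
             seed = seed)
}

test_that("noiseless generation reproduces the normalized truth exactly", {
  truth <- demo_truth()
  syn <- generate_dataset(truth, noiseless())
  ds <- syn$dataset
  for (dose in truth$doses) {
    tr <- simulate_pathway(truth$params, dose, truth$times)
    combos <- stat1dyn:::observable_combos(tr$states)
    # blot series equal the time-average-normalized species combinations
    for (obs in c("STAT1P_nuc", "STAT1_total", "STAT1P_total")) {
      d <- ds[ds$observable == obs & ds$dose_ng_ml == dose, ]
      expect_equal(d$mean, unname(combos[, obs] / mean(combos[, obs])),
                   tolerance = 1e-10)
    }
    # RSNC is reproduced unnormalized
    d <- ds[ds$observable == "RSNC" & ds$dose_ng_ml == dose, ]
    expect_equal(d$mean, unname(combos[, "RSNC"]), tolerance = 1e-10)
    # SOCS1 series excludes the unstimulated point, normalized over the rest
    d <- ds[ds$observable == "SOCS1_mRNA" & ds$dose_ng_ml == dose, ]
    expect_identical(d$time_min, truth$times[truth$times > 0])
    m <- combos[match(d$time_min, truth$times), "SOCS1_mRNA"]
    expect_equal(d$mean, unname(m / mean(m)), tolerance = 1e-10)
  }
  # zero-variance SEMs were replaced by the configured floor
  expect_true(all(ds$sem == 0.05))
  # and are rejected when no floor is configured
  ns0 <- noiseless()
  ns0$sem_floor <- 0
  expect_error(generate_dataset(truth, ns0), "SEM")
})

test_that("generation is reproducible from the seed", {
  a <- generate_dataset(noise = noise_spec(seed = 99))
  b <- generate_dataset(noise = noise_spec(seed = 99))
  c <- generate_dataset(noise = noise_spec(seed = 100))
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$raw, b$raw)
  expect_false(identical(a$dataset$mean, c$dataset$mean))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(7)
  before <- stats::runif(3)
  set.seed(7)
  invisible(generate_dataset(noise = noise_spec(seed = 1)))
  after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("empirical SEMs agree with the lognormal noise model", {
  truth <- demo_truth()
  truth$doses <- 100
  cv <- 0.2
  n_rep <- 6
  times <- truth$times
  tr <- simulate_pathway(truth$params, 100, times)
  combo <- stat1dyn:::observable_combos(tr$states)[, "STAT1_total"]
  sems_raw <- sems_norm <- matrix(NA_real_, 60, length(times))
  for (k in 1:60) {
    syn <- generate_dataset(truth, noise_spec(blot_cv = cv, loading_cv = 0,
                                              lane_gain_sd = 0,
                                              n_replicates = n_rep,
                                              sem_floor = 1e-9,
                                              seed = 1000 + k))
    b <- syn$raw$blots
    b <- b[b$observable == "STAT1_total", ]
    ratio <- b$target_signal / b$loading_signal
    sems_raw[k, ] <- tapply(ratio, b$time_min,
                            function(v) stats::sd(v) / sqrt(length(v)))
    d <- syn$dataset
    sems_norm[k, ] <- d$sem[d$observable == "STAT1_total"]
  }
  # closed-form lognormal moments: a mean-m, cv-0.2 band has sd 0.2 m, so
  # the SEM of n_rep replicates is 0.2 m / sqrt(n_rep)
  theo <- combo * cv / sqrt(n_rep)
  emp <- colMeans(sems_raw)
  expect_true(all(abs(emp - theo) / theo < 0.15))
  # per-series time-average normalization can only shrink the scatter
  level <- combo / mean(combo)
  theo_norm <- level * cv / sqrt(n_rep)
  expect_true(all(colMeans(sems_norm) < theo_norm * 1.05))
})

test_that("the packaged truth reproduces the measured signatures", {
  truth <- demo_truth()
  t <- seq(0, 720, by = 15)
  tr100 <- simulate_pathway(truth$params, 100, t)
  tr10 <- simulate_pathway(truth$params, 10, t)
  c100 <- stat1dyn:::observable_combos(tr100$states)
  c10 <- stat1dyn:::observable_combos(tr10$states)

  p100 <- c100[, "STAT1P_total"]
  # biphasic: most of the early rise is done by 60 min, yet the level keeps
  # growing long afterwards
  expect_gt(p100[t == 60], 0.6 * p100[t == 720])
  expect_gt(p100[t == 720], 1.15 * p100[t == 180])
  # early slope much steeper than late slope
  early <- (p100[t == 30] - p100[t == 0]) / 30
  late <- (p100[t == 720] - p100[t == 360]) / 360
  expect_gt(early, 10 * late)

  # dose monotonicity: pointwise ordering of the phospho signal
  expect_true(all(c100[, "STAT1P_total"] >= c10[, "STAT1P_total"]))
  # and a strictly slower rise at the low dose (later half-maximum)
  half_time <- function(x) t[which(x >= x[t == 720] / 2)[1]]
  expect_gt(half_time(c10[, "STAT1P_total"]),
            half_time(c100[, "STAT1P_total"]))

  # late rise of total STAT1 protein
  tot <- c100[, "STAT1_total"]
  expect_gt(tot[t == 720], 1.2 * tot[t == 0])
  expect_lt(tot[t == 120], 1.05 * tot[t == 0])

  # near-constant nuclear:cytoplasmic ratio
  rs <- c100[, "RSNC"]
  expect_lt(max(rs) / min(rs) - 1, 0.05)

  # headline fraction scale
  npf <- nuclear_phospho_fraction(tr100)
  expect_gt(npf$max, 0.002 * 0.8)
  expect_lt(npf$max, 0.002 * 1.2)

  # unstimulated cells stay flat
  tr0 <- simulate_pathway(truth$params, 0, c(0, 360, 720))
  expect_equal(tr0$states[3, ], tr0$states[1, ], tolerance = 1e-9)
})

test_that("generated datasets pass straight into the fitting stage", {
  syn <- generate_dataset(noise = noise_spec(seed = 3))
  expect_silent(stat1dyn:::validate_dataset(syn$dataset))
  sp <- parameter_space()
  ent <- stat1dyn:::space_entries(sp, unique(syn$dataset$dose_ng_ml))
  theta <- setNames(ent$init, ent$entry)
  c2 <- chi_squared(theta, syn$dataset, sp)
  expect_true(is.finite(c2) && c2 > 0)
})
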