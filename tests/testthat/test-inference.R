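test_that("MAP recovers random-preference parameters from 60 trials", {
  set.seed(30)
  est <- replicate(20, {
    d <- sim_phase1_dataset(-4, 1)
    map_fit("ku", d)$estimate[["m"]]
  })
  expect_lt(abs(median(est) - (-4)), 0.5)
})

test_that("degenerate one-sided data raise the boundary flag", {
  tr <- make_trials(rep(1, 30), "self", 1, 3, 10, rep(1, 30))
  f <- map_fit("ku", tr)
  expect_true(f$boundary)
  expect_false(f$converged)
})

test_that("softmax MAP matches an exhaustive grid search on a toy dataset", {
  tr <- make_trials(rep(1, 8), "self",
                    R0 = 1, RD = c(3, 3, 2, 2, 4, 4, 2.5, 2.5),
                    D = c(10, 10, 30, 30, 5, 5, 60, 60),
                    choice = c(1, 0, 0, 0, 1, 1, 1, 0))
  f <- map_fit("kt", tr)
  ks <- seq(-8, 2, 0.01)
  lts <- seq(-3, 2, 0.01)
  best <- c(-Inf, NA, NA)
  for (lt in lts) {
    ll <- vapply(ks, function(k)
      choice_loglik(kt_policy(tr, k, exp(lt)), tr$choice), numeric(1))
    i <- which.max(ll)
    if (ll[i] > best[1]) best <- c(ll[i], ks[i], lt)
  }
  expect_equal(f$loglik, best[1], tolerance = 1e-3)
  expect_equal(f$estimate[["k"]], best[2], tolerance = 0.05)
  expect_equal(log(f$estimate[["temp"]]), best[3], tolerance = 0.05)
})

test_that("the BIC identity holds for every fit", {
  set.seed(33)
  d <- sim_phase1_dataset(-5, 2)
  for (m in c("kt", "ku")) {
    f <- map_fit(m, d)
    expect_equal(f$bic, -2 * f$loglik + f$n_params * log(f$n_trials))
  }
})

test_that("the component-wise sampler reproduces a known Gaussian target", {
  set.seed(34)
  draws <- tasteshift:::metropolis_cw(
    function(th) sum(dnorm(th, c(1, -2), c(1, 0.5), log = TRUE)),
    init = c(0, 0), iter = 20000, warmup = 1000, thin = 5)
  mcse <- apply(draws, 2, sd) / sqrt(apply(draws, 2, ess))
  expect_lt(abs(median(draws[, 1]) - 1), 4 * max(mcse[1], 0.02))
  expect_lt(abs(median(draws[, 2]) - (-2)), 4 * max(mcse[2], 0.02))
  expect_equal(sd(draws[, 1]), 1, tolerance = 0.1)
  expect_equal(sd(draws[, 2]), 0.5, tolerance = 0.1)
})

test_that("effective sample size is sane on independent draws", {
  set.seed(35)
  x <- rnorm(4000)
  expect_equal(ess(x), 4000, tolerance = 0.2)
  expect_equal(ess(rep(1, 100)), 0)
  # heavily autocorrelated chain has far fewer effective draws
  y <- as.numeric(stats::filter(rnorm(4000), 0.95, "recursive"))
  expect_lt(ess(y), 1000)
})

test_that("MCMC fits are seed-reproducible and agree with the MAP mode", {
  set.seed(36)
  d <- sim_phase1_dataset(-4.5, 1.5)
  pr <- default_priors("ku")
  f1 <- mcmc_fit("ku", d, pr, chain = list(iter = 4000, warmup = 800,
                                           thin = 4, seed = 11))
  f2 <- mcmc_fit("ku", d, pr, chain = list(iter = 4000, warmup = 800,
                                           thin = 4, seed = 11))
  expect_identical(f1$samples, f2$samples)
  expect_true(all(f1$ess >= 100))
  m <- map_fit("ku", d, pr)
  psd <- apply(f1$samples, 2, sd)
  expect_true(all(abs(f1$transformed - m$transformed) <= 0.5 * psd + 0.05))
})

test_that("empirical-Bayes refits shrink estimates and restore excluded fits", {
  set.seed(37)
  pop <- lapply(1:25, function(i)
    sim_phase1_dataset(rnorm(1, -4.5, 2), exp(rnorm(1, 0, 0.7)),
                       id = sprintf("e%02d", i)))
  names(pop) <- vapply(pop, `[[`, character(1), "id")
  # one degenerate participant whose stage-1 fit cannot converge
  pop[[25]]$trials$choice <- 1L
  fits <- fit_population(pop, "ku")
  expect_false(fits[[25]]$converged)
  eb <- empirical_bayes_refit(fits, pop)
  expect_true("e25" %in% eb$excluded)
  expect_true(is.finite(eb$fits[["e25"]]$loglik))  # reappears with estimates
  t1 <- fits_table(fits)[1:24, ]
  t3 <- fits_table(eb$fits)[1:24, ]
  expect_lte(var(t3$m), var(t1$m))
  expect_lte(var(log(t3$u)), var(log(t1$u)))
  # sample priors sit near the generating hyperparameters
  pm <- eb$priors$mean[eb$priors$param == "m"]
  expect_lt(abs(pm - (-4.5)), 3 * 2.3 / sqrt(24))
  expect_error(empirical_bayes_refit(fits[1:5], pop[1:5]), "10 converged")
})

test_that("model comparison handles ties and guards against mismatched inputs", {
  set.seed(38)
  pop <- lapply(1:12, function(i)
    sim_phase1_dataset(rnorm(1, -4.5, 2), 1, id = sprintf("c%02d", i)))
  names(pop) <- vapply(pop, `[[`, character(1), "id")
  ku <- fit_population(pop, "ku", priors = default_priors("ku"))
  cmp <- compare_models(ku, ku)
  expect_equal(cmp$frac_a_better, 0.5)
  expect_equal(cmp$total_dbic, 0)
  expect_equal(cmp$wilcoxon_p, 1)
  kt <- fit_population(pop, "kt", priors = default_priors("kt"))
  expect_named(compare_models(ku, kt)$delta, c("participant_id", "dll", "dbic"))
  expect_error(compare_models(ku, kt[1:5]), "participant sets")
})

test_that("the perturbation model detects injected taste jumps", {
  set.seed(39)
  jumps <- c(-2, -1, 0, 1, 2)
  est <- numeric(length(jumps))
  dbic_jump2 <- NA_real_
  for (i in seq_along(jumps)) {
    d <- sim_jump_dataset(-5, 1, jumps[i])
    fp <- fit_perturbation_model(d, priors = default_priors("perturb"))
    est[i] <- fp$estimate[["m3"]] - fp$estimate[["m1"]]
    fs <- map_fit("ku_static", d, priors = default_priors("ku_static"))
    if (jumps[i] == 2) dbic_jump2 <- fs$bic - fp$bic
  }
  # recovered jump tracks the injected jump with slope ~ 1
  sl <- coef(lm(est ~ jumps))[2]
  expect_gt(sl, 0.7)
  expect_lt(sl, 1.3)
  # a real jump is strong evidence for the perturbation model ...
  expect_gt(dbic_jump2, 6)
  # ... while without a jump the parameter penalty favours the static model
  # on average (single datasets fluctuate by a chi-square(1)/2 of evidence)
  dbic_null <- replicate(5, {
    d <- sim_jump_dataset(-5, 1, 0)
    map_fit("ku_static", d, priors = default_priors("ku_static"))$bic -
      fit_perturbation_model(d, priors = default_priors("perturb"))$bic
  })
  expect_lt(mean(dbic_null), 0)
  expect_error(map_fit("perturb", sim_phase1_dataset(-4, 1)$trials),
               "phases 1 and 3")
})
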