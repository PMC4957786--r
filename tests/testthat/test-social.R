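test_that("self-posterior reduces correctly in the analytic corner cases", {
  # an infinitely dispersed reference population makes the Other irrelevant
  b <- posterior_self(gaussian_belief(-5, 2), gaussian_belief(-2, 0.3), 1e9)
  expect_equal(b$mean, -5, tolerance = 1e-12)
  expect_equal(1 / b$prec, 2, tolerance = 1e-6)
  # equal precisions 1 and 1/(2*0.5 + 0): posterior at the midpoint
  b <- posterior_self(gaussian_belief(0, 1), gaussian_belief(2, 0),
                      sqrt(0.5))
  expect_equal(b$mean, 1)
  expect_equal(1 / b$prec, 0.5)
  expect_error(posterior_self(flat_belief(), flat_belief(), 1), "improper")
})

test_that("other-posterior mirrors the self-posterior and widens a flat start", {
  # before any data about the Other: self-belief widened by 2 sigma_r^2
  b <- posterior_other(gaussian_belief(-5, 2), flat_belief(), 1.5)
  expect_equal(b$mean, -5)
  expect_equal(1 / b$prec, 2 + 2 * 1.5^2)
  # role symmetry
  a <- gaussian_belief(-6, 1.3)
  o <- gaussian_belief(-2, 0.6)
  expect_equal(posterior_other(a, o, 1.1)$mean,
               posterior_self(o, a, 1.1)$mean)
})

test_that("closed-form posteriors match brute-force integration of the joint", {
  or <- grid_posterior_self_oracle(-5, 2, -2.7, 0.4, 1.13)
  b <- posterior_self(gaussian_belief(-5, 2), gaussian_belief(-2.7, 0.4),
                      1.13)
  expect_equal(b$mean, or$mean, tolerance = 1e-3)
  expect_equal(1 / b$prec, or$var, tolerance = 1e-3)
})

test_that("the posterior self never overtakes the Other and shrinks variance", {
  set.seed(31)
  for (rep in 1:40) {
    m_s <- runif(1, -9, 1); u_s <- runif(1, 0.05, 4)
    ko <- m_s + runif(1, -4, 4); vo <- runif(1, 0.02, 3)
    sr <- runif(1, 0.3, 3)
    b <- posterior_self(gaussian_belief(m_s, u_s), gaussian_belief(ko, vo), sr)
    shift <- b$mean - m_s
    expect_lte(abs(shift), abs(ko - m_s) + 1e-12)
    if (abs(ko - m_s) > 1e-9) expect_gte(shift * (ko - m_s), 0)
    expect_lte(1 / b$prec, u_s + 1e-12)
  }
})

test_that("shift grows with taste uncertainty and shrinks with reference dispersion", {
  ko <- -2; vo <- 0.2; m_s <- -5
  shift <- function(u_s, sr)
    posterior_self(gaussian_belief(m_s, u_s), gaussian_belief(ko, vo),
                   sr)$mean - m_s
  us <- seq(0.2, 4, length.out = 12)
  expect_true(all(diff(vapply(us, shift, numeric(1), sr = 1)) > 0))
  srs <- seq(0.3, 3, length.out = 12)
  expect_true(all(diff(vapply(srs, function(s) shift(1.5, s),
                              numeric(1))) < 0))
})

test_that("the other-likelihood filter is flat with no data and calibrated", {
  b <- other_likelihood_filter(NULL, integer(0))
  expect_equal(b$prec, 0)
  # calibration: the Gaussianised likelihood should cover the generating k_o
  set.seed(55)
  k_o <- -2.2
  cfg <- task_config()
  hit <- logical(200)
  vars60 <- vars70 <- numeric(200)
  for (r in 1:200) {
    op <- random_option_pairs(70, cfg)
    ch <- as.integer(runif(70) < kt_policy(op, k_o, 1))
    b60 <- other_likelihood_filter(op[1:60, ], ch[1:60])
    b70 <- other_likelihood_filter(op, ch)
    sd60 <- sqrt(1 / b60$prec)
    hit[r] <- abs(b60$mean - k_o) <= 2 * sd60
    vars60[r] <- 1 / b60$prec
    vars70[r] <- 1 / b70$prec
  }
  expect_gte(mean(hit), 0.95)
  # more informative trials tighten the likelihood in expectation
  expect_lt(mean(vars70), mean(vars60))
})

test_that("per-trial policies match a step-by-step hand filter on a toy script", {
  pars <- ps_params(m_s = -5, u_s = 1.5, sigma_r = 1.2, tau_o = 1.8,
                    xi = 0.04)
  tr <- make_trials(
    phase = c(1, 2, 2, 3, 3, 3),
    role = c("self", "other", "other", "self", "other", "self"),
    R0 = c(1, 2, 1, 3, 1, 2), RD = c(3, 5, 2.5, 8, 3.2, 4),
    D = c(10, 60, 25, 100, 14, 40),
    choice = c(1, 0, 1, 1, 0, 0),
    other_choice = c(NA, 1, 1, NA, 0, NA),
    feedback = c(NA, 0, 1, NA, 1, NA))
  filt <- tasteshift:::other_filter_path(tr)
  got <- tasteshift:::ps_policy_vec(pars, tr, filt)

  # independent recomputation with inline arithmetic only
  grid <- seq(-12, 2, length.out = 601)
  logw <- rep(0, 601)
  expected <- numeric(6)
  for (t in 1:6) {
    th <- log((tr$RD[t] / tr$R0[t] - 1) / tr$D[t])
    if (sum(abs(logw)) == 0) { w_o <- 0; ohat <- 0; vo <- Inf }
    else {
      w <- exp(logw - max(logw)); w <- w / sum(w)
      ohat <- sum(w * grid); vo <- sum(w * (grid - ohat)^2)
      w_o <- 1 / (2 * pars$sigma_r^2 + vo)
    }
    if (tr$role[t] == "self") {
      wp <- 1 / pars$u_s + w_o
      mu <- (pars$m_s / pars$u_s + w_o * ohat) / wp
      p <- pnorm((th - mu) * sqrt(wp))
      expected[t] <- p * (1 - pars$xi) + pars$xi / 2
    } else {
      ws <- 1 / (2 * pars$sigma_r^2 + pars$u_s)
      prec_o <- if (is.infinite(vo)) 0 else 1 / vo
      wp <- prec_o + ws
      mu <- (prec_o * ohat + ws * pars$m_s) / wp
      p <- pnorm((th - mu) * sqrt(wp))
      expected[t] <- p^(1 / pars$tau_o) /
        (p^(1 / pars$tau_o) + (1 - p)^(1 / pars$tau_o))
      # the Other's revealed choice updates the filter AFTER this trial
      QD <- tr$RD[t] / (1 + exp(grid) * tr$D[t])
      pi1 <- 1 / (1 + exp(-(QD - tr$R0[t])))
      logw <- logw + if (tr$other_choice[t] == 1) log(pi1) else log(1 - pi1)
    }
  }
  expect_equal(got, expected, tolerance = 1e-8)
})

test_that("phase-1 trials reduce the shift model to the plain KU policy", {
  pars <- ps_params(-4.2, 1.1, 0.9, 1.5, 0.06)
  op <- option_pairs(2, 5, 30)
  expect_equal(ps_trial_policy(op, "self", pars),
               apply_lapse(ku_policy(op, -4.2, 1.1), 0.06))
  expect_error(ps_trial_policy(op, "parent", pars), "role")
  # whole-dataset reduction: phase-1-only data, xi = 0
  set.seed(12)
  d <- sim_phase1_dataset(-4, 1.2, n = 40)
  pars0 <- ps_params(-4, 1.2, 1, 1, 0)
  expect_equal(ps_loglik(pars0, d$trials),
               choice_loglik(ku_policy(d$trials, -4, 1.2), d$trials$choice))
})

test_that("boundary parameters collapse the shift model onto plain KU", {
  # huge sigma_r: self choices unaffected by the Other
  set.seed(13)
  ag <- did_agent("ps", m_s = -4.5, u_s = 1, sigma_r = 1e6, tau_o = 1,
                  xi = 0)
  d <- simulate_participant(ag, id = "b")
  tr <- d$trials
  pars <- ps_params(-4.5, 1, 1e6, 1, 0)
  filt <- tasteshift:::other_filter_path(tr)
  p <- tasteshift:::ps_policy_vec(pars, tr, filt)
  sf <- tr$role == "self"
  expect_equal(p[sf], ku_policy(tr[sf, ], -4.5, 1), tolerance = 1e-6)
})

test_that("shift-model likelihood requires feedback on phase-2 trials", {
  tr <- make_trials(phase = c(1, 2), role = c("self", "other"),
                    R0 = 1, RD = 3, D = 10, choice = c(1, 0))
  expect_error(ps_loglik(ps_params(-4, 1, 1, 1, 0), tr), "feedback|choice")
})

test_that("shift-model likelihood profiles peak near the generating sigma_r", {
  set.seed(77)
  ag <- did_agent("ps", m_s = -4, u_s = 2, sigma_r = 0.8, tau_o = 1.2,
                  xi = 0.01)
  lls <- matrix(NA_real_, 8, 3)
  srs <- c(0.8, 4, 15)
  for (r in 1:8) {
    d <- simulate_participant(ag, id = sprintf("pr%d", r))
    filt <- tasteshift:::other_filter_path(d$trials)
    lls[r, ] <- vapply(srs, function(s)
      ps_loglik(ps_params(-4, 2, s, 1.2, 0.01), d$trials, filt),
      numeric(1))
  }
  # on average the generating value beats values forced far away
  expect_gt(mean(lls[, 1]), mean(lls[, 2]))
  expect_gt(mean(lls[, 2]), mean(lls[, 3]))
})
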