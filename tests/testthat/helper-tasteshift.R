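# Shared helpers: independent numerical oracles and synthetic fixtures.

# Brute-force oracle for the coupled self/other posterior: numerical
# integration of the full joint over (k_r, k_o) on dense grids, completely
# independent of the package's closed-form Gaussian algebra.
#   p(k_s | d_s, d_o) propto N(k_s; m_s, u_s) *
#     int dk_r int dk_o N(k_o; ko_hat, vo) N(k_s; k_r, sr^2) N(k_o; k_r, sr^2)
# (flat prior over k_r). Returns moment-matched mean and variance.
grid_posterior_self_oracle <- function(m_s, u_s, ko_hat, vo, sigma_r,
                                       n = 1201) {
  lo <- min(m_s - 8 * sqrt(u_s), ko_hat - 8 * sqrt(vo + 2 * sigma_r^2))
  hi <- max(m_s + 8 * sqrt(u_s), ko_hat + 8 * sqrt(vo + 2 * sigma_r^2))
  ks <- seq(lo, hi, length.out = n)
  kr <- seq(lo - 4 * sigma_r, hi + 4 * sigma_r, length.out = n)
  ko <- seq(ko_hat - 8 * sqrt(vo), ko_hat + 8 * sqrt(vo), length.out = n)
  dko <- ko[2] - ko[1]
  dkr <- kr[2] - kr[1]
  # I1(kr) = int dko N(ko; ko_hat, vo) N(ko; kr, sr^2)
  I1 <- as.vector(exp(-outer(kr, ko, "-")^2 / (2 * sigma_r^2)) %*%
                    stats::dnorm(ko, ko_hat, sqrt(vo))) * dko
  # g(ks) = int dkr N(ks; kr, sr^2) I1(kr)
  g <- as.vector(exp(-outer(ks, kr, "-")^2 / (2 * sigma_r^2)) %*% I1) * dkr
  w <- stats::dnorm(ks, m_s, sqrt(u_s)) * g
  w <- w / sum(w)
  m <- sum(w * ks)
  list(mean = m, var = sum(w * (ks - m)^2))
}

# Minimal trial-table constructor for hand-built toy datasets.
make_trials <- function(phase, role, R0, RD, D, choice,
                        other_choice = NA_integer_, feedback = NA_integer_,
                        id = "toy") {
  n <- length(phase)
  data.frame(participant_id = id, phase = as.integer(phase),
             trial_index = seq_len(n), role = role,
             R0 = rep_len(R0, n), RD = rep_len(RD, n), D = rep_len(D, n),
             choice = as.integer(choice),
             other_choice = as.integer(rep_len(other_choice, n)),
             feedback = as.integer(rep_len(feedback, n)),
             stringsAsFactors = FALSE)
}

as_dataset <- function(trials, id = trials$participant_id[1], truth = list()) {
  structure(list(id = id, trials = trials, truth = truth),
            class = "participant_dataset")
}

# Phase-1-only dataset from a random-preference agent, without running the
# full task machinery: choices sampled directly from the KU policy on the
# standard option set (repeated to n trials).
sim_phase1_dataset <- function(m, u, n = 60, id = "sim") {
  cfg <- task_config()
  op <- standard_option_set(cfg)
  op <- op[rep_len(seq_len(nrow(op)), n), ]
  p <- ku_policy(op, m, u)
  make_trials(rep(1L, n), "self", op$R0, op$RD, op$D,
              stats::runif(n) < p, id = id) |> as_dataset(id)
}

# Composite self-only dataset with an injected taste jump between phases:
# phase-1 choices at taste m, phase-3 self choices at m + jump, shared u.
sim_jump_dataset <- function(m, u, jump, n_per_phase = 60, id = "jump") {
  cfg <- task_config()
  op <- standard_option_set(cfg)
  op <- op[rep_len(seq_len(nrow(op)), n_per_phase), ]
  p1 <- ku_policy(op, m, u)
  p3 <- ku_policy(op, m + jump, u)
  tr <- rbind(
    make_trials(rep(1L, n_per_phase), "self", op$R0, op$RD, op$D,
                stats::runif(n_per_phase) < p1, id = id),
    make_trials(rep(3L, n_per_phase), "self", op$R0, op$RD, op$D,
                stats::runif(n_per_phase) < p3, id = id))
  tr$trial_index <- seq_len(nrow(tr))
  as_dataset(tr, id)
}

# Memoised fixtures shared across test files (helpers persist for the whole
# test_dir() session, so expensive cohorts are built once).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 50 preference-shift participants through the full task, with stage-1 MAP
# fits (weakly informative priors) and the empirical-Bayes refit.
ps_cohort_fixture <- function() {
  fixture("ps_cohort", function() {
    pop <- simulate_population(50, population_spec("ps"), seed = 7)
    s1 <- fit_population(pop, "ps", priors = default_priors("ps"))
    eb <- empirical_bayes_refit(s1, pop)
    list(pop = pop, truth = truth_table(pop), stage1 = s1, eb = eb)
  })
}
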