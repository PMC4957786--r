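#' Configuration of the three-phase delegated discounting task
#'
#' Defaults encode the study conditions: a population of log discount rates
#' `k ~ N(-4.5, 2.3^2)`; an Other whose `k_o` sits one population SD (2.3)
#' from the participant's phase-1 estimate, towards -4.5 with probability 2/3;
#' phase 1 of 30 standard plus 30 adaptively selected trials; phase 2 until
#' 8-of-the-last-10 correct or 60 trials; phase 3 of interleaved 10-trial
#' self/other mini-blocks.
#'
#' @param pop_mean_k,pop_sd_k population mean and SD of `k = ln K`.
#' @param other_shift distance of the Other's `k_o` from the phase-1 estimate.
#' @param p_toward probability the shift points towards `pop_mean_k`.
#' @param n_standard,n_adaptive phase-1 trial counts (standard / adaptive arm).
#' @param phase2_max,phase2_window,phase2_ncorrect phase-2 stopping rule:
#'   stop at `phase2_ncorrect` correct of the last `phase2_window` trials
#'   (full window required) or at `phase2_max` trials.
#' @param phase3_blocks number of phase-3 mini-blocks per role.
#' @param block_size trials per mini-block.
#' @param n_candidates size of the random candidate pool the adaptive arm
#'   scores on each trial.
#' @param assumed_T softmax temperature assumed in the in-task grid tracker
#'   and used to generate the Other's actual choices.
#' @param grid_lo,grid_hi,grid_n `k` grid of the in-task posterior tracker.
#' @param k_lo,k_hi range of indifference points spanned by generated options.
#' @param R0_set immediate reward menu (currency units).
#' @param D_max maximum delay in days.
#' @return A list of class `task_config`.
#' @export
task_config <- function(pop_mean_k = -4.5, pop_sd_k = 2.3,
                        other_shift = 2.3, p_toward = 2 / 3,
                        n_standard = 30, n_adaptive = 30,
                        phase2_max = 60, phase2_window = 10,
                        phase2_ncorrect = 8,
                        phase3_blocks = 3, block_size = 10,
                        n_candidates = 200, assumed_T = 1,
                        grid_lo = -12, grid_hi = 2, grid_n = 601,
                        k_lo = -9, k_hi = 0,
                        R0_set = 1:10, D_max = 365) {
  stopifnot(p_toward >= 0, p_toward <= 1,
            n_standard > 0, n_adaptive > 0, phase2_max > 0,
            phase3_blocks >= 0, block_size > 0, n_candidates > 0)
  structure(as.list(environment()), class = "task_config")
}

# Build option pairs whose indifference points are exactly the requested k
# values: RD = R0 * (1 + D * exp(k)). Delays scale as exp(-k) (capped at
# D_max, floored at 1 day) so reward ratios stay in a plausible (1, 5] band.
pairs_at_indifference <- function(k, cfg, D_jitter = NULL) {
  n <- length(k)
  D <- round(if (is.null(D_jitter)) 2 * exp(-k) else D_jitter * exp(-k))
  D <- pmin(cfg$D_max, pmax(1, D))
  R0 <- rep_len(cfg$R0_set, n)
  option_pairs(R0, R0 * (1 + D * exp(k)), D)
}

#' Standard phase-1 option set
#'
#' 30 pairs (by default) whose indifference `k` values are evenly spaced over
#' `[k_lo, k_hi]`, covering a wide range of discount rates. Deterministic
#' given the configuration.
#'
#' @param cfg a [task_config()].
#' @return An option-pair table with `cfg$n_standard` rows.
#' @export
standard_option_set <- function(cfg = task_config()) {
  k <- seq(cfg$k_lo, cfg$k_hi, length.out = cfg$n_standard)
  pairs_at_indifference(k, cfg)
}

# Random option pairs with indifference points uniform over [k_lo, k_hi] and
# jittered delays; used for adaptive candidates and phase-2/3 menus.
random_option_pairs <- function(n, cfg = task_config()) {
  k <- stats::runif(n, cfg$k_lo, cfg$k_hi)
  pairs_at_indifference(k, cfg, D_jitter = stats::runif(n, 1, 4))
}

#' Posterior over the discount rate on a grid
#'
#' @param cfg a [task_config()].
#' @return List of class `grid_posterior` with nodes `k` and normalised
#'   masses `p` (flat at construction).
#' @export
grid_posterior <- function(cfg = task_config()) {
  k <- k_grid(cfg$grid_lo, cfg$grid_hi, cfg$grid_n)
  structure(list(k = k, p = rep(1 / length(k), length(k))),
            class = "grid_posterior")
}

#' Bayes update of the grid posterior after one observed choice
#'
#' Multiplies each node's mass by the softmax likelihood of the observed
#' choice at that node (temperature `assumed_T`) and renormalises.
#'
#' @param post a [grid_posterior()].
#' @param op one-row option-pair table.
#' @param choice observed choice (1 = delayed).
#' @param assumed_T likelihood temperature.
#' @return Updated `grid_posterior`.
#' @export
grid_update <- function(post, op, choice, assumed_T = 1) {
  validate_option_pairs(op)
  pi1 <- kt_policy(op, post$k, assumed_T)
  lik <- if (choice == 1) pi1 else 1 - pi1
  w <- post$p * lik
  s <- sum(w)
  if (!is.finite(s) || s <= 0) stop("grid posterior vanished")
  post$p <- w / s
  post
}

grid_entropy <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

grid_mode <- function(post) post$k[which.max(post$p)]

#' Entropy-minimising adaptive trial selection
#'
#' Scores each candidate pair by the expected entropy of the grid posterior
#' after observing the choice it would elicit (expectation over the two
#' predicted choices under the current posterior), and returns the candidate
#' with the smallest expected posterior entropy. Ties break to the lowest
#' candidate index.
#'
#' @param post a [grid_posterior()].
#' @param candidates candidate option-pair table (>= 1 row).
#' @param assumed_T likelihood temperature.
#' @return The selected one-row option-pair table, with the expected entropy
#'   in attribute `"expected_entropy"`.
#' @export
adaptive_select <- function(post, candidates, assumed_T = 1) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("empty candidate list")
  QD <- outer(seq_len(nrow(candidates)), post$k,
              function(i, k) candidates$RD[i] / (1 + exp(k) * candidates$D[i]))
  piD <- stats::plogis((QD - candidates$R0) / assumed_T)  # n_cand x n_grid
  pred1 <- drop(piD %*% post$p)
  eh <- vapply(seq_len(nrow(candidates)), function(j) {
    w1 <- post$p * piD[j, ]
    w0 <- post$p - w1
    s1 <- sum(w1)
    h1 <- if (s1 > 0) grid_entropy(w1 / s1) else 0
    h0 <- if (s1 < 1) grid_entropy(w0 / (1 - s1)) else 0
    pred1[j] * h1 + (1 - pred1[j]) * h0
  }, numeric(1))
  sel <- which.min(eh)  # which.min takes the first minimum: the tie rule
  out <- candidates[sel, , drop = FALSE]
  attr(out, "expected_entropy") <- eh[sel]
  out
}

#' Draw the Other's log discount rate
#'
#' `k_o = k_b +/- other_shift`, with the sign pointing towards the population
#' mean with probability `p_toward` (2/3 by default). If `k_b` equals the
#' population mean exactly the sign is uniform.
#'
#' @param k_b phase-1 point estimate of the participant's `k`.
#' @param cfg a [task_config()].
#' @return The Other's `k_o`.
#' @export
choose_other_k <- function(k_b, cfg = task_config()) {
  if (!is.finite(k_b)) stop("k_b must be finite")
  toward <- sign(cfg$pop_mean_k - k_b)
  if (toward == 0) toward <- sample(c(-1, 1), 1)
  s <- if (stats::runif(1) < cfg$p_toward) toward else -toward
  k_b + s * cfg$other_shift
}

#' Phase-2 stopping rule
#'
#' @param correct logical/0-1 history of feedback correctness so far.
#' @param cfg a [task_config()].
#' @return `TRUE` iff a full recent window holds enough correct answers
#'   (default 8 of the last 10) or the trial cap (default 60) is reached.
#' @export
phase2_should_stop <- function(correct, cfg = task_config()) {
  n <- length(correct)
  if (n >= cfg$phase2_max) return(TRUE)
  n >= cfg$phase2_window &&
    sum(utils::tail(correct, cfg$phase2_window)) >= cfg$phase2_ncorrect
}

#' Generative agent specification
#'
#' `"ku"` agents sample their taste from `N(m, u)` each self trial (optionally
#' with lapse `xi`) and treat the Other as essentially irrelevant to their own
#' taste (`sigma_r` very large) while still learning the Other's taste from
#' observed choices. `"ps"` agents run the full uncertainty-relevance model.
#' `"kt"` agents use the softmax policy with taste `k` and temperature `temp`.
#'
#' @param type `"ku"`, `"ps"` or `"kt"` (named `type` so that parameter
#'   names passed through `...` cannot partially match it).
#' @param ... model parameters: `m`, `u`, `xi` (ku); `m_s`, `u_s`, `sigma_r`,
#'   `tau_o`, `xi` (ps); `k`, `temp`, `xi` (kt).
#' @return A list of class `did_agent`.
#' @export
did_agent <- function(type = c("ku", "ps", "kt"), ...) {
  model <- match.arg(type)
  pars <- list(...)
  agent <- switch(model,
    ku = ps_params(m_s = pars$m, u_s = pars$u, sigma_r = 1e6,
                   tau_o = if (is.null(pars$tau_o)) 1 else pars$tau_o,
                   xi = if (is.null(pars$xi)) 0 else pars$xi),
    ps = ps_params(m_s = pars$m_s, u_s = pars$u_s, sigma_r = pars$sigma_r,
                   tau_o = pars$tau_o, xi = pars$xi),
    kt = {
      if (is.null(pars$k) || is.null(pars$temp)) stop("kt agent needs k, temp")
      list(k = pars$k, temp = pars$temp,
           xi = if (is.null(pars$xi)) 0 else pars$xi)
    })
  structure(list(model = model, params = agent, spec = pars),
            class = "did_agent")
}

# One generative choice probability. other_b is the agent's own filtered
# belief about the Other.
agent_policy <- function(agent, op, role, other_b) {
  if (agent$model == "kt") {
    if (role == "self")
      return(apply_lapse(kt_policy(op, agent$params$k, agent$params$temp),
                         agent$params$xi))
    # for-other choices: softmax at the current point estimate of the Other
    if (other_b$prec == 0) return(0.5)
    return(kt_policy(op, other_b$mean, agent$params$temp))
  }
  ps_trial_policy(op, role, agent$params, other_b)
}

empty_trials <- function() {
  data.frame(participant_id = character(), phase = integer(),
             trial_index = integer(), role = character(),
             R0 = numeric(), RD = numeric(), D = numeric(),
             choice = integer(), other_choice = integer(),
             feedback = integer(), stringsAsFactors = FALSE)
}

#' Simulate one participant through the full task
#'
#' Phase 1 interleaves the standard set with entropy-minimising adaptive
#' trials while tracking a grid posterior over the participant's `k` (softmax
#' likelihood at `assumed_T`). The posterior mode `k_b` then fixes the Other's
#' `k_o` via [choose_other_k()]. Phase 2 presents choose-for-other trials with
#' veridical feedback (the Other's actual choice is simulated with the softmax
#' policy at `assumed_T`) until [phase2_should_stop()]. Phase 3 interleaves
#' self and other mini-blocks; other trials continue to reveal the Other's
#' choice, so the agent's filter keeps updating.
#'
#' @param agent a [did_agent()].
#' @param cfg a [task_config()].
#' @param id participant identifier.
#' @param phases subset of `1:3` to run (phase 1 is always required).
#' @return A list of class `participant_dataset` with elements `trials`
#'   (the trial table), `truth` (generating parameters, `k_b`, `k_o`, and the
#'   direction of the Other), and `id`.
#' @export
simulate_participant <- function(agent, cfg = task_config(), id = "p1",
                                 phases = 1:3) {
  stopifnot(1 %in% phases)
  rows <- list()
  ti <- 0L
  add_row <- function(phase, role, op, choice, other_choice = NA_integer_,
                      feedback = NA_integer_) {
    ti <<- ti + 1L
    rows[[ti]] <<- data.frame(
      participant_id = id, phase = phase, trial_index = ti, role = role,
      R0 = op$R0, RD = op$RD, D = op$D, choice = choice,
      other_choice = other_choice, feedback = feedback,
      stringsAsFactors = FALSE)
  }

  # agent-side filtered belief about the Other (grid over k)
  agent_grid <- k_grid(cfg$grid_lo, cfg$grid_hi, cfg$grid_n)
  agent_logw <- rep(0, length(agent_grid))
  agent_other_b <- flat_belief()
  observe_other <- function(op, oc) {
    agent_logw <<- agent_logw +
      grid_choice_loglik(op, oc, agent_grid, cfg$assumed_T)
    agent_other_b <<- moment_match_grid(agent_grid, agent_logw)
  }

  # ---- phase 1: interleave standard and adaptive arms ----
  std <- standard_option_set(cfg)
  std <- std[sample.int(nrow(std)), , drop = FALSE]
  tracker <- grid_posterior(cfg)
  n1 <- cfg$n_standard + cfg$n_adaptive
  use_std <- rep_len(c(TRUE, FALSE), n1)
  si <- 0L
  for (t in seq_len(n1)) {
    if (use_std[t] && si < nrow(std)) {
      si <- si + 1L
      op <- std[si, , drop = FALSE]
    } else {
      op <- adaptive_select(tracker, random_option_pairs(cfg$n_candidates, cfg),
                            cfg$assumed_T)
    }
    p <- agent_policy(agent, op, "self", agent_other_b)
    ch <- as.integer(stats::runif(1) < p)
    tracker <- grid_update(tracker, op, ch, cfg$assumed_T)
    add_row(1L, "self", op, ch)
  }
  k_b <- grid_mode(tracker)
  k_o <- choose_other_k(k_b, cfg)

  other_choice_for <- function(op)
    as.integer(stats::runif(1) < kt_policy(op, k_o, cfg$assumed_T))

  # Phase-2/3 menus are "as in phase 1": half drawn at random, half selected
  # by the entropy rule against the running posterior for whoever the trial
  # is about (the participant's own k on self trials, the Other's k_o on
  # other trials, tracked from the Other's revealed choices).
  other_tracker <- grid_posterior(cfg)
  next_option <- function(adaptive, tracker) {
    if (adaptive)
      adaptive_select(tracker, random_option_pairs(cfg$n_candidates, cfg),
                      cfg$assumed_T)
    else random_option_pairs(1, cfg)
  }

  # ---- phase 2: learn the Other with feedback ----
  if (2 %in% phases) {
    correct <- integer(0)
    while (!phase2_should_stop(correct, cfg)) {
      op <- next_option(length(correct) %% 2 == 1, other_tracker)
      p <- agent_policy(agent, op, "other", agent_other_b)
      guess <- as.integer(stats::runif(1) < p)
      oc <- other_choice_for(op)
      fb <- as.integer(guess == oc)
      correct <- c(correct, fb)
      add_row(2L, "other", op, guess, oc, fb)
      other_tracker <- grid_update(other_tracker, op, oc, cfg$assumed_T)
      observe_other(op, oc)
    }
  }

  # ---- phase 3: interleaved self/other mini-blocks ----
  if (3 %in% phases) {
    for (b in seq_len(cfg$phase3_blocks)) {
      for (role in c("self", "other")) {
        for (j in seq_len(cfg$block_size)) {
          if (role == "self") {
            op <- next_option(j %% 2 == 0, tracker)
            p <- agent_policy(agent, op, role, agent_other_b)
            ch <- as.integer(stats::runif(1) < p)
            tracker <- grid_update(tracker, op, ch, cfg$assumed_T)
            add_row(3L, role, op, ch)
          } else {
            op <- next_option(j %% 2 == 0, other_tracker)
            p <- agent_policy(agent, op, role, agent_other_b)
            ch <- as.integer(stats::runif(1) < p)
            oc <- other_choice_for(op)
            fb <- as.integer(ch == oc)
            add_row(3L, role, op, ch, oc, fb)
            other_tracker <- grid_update(other_tracker, op, oc, cfg$assumed_T)
            observe_other(op, oc)
          }
        }
      }
    }
  }

  trials <- do.call(rbind, rows)
  truth <- c(list(model = agent$model), agent$spec,
             list(k_b = k_b, k_o = k_o,
                  other_direction = if (abs(k_o - cfg$pop_mean_k) <
                                        abs(k_b - cfg$pop_mean_k))
                    "toward" else "away",
                  other_patient = k_o < k_b))
  structure(list(id = id, trials = trials, truth = truth),
            class = "participant_dataset")
}

#' @export
print.participant_dataset <- function(x, ...) {
  cat(sprintf("<participant %s: %d trials (phase 1: %d, 2: %d, 3: %d)>\n",
              x$id, nrow(x$trials), sum(x$trials$phase == 1),
              sum(x$trials$phase == 2), sum(x$trials$phase == 3)))
  invisible(x)
}

#' Population specification for synthetic cohorts
#'
#' Defaults describe a community cohort: `m ~ N(-4.5, 2.3^2)` (log discount
#' rate), taste-uncertainty variance `u` log-normal with median 1,
#' reference dispersion `sigma_r` log-normal with median near 1.1, relaxation
#' `tau_o` log-normal with median 1.5, lapse `xi ~ Beta(1, 60)` (median about
#' 0.01; drawn for `ps` cohorts only -- the bare `ku`/`kt` models carry no
#' lapse process), and ages uniform over 14-24. `m` and `u` are drawn
#' independently (uncorrelated).
#'
#' @param model agent model for the cohort (`"ku"`, `"ps"` or `"kt"`).
#' @param m_mean,m_sd Gaussian for `m` (or `k` for kt agents).
#' @param ln_u_mean,ln_u_sd Gaussian for `ln u` (or `ln temp` for kt agents).
#' @param ln_sigma_r_mean,ln_sigma_r_sd Gaussian for `ln sigma_r` (ps only).
#' @param ln_tau_o_mean,ln_tau_o_sd Gaussian for `ln tau_o` (ps only).
#' @param xi_shape1,xi_shape2 Beta for the lapse rate.
#' @param age_range sampling range for participant age.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(model = c("ku", "ps", "kt"),
                            m_mean = -4.5, m_sd = 2.3,
                            ln_u_mean = 0, ln_u_sd = 1,
                            ln_sigma_r_mean = log(1.1), ln_sigma_r_sd = 0.4,
                            ln_tau_o_mean = log(1.5), ln_tau_o_sd = 0.3,
                            xi_shape1 = 1, xi_shape2 = 60,
                            age_range = c(14, 24)) {
  model <- match.arg(model)
  structure(as.list(environment()), class = "population_spec")
}

draw_agent <- function(spec) {
  m <- stats::rnorm(1, spec$m_mean, spec$m_sd)
  u <- exp(stats::rnorm(1, spec$ln_u_mean, spec$ln_u_sd))
  # the lapse process belongs to the preference-shift observation model;
  # bare ku/kt cohorts are lapse-free
  xi <- if (spec$model == "ps")
    stats::rbeta(1, spec$xi_shape1, spec$xi_shape2) else 0
  switch(spec$model,
    ku = did_agent("ku", m = m, u = u, xi = xi),
    kt = did_agent("kt", k = m, temp = u, xi = xi),
    ps = did_agent("ps", m_s = m, u_s = u,
                   sigma_r = exp(stats::rnorm(1, spec$ln_sigma_r_mean,
                                              spec$ln_sigma_r_sd)),
                   tau_o = exp(stats::rnorm(1, spec$ln_tau_o_mean,
                                            spec$ln_tau_o_sd)),
                   xi = xi))
}

#' Simulate a synthetic cohort through the task
#'
#' Draws per-agent parameters from the population spec and runs each agent
#' through [simulate_participant()]. Fully reproducible from `seed`.
#'
#' @param N number of participants (> 0).
#' @param spec a [population_spec()].
#' @param cfg a [task_config()].
#' @param seed integer seed governing all randomness.
#' @param phases phases to run (see [simulate_participant()]).
#' @return A list of class `did_population` of `participant_dataset`s.
#' @export
simulate_population <- function(N, spec = population_spec(),
                                cfg = task_config(), seed = 1,
                                phases = 1:3) {
  stopifnot(N > 0)
  set.seed(seed)
  ages <- round(stats::runif(N, spec$age_range[1], spec$age_range[2]))
  genders <- sample(c("F", "M"), N, replace = TRUE)
  out <- vector("list", N)
  for (i in seq_len(N)) {
    agent <- draw_agent(spec)
    d <- simulate_participant(agent, cfg, id = sprintf("p%04d", i),
                              phases = phases)
    d$truth$age <- ages[i]
    d$truth$gender <- genders[i]
    out[[i]] <- d
  }
  structure(out, class = "did_population", seed = seed)
}

#' Ground-truth parameter table of a synthetic cohort
#'
#' @param pop a `did_population` from [simulate_population()].
#' @return A data.frame with one row per participant: generating parameters,
#'   the in-task estimate `k_b`, the Other's `k_o`, and demographics.
#' @export
truth_table <- function(pop) {
  do.call(rbind, lapply(pop, function(d) {
    tr <- d$truth
    data.frame(participant_id = d$id, model = tr$model,
               m = if (!is.null(tr$m)) tr$m else
                   if (!is.null(tr$m_s)) tr$m_s else tr$k,
               u = if (!is.null(tr$u)) tr$u else
                   if (!is.null(tr$u_s)) tr$u_s else NA_real_,
               sigma_r = if (!is.null(tr$sigma_r)) tr$sigma_r else NA_real_,
               tau_o = if (!is.null(tr$tau_o)) tr$tau_o else NA_real_,
               xi = if (!is.null(tr$xi)) tr$xi else 0,
               k_b = tr$k_b, k_o = tr$k_o,
               other_patient = tr$other_patient,
               age = if (!is.null(tr$age)) tr$age else NA_real_,
               gender = if (!is.null(tr$gender)) tr$gender else NA_character_,
               stringsAsFactors = FALSE)
  }))
}
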