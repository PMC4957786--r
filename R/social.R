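#' Gaussian belief over a log discount rate
#'
#' Beliefs are stored as (mean, precision) so that the flat belief is the
#' well-behaved `precision = 0` state rather than an infinite variance.
#'
#' @param mean location of the belief over `k = ln K`.
#' @param var variance (>= 0; `Inf` for the flat belief).
#' @return An object of class `gaussian_belief` with fields `mean` and `prec`.
#' @export
gaussian_belief <- function(mean, var) {
  if (var < 0) stop("variance must be >= 0")
  structure(list(mean = as.numeric(mean), prec = 1 / as.numeric(var)),
            class = "gaussian_belief")
}

#' @rdname gaussian_belief
#' @export
flat_belief <- function() {
  structure(list(mean = 0, prec = 0), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  if (x$prec == 0) cat("<flat belief over k>\n")
  else cat(sprintf("<belief over k: mean %.4g, var %.4g>\n", x$mean, 1 / x$prec))
  invisible(x)
}

belief_var <- function(b) 1 / b$prec

# Effective precision with which the other-belief bears on the self (and vice
# versa): the two are siblings drawn from a latent reference mean k_r with
# per-draw variance sigma_r^2 (k_r integrated out under a flat prior), so the
# coupling channel has variance 2*sigma_r^2 + var(other).
coupling_precision <- function(b, sigma_r) {
  if (b$prec == 0) return(0)
  1 / (2 * sigma_r^2 + 1 / b$prec)
}

combine_precisions <- function(m1, w1, m2, w2) {
  w <- w1 + w2
  if (w == 0) stop("posterior improper: both belief components are flat")
  if (is.infinite(w1)) return(list(mean = m1, prec = Inf))
  if (is.infinite(w2)) return(list(mean = m2, prec = Inf))
  list(mean = (w1 * m1 + w2 * m2) / w, prec = w)
}

#' Posterior belief about one's own taste given data about the Other
#'
#' Precision-weighted product of the self-likelihood `N(k; m_s, u_s)` and the
#' Other's evidence seen through the reference population,
#' `N(k; k_o_hat, 2*sigma_r^2 + var_o)`. The posterior mean always lies
#' between the self mean and the Other's mean (no overtaking), and the
#' posterior variance never exceeds the self variance.
#'
#' @param self_b self belief ([gaussian_belief()]).
#' @param other_b belief about the Other ([gaussian_belief()]; may be flat).
#' @param sigma_r reference-population SD (> 0; `Inf` renders the Other
#'   irrelevant and returns `self_b` unchanged).
#' @return A `gaussian_belief`.
#' @export
posterior_self <- function(self_b, other_b, sigma_r) {
  if (sigma_r <= 0) stop("sigma_r must be > 0")
  w_o <- coupling_precision(other_b, sigma_r)
  out <- combine_precisions(self_b$mean, self_b$prec, other_b$mean, w_o)
  structure(out, class = "gaussian_belief")
}

#' Posterior belief about the Other's taste
#'
#' Mirror image of [posterior_self()]: the Other's own evidence combined with
#' the self-likelihood widened by `2*sigma_r^2`. With no data about the Other
#' yet, this is the self belief widened by `2*sigma_r^2`.
#'
#' @inheritParams posterior_self
#' @return A `gaussian_belief`.
#' @export
posterior_other <- function(self_b, other_b, sigma_r) {
  if (sigma_r <= 0) stop("sigma_r must be > 0")
  w_s <- coupling_precision(self_b, sigma_r)
  out <- combine_precisions(other_b$mean, other_b$prec, self_b$mean, w_s)
  structure(out, class = "gaussian_belief")
}

#' Grid over plausible log discount rates
#'
#' @param lo,hi grid end points on the `k = ln K` scale.
#' @param n number of nodes.
#' @return Numeric vector of grid nodes.
#' @export
k_grid <- function(lo = -12, hi = 2, n = 601) {
  if (n < 2 || hi <= lo) stop("degenerate grid")
  seq(lo, hi, length.out = n)
}

# Log-likelihood of one observed choice on each grid node, under the softmax
# policy at the observer's assumed temperature for the Other.
grid_choice_loglik <- function(op_row, choice, grid, assumed_T = 1) {
  p <- kt_policy(op_row, grid, assumed_T)
  p <- pmin(pmax(p, PI_CLIP), 1 - PI_CLIP)
  if (choice == 1) log(p) else log1p(-p)
}

moment_match_grid <- function(grid, logw) {
  w <- exp(logw - max(logw))
  s <- sum(w)
  if (!is.finite(s) || s <= 0) stop("degenerate grid posterior")
  w <- w / s
  m <- sum(w * grid)
  v <- sum(w * (grid - m)^2)
  gaussian_belief(m, v)
}

#' Gaussianised likelihood of the Other's observed choices
#'
#' Evaluates the product of softmax (`T = assumed_T`) likelihood terms for the
#' Other's choices on a `k` grid, normalises, and moment-matches a Gaussian.
#' This is the `(k_o_hat, var_o)` likelihood summary that enters the
#' preference-shift posteriors. With zero observations the flat belief is
#' returned.
#'
#' @param op option-pair table of the Other's observed trials (possibly 0 rows).
#' @param choices the Other's choices (1 = delayed).
#' @param assumed_T softmax temperature the observer attributes to the Other
#'   (default 1, the Other's true generative temperature in the task).
#' @param grid `k` grid from [k_grid()].
#' @return A `gaussian_belief`.
#' @export
other_likelihood_filter <- function(op, choices, assumed_T = 1,
                                    grid = k_grid()) {
  if (length(grid) < 2) stop("degenerate grid")
  n <- if (is.null(op)) 0L else nrow(op)
  if (n == 0L) return(flat_belief())
  if (length(choices) != n) stop("choices must match option rows")
  logw <- rep(0, length(grid))
  for (i in seq_len(n))
    logw <- logw + grid_choice_loglik(op[i, , drop = FALSE], choices[i],
                                      grid, assumed_T)
  moment_match_grid(grid, logw)
}

# Per-trial filtered other-beliefs for a participant's trial table: trial t
# uses the Gaussianised likelihood of the Other's choices on trials 1..t-1.
# The filter depends only on the observed data (softmax at assumed_T), not on
# the PS parameters, so it is computed once per dataset and reused across
# likelihood evaluations.
other_filter_path <- function(trials, assumed_T = 1, grid = k_grid()) {
  is_other <- trials$role == "other"
  if (any(is_other & is.na(trials$other_choice)))
    stop("other-role trials must record the Other's revealed choice")
  n_other <- sum(is_other)
  means <- numeric(n_other + 1)
  precs <- numeric(n_other + 1)  # state 1 = flat (no data)
  logw <- rep(0, length(grid))
  oi <- which(is_other)
  for (j in seq_len(n_other)) {
    i <- oi[j]
    logw <- logw + grid_choice_loglik(trials[i, c("R0", "RD", "D")],
                                      trials$other_choice[i], grid, assumed_T)
    b <- moment_match_grid(grid, logw)
    means[j + 1] <- b$mean
    precs[j + 1] <- b$prec
  }
  # number of other-choices observed before each trial
  seen <- cumsum(is_other) - is_other
  list(mean = means[seen + 1], prec = precs[seen + 1])
}

#' Preference-shift parameter set
#'
#' The five parameters of the uncertainty-relevance model.
#'
#' @param m_s mode of the self-likelihood over `k`.
#' @param u_s variance of the self-likelihood (>= 0).
#' @param sigma_r reference-population SD (> 0); smaller values make the
#'   Other more relevant and the shift larger.
#' @param tau_o relaxation temperature for unincentivised choices made on
#'   behalf of the Other (> 0).
#' @param xi lapse rate for self-choices, in `[0, 1]`.
#' @return A named list of class `ps_params`.
#' @export
ps_params <- function(m_s, u_s, sigma_r, tau_o, xi) {
  if (u_s < 0) stop("u_s must be >= 0")
  if (sigma_r <= 0) stop("sigma_r must be > 0")
  if (tau_o <= 0) stop("tau_o must be > 0")
  if (xi < 0 || xi > 1) stop("xi must be in [0, 1]")
  structure(list(m_s = m_s, u_s = u_s, sigma_r = sigma_r,
                 tau_o = tau_o, xi = xi), class = "ps_params")
}

#' Per-trial choice probability under the preference-shift model
#'
#' Self trials use the posterior self-belief given the filtered other-belief,
#' a random-preference (KU) read-out, and the lapse mix. Other trials use the
#' posterior other-belief, a KU read-out, and the temperature relaxation.
#'
#' @param op one-row option-pair table.
#' @param role `"self"` or `"other"`.
#' @param params a [ps_params()] object.
#' @param other_b filtered belief about the Other before this trial.
#' @return Probability of choosing the delayed option.
#' @export
ps_trial_policy <- function(op, role, params, other_b = flat_belief()) {
  self_b <- gaussian_belief(params$m_s, params$u_s)
  if (identical(role, "self")) {
    post <- posterior_self(self_b, other_b, params$sigma_r)
    apply_lapse(ku_policy(op, post$mean, belief_var(post)), params$xi)
  } else if (identical(role, "other")) {
    post <- posterior_other(self_b, other_b, params$sigma_r)
    relax_policy(ku_policy(op, post$mean, belief_var(post)), params$tau_o)
  } else stop("role must be 'self' or 'other'")
}

# Vectorised per-trial policies for a whole trial table, given the
# precomputed filter path. Precision arithmetic mirrors posterior_self/other.
ps_policy_vec <- function(params, trials, filt) {
  theta <- log((trials$RD / trials$R0 - 1) / trials$D)
  w_prior <- 1 / params$u_s                               # self precision
  w_o <- ifelse(filt$prec == 0, 0,
                1 / (2 * params$sigma_r^2 + 1 / filt$prec))
  is_self <- trials$role == "self"
  p <- numeric(nrow(trials))

  # self: product of N(m_s, u_s) and N(ohat, 2 sigma_r^2 + var_o)
  wp <- w_prior + w_o
  if (is.infinite(w_prior)) {
    ms <- rep(params$m_s, nrow(trials)); vs <- rep(0, nrow(trials))
  } else {
    ms <- (w_prior * params$m_s + w_o * filt$mean) / wp
    vs <- 1 / wp
  }
  # other: product of N(ohat, var_o) and N(m_s, 2 sigma_r^2 + u_s)
  w_s <- 1 / (2 * params$sigma_r^2 + params$u_s)
  wo <- filt$prec + w_s
  mo <- (filt$prec * filt$mean + w_s * params$m_s) / wo
  vo <- 1 / wo

  cdf <- function(th, m, v) {
    out <- ifelse(v > 0, stats::pnorm((th - m) / sqrt(pmax(v, 1e-300))),
                  0.5 + 0.5 * sign(th - m))
    out
  }
  p[is_self] <- apply_lapse(cdf(theta[is_self], ms[is_self], vs[is_self]),
                            params$xi)
  p[!is_self] <- relax_policy(cdf(theta[!is_self], mo[!is_self], vo[!is_self]),
                              params$tau_o)
  p
}

#' Whole-dataset log-likelihood of the preference-shift model
#'
#' Sums Bernoulli log-likelihoods of the participant's own choices over all
#' phases, with the other-belief refiltered from the Other's revealed choices
#' up to each trial. With only phase-1 trials and `xi = 0` this reduces to the
#' KU log-likelihood at `(m_s, u_s)`.
#'
#' @param params a [ps_params()] object.
#' @param trials a participant trial table (see [simulate_participant()]).
#' @param filt optional precomputed filter path (internal speed-up).
#' @param assumed_T temperature attributed to the Other in the filter.
#' @return Scalar log-likelihood.
#' @export
ps_loglik <- function(params, trials, filt = NULL, assumed_T = 1) {
  if (nrow(trials) == 0L) stop("empty trial list")
  if (any(trials$phase == 2 & is.na(trials$other_choice)))
    stop("phase-2 trials lack feedback about the Other's choice")
  if (is.null(filt)) filt <- other_filter_path(trials, assumed_T)
  p <- ps_policy_vec(params, trials, filt)
  choice_loglik(p, trials$choice)
}
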