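# Model registry ------------------------------------------------------------
#
# Each model is fitted on an unconstrained transformed scale:
#   m-type location parameters: identity
#   variances / temperatures (u, T, sigma_r, tau_o): log
#   lapse rate xi: logit
# Flat priors are flat on this transformed scale.

TRANSFORM_BOUND <- 12  # search box on the transformed scale

get_trials <- function(data) {
  if (inherits(data, "participant_dataset")) data$trials else data
}

model_def <- function(model) {
  switch(model,
    kt = list(
      params = c("k", "ln_T"),
      natural = function(th) c(k = th[[1]], temp = exp(th[[2]])),
      n_params = 2L,
      subset = function(tr) tr[tr$phase == 1 & tr$role == "self", ],
      loglik = function(th, sub, aux) {
        p <- kt_policy(sub, th[[1]], exp(th[[2]]))
        choice_loglik(p, sub$choice)
      },
      starts = function(sub) {
        m0 <- stats::median(indifference_k(sub))
        as.matrix(expand.grid(k = m0 + c(-2, 0, 2), ln_T = c(-1, 0.5)))
      }),
    ku = list(
      params = c("m", "ln_u"),
      natural = function(th) c(m = th[[1]], u = exp(th[[2]])),
      n_params = 2L,
      subset = function(tr) tr[tr$phase == 1 & tr$role == "self", ],
      loglik = function(th, sub, aux) {
        p <- ku_policy(sub, th[[1]], exp(th[[2]]))
        choice_loglik(p, sub$choice)
      },
      starts = function(sub) {
        m0 <- stats::median(indifference_k(sub))
        as.matrix(expand.grid(m = m0 + c(-2, 0, 2), ln_u = c(-1, 1)))
      }),
    ku_static = list(
      params = c("m", "ln_u"),
      natural = function(th) c(m = th[[1]], u = exp(th[[2]])),
      n_params = 2L,
      subset = function(tr) {
        if (!any(tr$phase == 1) || !any(tr$phase == 3))
          stop("static comparator needs self trials in phases 1 and 3")
        tr[tr$role == "self" & tr$phase %in% c(1, 3), ]
      },
      loglik = function(th, sub, aux) {
        p <- ku_policy(sub, th[[1]], exp(th[[2]]))
        choice_loglik(p, sub$choice)
      },
      starts = function(sub) {
        m0 <- stats::median(indifference_k(sub))
        as.matrix(expand.grid(m = m0 + c(-2, 0, 2), ln_u = c(-1, 1)))
      }),
    perturb = list(
      params = c("m1", "m3", "ln_u"),
      natural = function(th) c(m1 = th[[1]], m3 = th[[2]], u = exp(th[[3]])),
      n_params = 3L,
      subset = function(tr) {
        if (!any(tr$phase == 1) || !any(tr$phase == 3))
          stop("perturbation model needs self trials in phases 1 and 3")
        tr[tr$role == "self" & tr$phase %in% c(1, 3), ]
      },
      loglik = function(th, sub, aux) {
        m <- ifelse(sub$phase == 1, th[[1]], th[[2]])
        p <- ku_policy(sub, m, exp(th[[3]]))
        choice_loglik(p, sub$choice)
      },
      starts = function(sub) {
        m0 <- stats::median(indifference_k(sub))
        as.matrix(expand.grid(m1 = m0 + c(-2, 0, 2), m3 = m0,
                              ln_u = c(-1, 1)))
      }),
    ps = list(
      params = c("m_s", "ln_u_s", "ln_sigma_r", "ln_tau_o", "logit_xi"),
      natural = function(th) c(m_s = th[[1]], u_s = exp(th[[2]]),
                               sigma_r = exp(th[[3]]), tau_o = exp(th[[4]]),
                               xi = stats::plogis(th[[5]])),
      n_params = 5L,
      subset = function(tr) tr,
      loglik = function(th, sub, aux) {
        pars <- ps_params(th[[1]], exp(th[[2]]), exp(th[[3]]), exp(th[[4]]),
                          stats::plogis(th[[5]]))
        ps_loglik(pars, sub, filt = aux)
      },
      starts = function(sub) {
        p1 <- sub[sub$phase == 1, ]
        m0 <- stats::median(indifference_k(if (nrow(p1)) p1 else sub))
        as.matrix(expand.grid(m_s = m0 + c(-2, 0, 2), ln_u_s = c(-1, 1),
                              ln_sigma_r = 0.2, ln_tau_o = 0.3,
                              logit_xi = -3.5))
      }),
    stop("unknown model: ", model))
}

model_aux <- function(model, sub) {
  if (model == "ps") other_filter_path(sub) else NULL
}

#' Default weakly informative priors on the transformed scale
#'
#' Gaussian priors wide enough to be dominated by 60+ trials of data:
#' location parameters centred on the expected population mean of
#' `ln K` (-4.5) with SD 5; log-variance/temperature parameters centred on 0
#' with SD 3; the logit lapse centred on -3.5 (about 0.03) with SD 2.
#'
#' @param model one of `"kt"`, `"ku"`, `"perturb"`, `"ps"`.
#' @return A data.frame with columns `param`, `mean`, `sd`.
#' @export
default_priors <- function(model) {
  def <- model_def(model)
  mean <- ifelse(grepl("^(k$|m)", def$params), -4.5,
                 ifelse(def$params == "logit_xi", -3.5, 0))
  sd <- ifelse(grepl("^(k$|m)", def$params), 5,
               ifelse(def$params == "logit_xi", 2, 3))
  data.frame(param = def$params, mean = mean, sd = sd,
             stringsAsFactors = FALSE)
}

log_prior <- function(th, priors) {
  if (is.null(priors)) return(0)
  sum(stats::dnorm(th, priors$mean, priors$sd, log = TRUE))
}

new_fit <- function(model, estimate, transformed, loglik, n_trials, n_params,
                    method, converged, boundary = FALSE, vcov = NULL,
                    ess = NULL, geweke = NULL, samples = NULL) {
  structure(list(
    model = model, estimate = estimate, transformed = transformed,
    loglik = loglik, n_trials = n_trials, n_params = n_params,
    bic = -2 * loglik + n_params * log(n_trials),
    method = method, converged = converged, boundary = boundary,
    vcov = vcov, ess = ess, geweke = geweke, samples = samples),
    class = "did_fit")
}

#' @export
print.did_fit <- function(x, ...) {
  cat(sprintf("<%s fit (%s): LL %.2f, BIC %.2f over %d trials%s>\n",
              x$model, x$method, x$loglik, x$bic, x$n_trials,
              if (x$converged) "" else ", NOT converged"))
  print(round(x$estimate, 4))
  invisible(x)
}

#' MAP fit with Laplace approximation
#'
#' Multi-start bounded optimisation of the log-posterior (log-likelihood
#' under flat transformed-scale priors when `priors` is `NULL`), followed by
#' a numerical Hessian at the mode (Laplace covariance). Fits hitting the
#' search box or run on degenerate one-sided data are flagged `boundary`.
#'
#' @param model `"kt"`, `"ku"`, `"perturb"` or `"ps"`.
#' @param data a `participant_dataset` or trial table.
#' @param priors optional data.frame (`param`, `mean`, `sd`) of Gaussian
#'   priors on the transformed scale.
#' @return A `did_fit` with natural-scale `estimate`, transformed-scale mode
#'   and Laplace `vcov`, log-likelihood at the mode, and BIC.
#' @export
map_fit <- function(model, data, priors = NULL) {
  def <- model_def(model)
  sub <- def$subset(get_trials(data))
  if (nrow(sub) == 0L) stop("no trials selected for model ", model)
  aux <- model_aux(model, sub)
  neg <- function(th) {
    v <- try(def$loglik(th, sub, aux) + log_prior(th, priors), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) return(1e10)
    -v
  }
  starts <- def$starts(sub)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- try(stats::optim(pmin(pmax(starts[i, ], -TRANSFORM_BOUND + 0.5),
                               TRANSFORM_BOUND - 0.5),
                          neg, method = "L-BFGS-B",
                          lower = rep(-TRANSFORM_BOUND, def$n_params),
                          upper = rep(TRANSFORM_BOUND, def$n_params)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || best$value >= 1e10) {
    est <- def$natural(rep(NA_real_, def$n_params))
    return(new_fit(model, est, rep(NA_real_, def$n_params), -Inf, nrow(sub),
                   def$n_params, "map", converged = FALSE, boundary = TRUE))
  }
  th <- best$par
  names(th) <- def$params
  H <- try(stats::optimHess(th, neg), silent = TRUE)
  vc <- NULL
  hess_ok <- FALSE
  if (!inherits(H, "try-error")) {
    vc <- try(solve(H), silent = TRUE)
    hess_ok <- !inherits(vc, "try-error") && all(is.finite(vc)) &&
      all(diag(vc) > 0)
    if (!hess_ok) vc <- NULL
  }
  at_bound <- any(abs(th) > TRANSFORM_BOUND - 1e-6)
  degenerate <- length(unique(sub$choice)) < 2
  ll <- def$loglik(th, sub, aux)
  new_fit(model, def$natural(th), th, ll, nrow(sub), def$n_params, "map",
          converged = hess_ok && !at_bound && !degenerate,
          boundary = at_bound || degenerate, vcov = vc)
}

# Component-wise adaptive random-walk Metropolis on an arbitrary log-density.
# Proposal scales adapt towards 0.44 acceptance during warm-up, then freeze.
metropolis_cw <- function(lp, init, iter, warmup, thin, bound = Inf) {
  th <- init
  p <- length(th)
  lsc <- rep(log(0.5), p)
  cur <- lp(th)
  keep <- matrix(NA_real_, nrow = floor(iter / thin), ncol = p)
  acc <- rep(0, p)
  kept <- 0L
  for (it in seq_len(warmup + iter)) {
    for (j in seq_len(p)) {
      prop <- th
      prop[j] <- th[j] + exp(lsc[j]) * stats::rnorm(1)
      if (abs(prop[j]) <= bound) {
        cand <- lp(prop)
        a <- cand - cur
        ok <- is.finite(a) && log(stats::runif(1)) < a
      } else ok <- FALSE
      if (ok) { th <- prop; cur <- cand; acc[j] <- acc[j] + 1 }
      if (it <= warmup && it %% 50 == 0) {
        rate <- acc[j] / 50
        lsc[j] <- lsc[j] + (rate - 0.44) / sqrt(it / 50)
        acc[j] <- 0
      }
    }
    if (it > warmup && (it - warmup) %% thin == 0) {
      kept <- kept + 1L
      keep[kept, ] <- th
    }
  }
  keep[seq_len(kept), , drop = FALSE]
}

# Chain diagnostics ----------------------------------------------------------

#' Effective sample size of a chain
#'
#' Geyer initial-positive-sequence estimator: autocovariances are summed in
#' adjacent pairs until a pair sum goes non-positive.
#'
#' @param x numeric chain.
#' @return Estimated number of independent draws (0 for a constant chain).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(0)
  rho <- drop(stats::acf(x, lag.max = min(n - 2, 400), plot = FALSE,
                         demean = TRUE)$acf)
  tau <- 1
  k <- 2
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  n / tau
}

geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
  va <- stats::var(a) / max(ess(a), 1)
  vb <- stats::var(b) / max(ess(b), 1)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Component-wise adaptive Metropolis sampler
#'
#' Random-walk Metropolis updating one parameter at a time on the
#' transformed scale, with per-component proposal scales adapted towards a
#' 0.44 acceptance rate during warm-up and then frozen. Point estimates are
#' posterior medians (medians commute with the monotone transforms). The fit
#' is flagged non-converged if any parameter's effective sample size falls
#' below 100 or a Geweke-style stationarity comparison of the early and late
#' chain fails (|z| > 3).
#'
#' @inheritParams map_fit
#' @param chain list with `iter` (post-warm-up iterations, default 20000),
#'   `warmup` (default 2000), `thin` (default 10), `seed`.
#' @param init optional transformed-scale start (defaults to the MAP mode).
#' @return A `did_fit` with `samples` (thinned, transformed scale), per-
#'   parameter `ess`, Geweke `geweke`, medians as `estimate`.
#' @export
mcmc_fit <- function(model, data, priors = default_priors(model),
                     chain = list(), init = NULL) {
  def <- model_def(model)
  sub <- def$subset(get_trials(data))
  aux <- model_aux(model, sub)
  iter <- chain$iter %||% 20000L
  warmup <- chain$warmup %||% 2000L
  thin <- chain$thin %||% 10L
  if (!is.null(chain$seed)) set.seed(chain$seed)
  lp <- function(th) {
    v <- try(def$loglik(th, sub, aux) + log_prior(th, priors), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) -Inf else v
  }
  if (is.null(init)) {
    m0 <- map_fit(model, sub, priors)
    init <- if (all(is.finite(m0$transformed))) m0$transformed
            else rep(0, def$n_params)
  }
  keep <- metropolis_cw(lp, pmin(pmax(init, -TRANSFORM_BOUND),
                                 TRANSFORM_BOUND),
                        iter = iter, warmup = warmup, thin = thin,
                        bound = TRANSFORM_BOUND)
  colnames(keep) <- def$params
  med <- apply(keep, 2, stats::median)
  ll <- def$loglik(med, sub, aux)
  ess_p <- apply(keep, 2, ess)
  gz <- apply(keep, 2, geweke_z)
  new_fit(model, def$natural(med), med, ll, nrow(sub), def$n_params, "mcmc",
          converged = all(ess_p >= 100) && all(abs(gz) <= 3),
          ess = ess_p, geweke = gz, samples = keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit one model to every participant of a cohort
#'
#' @param pop a `did_population` (or list of `participant_dataset`s).
#' @param model model tag (see [map_fit()]).
#' @param method `"map"` or `"mcmc"`.
#' @param priors optional priors shared by all participants.
#' @param chain MCMC settings (see [mcmc_fit()]).
#' @return A list of `did_fit`s, named by participant id, class `did_fits`.
#' @export
fit_population <- function(pop, model, method = c("map", "mcmc"),
                           priors = NULL, chain = list()) {
  method <- match.arg(method)
  fits <- lapply(pop, function(d) {
    if (method == "map") map_fit(model, d, priors)
    else mcmc_fit(model, d, priors %||% default_priors(model), chain)
  })
  names(fits) <- vapply(pop, function(d) d$id, character(1))
  structure(fits, class = "did_fits", model = model)
}

#' Tabulate fits
#'
#' @param fits a `did_fits` list.
#' @return A data.frame: one row per participant with estimates, LL, BIC,
#'   convergence and boundary flags.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    cbind(data.frame(participant_id = id, model = f$model,
                     loglik = f$loglik, bic = f$bic,
                     n_trials = f$n_trials, converged = f$converged,
                     boundary = f$boundary, stringsAsFactors = FALSE),
          as.data.frame(as.list(f$estimate)))
  }))
}

#' Two-pass empirical-Bayes refit
#'
#' Stage 2 of the fitting scheme: (i) participants whose stage-1 fits did not
#' converge are dropped from prior construction; (ii) a Gaussian is fitted to
#' each parameter over the sample on the transformed scale; (iii) every
#' participant (including the dropped ones) is refitted under these sample
#' priors.
#'
#' @param fits stage-1 `did_fits`.
#' @param pop the cohort the fits came from.
#' @param method refitting method, `"map"` (default) or `"mcmc"`.
#' @param chain MCMC settings when `method = "mcmc"`.
#' @return List with `fits` (stage-3 refits), `priors` (the fitted sample
#'   distributions), and `excluded` (ids dropped at stage i).
#' @export
empirical_bayes_refit <- function(fits, pop, method = c("map", "mcmc"),
                                  chain = list()) {
  method <- match.arg(method)
  model <- attr(fits, "model") %||% fits[[1]]$model
  def <- model_def(model)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (sum(ok) < 10)
    stop("fewer than 10 converged stage-1 fits; cannot build sample priors")
  th <- do.call(rbind, lapply(fits[ok], function(f) f$transformed))
  priors <- data.frame(param = def$params,
                       mean = apply(th, 2, mean),
                       sd = pmax(apply(th, 2, stats::sd), 0.05),
                       stringsAsFactors = FALSE)
  refits <- fit_population(pop, model, method, priors = priors, chain = chain)
  list(fits = refits, priors = priors, excluded = names(fits)[!ok])
}

#' Per-participant model comparison
#'
#' @param fits_a,fits_b `did_fits` for the same participants on the same
#'   trials (checked).
#' @return List: per-participant `delta` table (`dll`, `dbic`; positive
#'   favours model A), `frac_a_better` by log-likelihood with ties counted
#'   half, its binomial `sem`, Wilcoxon signed-rank `p` on the
#'   log-likelihood differences, `total_dbic` (sum of BIC_B - BIC_A, positive
#'   favours A), and the fractions of |dBIC| exceeding the conventional
#'   positive (2) and strong (6) evidence thresholds in each direction.
#' @export
compare_models <- function(fits_a, fits_b) {
  if (!identical(names(fits_a), names(fits_b)))
    stop("participant sets differ between fits")
  nt_a <- vapply(fits_a, `[[`, numeric(1), "n_trials")
  nt_b <- vapply(fits_b, `[[`, numeric(1), "n_trials")
  if (!all(nt_a == nt_b)) stop("models were fitted on different trials")
  dll <- vapply(fits_a, `[[`, numeric(1), "loglik") -
    vapply(fits_b, `[[`, numeric(1), "loglik")
  dbic <- vapply(fits_b, `[[`, numeric(1), "bic") -
    vapply(fits_a, `[[`, numeric(1), "bic")
  n <- length(dll)
  f <- (sum(dll > 0) + 0.5 * sum(dll == 0)) / n
  w <- if (all(dll == 0)) list(p.value = 1)
       else stats::wilcox.test(dll[dll != 0], exact = FALSE)
  list(model_a = attr(fits_a, "model"), model_b = attr(fits_b, "model"),
       delta = data.frame(participant_id = names(fits_a), dll = dll,
                          dbic = dbic, stringsAsFactors = FALSE),
       n = n, frac_a_better = f, sem = sqrt(f * (1 - f) / n),
       wilcoxon_p = w$p.value, total_dbic = sum(dbic),
       frac_a_dbic2 = mean(dbic > 2), frac_a_dbic6 = mean(dbic > 6),
       frac_b_dbic2 = mean(dbic < -2), frac_b_dbic6 = mean(dbic < -6))
}

#' Fit the phase-1/phase-3 perturbation comparator
#'
#' A random-preference model with an arbitrary jump in the taste location
#' between phases: separate `m1` and `m3`, shared `u`, likelihood over self
#' trials only. Used as the agnostic comparator that can absorb any
#' preference shift.
#'
#' @inheritParams map_fit
#' @param method `"map"` or `"mcmc"`.
#' @param chain MCMC settings.
#' @return A `did_fit` with estimates `m1`, `m3`, `u`.
#' @export
fit_perturbation_model <- function(data, priors = NULL,
                                   method = c("map", "mcmc"), chain = list()) {
  method <- match.arg(method)
  if (method == "map") map_fit("perturb", data, priors)
  else mcmc_fit("perturb", data, priors %||% default_priors("perturb"), chain)
}
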