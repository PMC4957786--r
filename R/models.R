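#' Construct a table of intertemporal option pairs
#'
#' An option pair offers an immediate reward `R0` against a larger reward `RD`
#' delivered after a delay of `D` days. The log discount rate at which a
#' hyperbolic discounter is exactly indifferent between the two options is
#' `ln[(RD/R0 - 1)/D]`, which requires `RD > R0`.
#'
#' @param R0 numeric vector of immediate reward amounts (> 0).
#' @param RD numeric vector of delayed reward amounts (> `R0`).
#' @param D numeric vector of delays in days (> 0).
#' @return A `data.frame` with columns `R0`, `RD`, `D`.
#' @examples
#' op <- option_pairs(1, 3, 10)
#' indifference_k(op)  # log(0.2)
#' @export
option_pairs <- function(R0, RD, D) {
  n <- max(length(R0), length(RD), length(D))
  op <- data.frame(R0 = rep_len(as.numeric(R0), n),
                   RD = rep_len(as.numeric(RD), n),
                   D = rep_len(as.numeric(D), n))
  validate_option_pairs(op)
  op
}

validate_option_pairs <- function(op) {
  stopifnot(is.data.frame(op), all(c("R0", "RD", "D") %in% names(op)))
  if (any(!is.finite(op$R0)) || any(op$R0 <= 0))
    stop("R0 must be finite and > 0")
  if (any(!is.finite(op$D)) || any(op$D <= 0))
    stop("D must be finite and > 0")
  if (any(op$RD <= op$R0))
    stop("RD must exceed R0 (indifference threshold otherwise undefined)")
  invisible(op)
}

#' Indifference log discount rate of option pairs
#'
#' @param op option-pair table from [option_pairs()].
#' @return Numeric vector `ln[(RD/R0 - 1)/D]`: a hyperbolic discounter with
#'   `k = ln K` below this value prefers to wait.
#' @export
indifference_k <- function(op) {
  log((op$RD / op$R0 - 1) / op$D)
}

#' Hyperbolically discounted value of a delayed reward
#'
#' `V = RD / (1 + K * D)`.
#'
#' @param RD reward amount.
#' @param D delay in days (>= 0).
#' @param K discount rate on the natural scale (>= 0).
#' @return Discounted value, same length as the longest argument.
#' @export
discounted_value <- function(RD, D, K) {
  if (any(D < 0)) stop("negative delay")
  if (any(K < 0)) stop("negative discount rate")
  RD / (1 + K * D)
}

#' Softmax (KT) choice policy
#'
#' Hyperbolic valuation followed by a softmax over the immediate value
#' `Q0 = R0` and the discounted delayed value `QD = RD/(1+K*D)`:
#' `pi_D = 1 / (1 + exp((Q0 - QD)/T))`. Decision noise is independent of the
#' taste parameter ("trembling hand").
#'
#' @param op option-pair table.
#' @param k log discount rate `ln K` (scalar or one per row).
#' @param temp softmax temperature `T` (> 0), in the units of the rewards.
#' @return Probability of choosing the delayed option, per row.
#' @export
kt_policy <- function(op, k, temp) {
  if (any(temp <= 0)) stop("softmax temperature must be > 0")
  QD <- discounted_value(op$RD, op$D, exp(k))
  stats::plogis((QD - op$R0) / temp)
}

#' Random-preference (KU) choice policy
#'
#' The agent holds a Gaussian belief `k ~ N(m, u)` (with `u` a variance) over
#' its log discount rate, samples one `k` per trial and waits deterministically
#' whenever `k < ln[(RD/R0 - 1)/D]`. The choice probability is therefore the
#' normal CDF of the indifference point: `pi_D = Phi((theta - m)/sqrt(u))`.
#' At `u = 0` the policy is the step function (0.5 exactly at indifference).
#'
#' @param op option-pair table (requires `RD > R0`).
#' @param m mean of the belief over `k`.
#' @param u variance of the belief over `k` (>= 0).
#' @return Probability of choosing the delayed option, per row.
#' @export
ku_policy <- function(op, m, u) {
  if (any(u < 0)) stop("taste-uncertainty variance u must be >= 0")
  theta <- indifference_k(op)
  n <- length(theta)
  m <- rep_len(m, n)
  u <- rep_len(u, n)
  p <- numeric(n)
  pos <- u > 0
  p[pos] <- stats::pnorm((theta[pos] - m[pos]) / sqrt(u[pos]))
  if (any(!pos)) {
    d <- sign(theta[!pos] - m[!pos])
    p[!pos] <- 0.5 + 0.5 * d
  }
  p
}

#' Temperature relaxation of a choice probability
#'
#' Choices made on behalf of another person are unincentivised; the policy is
#' relaxed towards 0.5 by a power transform with exponent `1/tau_o`:
#' `p^(1/tau) / (p^(1/tau) + (1-p)^(1/tau))`. `tau_o = 1` is the identity;
#' `tau_o -> Inf` maps every interior probability to 0.5.
#'
#' @param p probability in `[0, 1]`.
#' @param tau_o relaxation temperature (> 0).
#' @return Relaxed probability.
#' @export
relax_policy <- function(p, tau_o) {
  if (any(tau_o <= 0)) stop("tau_o must be > 0")
  if (any(p < 0 | p > 1)) stop("probability outside [0, 1]")
  # log-space for numerical stability at extreme p / small tau_o
  a <- log(p) / tau_o
  b <- log1p(-p) / tau_o
  out <- 1 / (1 + exp(b - a))
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

#' Mix a lapse process into a choice probability
#'
#' With probability `xi` the response is taste-independent and uniform over
#' the two options: `p' = p * (1 - xi) + xi/2`.
#'
#' @param p probability in `[0, 1]`.
#' @param xi lapse rate in `[0, 1]`.
#' @return Lapse-mixed probability, in `[xi/2, 1 - xi/2]`.
#' @export
apply_lapse <- function(p, xi) {
  if (any(xi < 0 | xi > 1)) stop("lapse rate xi must be in [0, 1]")
  p * (1 - xi) + xi / 2
}

# Probabilities are clipped to [PI_CLIP, 1 - PI_CLIP] inside log-likelihoods
# so that a deterministic policy never yields -Inf.
PI_CLIP <- 1e-12

#' Bernoulli log-likelihood of a choice sequence
#'
#' @param p per-trial probability of choosing the delayed option.
#' @param choice per-trial choices, coded 1 = delayed, 0 = immediate.
#' @return Sum of `log(p)` over delayed choices and `log(1-p)` over immediate
#'   ones, with `p` clipped to `[1e-12, 1 - 1e-12]`.
#' @export
choice_loglik <- function(p, choice) {
  if (length(p) == 0L) stop("empty trial list")
  if (length(p) != length(choice)) stop("p and choice lengths differ")
  if (!all(choice %in% c(0, 1))) stop("choices must be coded 0/1")
  p <- pmin(pmax(p, PI_CLIP), 1 - PI_CLIP)
  sum(log(ifelse(choice == 1, p, 1 - p)))
}
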