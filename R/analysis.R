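# Population-level statistics: correlations, partial correlations, the shift
# regression, group contrasts, mediation by partial correlation, and the
# headline report.

residualise <- function(y, controls) {
  if (is.null(controls) || length(controls) == 0) return(y)
  X <- as.matrix(as.data.frame(controls))
  stats::residuals(stats::lm.fit(cbind(1, X), y))
}

#' Pearson and partial correlation
#'
#' With controls, both variables are residualised on the controls by ordinary
#' least squares and the Pearson correlation of the residuals is reported,
#' with degrees of freedom reduced by the number of controls.
#'
#' @param table a data.frame.
#' @param x,y column names.
#' @param controls optional character vector of control column names.
#' @return List: `r`, `p`, `n`, `df`, `controls`.
#' @export
association_stats <- function(table, x, y, controls = NULL) {
  cols <- c(x, y, controls)
  d <- table[stats::complete.cases(table[, cols, drop = FALSE]), cols,
             drop = FALSE]
  n <- nrow(d)
  if (n < 3) stop("need at least 3 complete rows")
  if (any(vapply(d, stats::sd, numeric(1)) == 0))
    stop("zero variance in ", paste(cols[vapply(d, stats::sd, numeric(1)) == 0],
                                    collapse = ", "))
  rx <- residualise(d[[x]], d[controls])
  ry <- residualise(d[[y]], d[controls])
  if (stats::sd(rx) < 1e-10 * stats::sd(d[[x]]) ||
      stats::sd(ry) < 1e-10 * stats::sd(d[[y]]))
    stop("zero residual variance after controlling (degenerate control)")
  r <- stats::cor(rx, ry)
  df <- n - 2 - length(controls)
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df,
       controls = controls)
}

#' Shift regression with uncertainty-relevance interaction
#'
#' OLS of the signed preference shift on taste uncertainty `u`, reference
#' dispersion `sigma_r`, and their interaction:
#' `shift = b0 + b1 u + b2 sigma_r + b3 u:sigma_r`.
#'
#' @param table data.frame with columns `shift`, `u`, `sigma_r` (override via
#'   arguments).
#' @param shift,u,sigma_r column names.
#' @return The fitted `lm` object.
#' @export
shift_regression <- function(table, shift = "shift", u = "u",
                             sigma_r = "sigma_r") {
  if (nrow(table) < 5) stop("need at least 5 rows")
  d <- data.frame(shift = table[[shift]], u = table[[u]],
                  sigma_r = table[[sigma_r]])
  stats::lm(shift ~ u * sigma_r, data = d)
}

#' Two-group contrast by rank-sum test
#'
#' @param table data.frame.
#' @param group_col name of a two-level grouping column.
#' @param value_col name of the value column.
#' @return List: group `means`, Wilcoxon rank-sum `p`, and standardised
#'   `effect_size` (difference of means over the pooled SD).
#' @export
group_difference <- function(table, group_col, value_col) {
  g <- factor(table[[group_col]])
  if (nlevels(g) != 2) stop("group column must have exactly two levels")
  v <- table[[value_col]]
  a <- v[g == levels(g)[1]]
  b <- v[g == levels(g)[2]]
  if (!length(a) || !length(b)) stop("empty group")
  pooled <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
  list(groups = levels(g), means = c(mean(a), mean(b)),
       p = stats::wilcox.test(a, b, exact = FALSE)$p.value,
       effect_size = if (pooled > 0) (mean(a) - mean(b)) / pooled else 0)
}

#' Mediation assessed through partial correlations
#'
#' Reports the raw correlation `r(x, y)`, the partial `r(x, y; m)` and the
#' partial `r(m, y; x)`. Mediation of the x-y association by m is declared
#' "full" when the raw association is significant, the partial association
#' controlling for the mediator is not, and the mediator retains an
#' association with the outcome controlling for x.
#'
#' @param table data.frame.
#' @param x,m,y column names of predictor, mediator, outcome.
#' @param alpha significance level for the declaration (default 0.05).
#' @return List of the three correlation results and `fully_mediated`.
#' @export
mediation_by_partial <- function(table, x, m, y, alpha = 0.05) {
  raw <- association_stats(table, x, y)
  xy_m <- association_stats(table, x, y, controls = m)
  my_x <- association_stats(table, m, y, controls = x)
  list(raw_xy = raw, partial_xy_given_m = xy_m, partial_my_given_x = my_x,
       fully_mediated = raw$p < alpha && xy_m$p >= alpha && my_x$p < alpha)
}

#' Assemble the per-participant population table
#'
#' Joins fitted parameters across models with ground truth/demographics. The
#' signed shift is `(m3 - m1) * sign(k_o - m1)`: positive when the phase-3
#' taste moved towards the Other.
#'
#' @param truth ground-truth/demographics table ([truth_table()]), needing at
#'   least `participant_id` and `k_o`.
#' @param kt_fits,ku_fits,perturb_fits,ps_fits `did_fits` lists (any may be
#'   `NULL`).
#' @return A data.frame, one row per participant, with columns such as `k_b`,
#'   `temp`, `m1`, `u1`, `m3`, `m_s`, `u_s` (as `u`), `sigma_r`, `tau_o`,
#'   `xi`, `shift`, `abs_shift`, demographics.
#' @export
population_table <- function(truth, kt_fits = NULL, ku_fits = NULL,
                             perturb_fits = NULL, ps_fits = NULL) {
  out <- truth
  names(out)[names(out) == "m"] <- "m_true"
  names(out)[names(out) == "u"] <- "u_true"
  names(out)[names(out) == "sigma_r"] <- "sigma_r_true"
  names(out)[names(out) == "tau_o"] <- "tau_o_true"
  names(out)[names(out) == "xi"] <- "xi_true"
  merge_fit <- function(out, fits, keep, rename) {
    if (is.null(fits)) return(out)
    tb <- fits_table(fits)[, c("participant_id", keep)]
    names(tb) <- c("participant_id", rename)
    merge(out, tb, by = "participant_id", sort = FALSE)
  }
  out <- merge_fit(out, kt_fits, c("k", "temp"), c("k_b_fit", "temp"))
  out <- merge_fit(out, ku_fits, c("m", "u"), c("m1", "u1"))
  out <- merge_fit(out, perturb_fits, c("m1", "m3"), c("m1_perturb", "m3"))
  out <- merge_fit(out, ps_fits, c("m_s", "u_s", "sigma_r", "tau_o", "xi"),
                   c("m_s", "u", "sigma_r", "tau_o", "xi"))
  if (!is.null(out$m3) && !is.null(out$m1) && !is.null(out$k_o)) {
    out$shift <- (out$m3 - out$m1) * sign(out$k_o - out$m1)
    out$abs_shift <- abs(out$m3 - out$m1)
  }
  out
}

#' Headline population report
#'
#' Collects the package's summary quantities from a population table and
#' (optionally) a KU-vs-KT comparison: taste distribution moments, the
#' fitted-KT correlation between `k` and `ln T`, random-preference parameter
#' correlations, shift partial correlations, the perturbation-model BIC
#' tally, and age effects. Every number is a pure function of its inputs.
#'
#' @param table a [population_table()].
#' @param ku_vs_kt optional [compare_models()] result (KU as model A).
#' @param ku_vs_perturb optional [compare_models()] result (KU as model A,
#'   perturbation model as B).
#' @param near_zero_u threshold below which a fitted `u` counts as
#'   effectively deterministic (default 0.01).
#' @return A nested list (JSON-serialisable).
#' @export
results_report <- function(table, ku_vs_kt = NULL, ku_vs_perturb = NULL,
                           near_zero_u = 0.01) {
  rep <- list(n = nrow(table))
  if (!is.null(table$m1))
    rep$taste <- list(mean_m1 = mean(table$m1), sd_m1 = stats::sd(table$m1),
                      near_zero_u_fraction = mean(table$u1 < near_zero_u))
  if (!is.null(table$k_b_fit)) {
    rep$kt <- list(mean_k = mean(table$k_b_fit),
                   sd_k = stats::sd(table$k_b_fit),
                   mean_T = mean(table$temp), sd_T = stats::sd(table$temp))
    tb <- table
    tb$ln_T <- log(tb$temp)
    a <- association_stats(tb, "k_b_fit", "ln_T")
    rep$kt$r_k_lnT <- a$r
    rep$kt$p_k_lnT <- a$p
    if (!is.null(tb$m1)) {
      rep$kt$r_m1_u1 <- association_stats(tb, "m1", "u1")$r
      rep$kt$r_lnT_u1 <- association_stats(tb, "ln_T", "u1")$r
    }
  }
  if (!is.null(ku_vs_kt))
    rep$ku_vs_kt <- ku_vs_kt[c("frac_a_better", "sem", "wilcoxon_p",
                               "total_dbic")]
  if (!is.null(table$shift) && !is.null(table$sigma_r)) {
    rep$shift <- list(
      mean_sigma_r = mean(table$sigma_r),
      partial_r_shift_sigma_r_given_u =
        association_stats(table, "shift", "sigma_r", "u")$r,
      partial_r_shift_u_given_sigma_r =
        association_stats(table, "shift", "u", "sigma_r")$r)
  }
  if (!is.null(ku_vs_perturb))
    rep$perturbation <- list(frac_perturb_dbic2 = ku_vs_perturb$frac_b_dbic2,
                             frac_perturb_dbic6 = ku_vs_perturb$frac_b_dbic6)
  if (!is.null(table$age)) {
    rep$age <- list()
    if (!is.null(table$m1))
      rep$age$r_m1_age <- association_stats(table, "m1", "age")$r
    if (!is.null(table$abs_shift)) {
      a <- association_stats(table, "abs_shift", "age")
      rep$age$r_abs_shift_age <- a$r
      rep$age$p_abs_shift_age <- a$p
    }
  }
  rep
}
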