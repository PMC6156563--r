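## Attribution of 30-year occupancy trends to climate trends.

#' Linear trend in annual climate values
#'
#' OLS slope of annual values against year (SD units per year when fed
#' standardized anomalies).
#'
#' @param values annual values.
#' @param years matching years (default consecutive).
#' @return Slope per year.
#' @export
climateTrend <- function(values, years = seq_along(values)) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("need at least 3 years for a trend")
  unname(coef(lm(values[ok] ~ years[ok]))[2])
}

#' Expected climate-driven occupancy trend
#'
#' Combines sensitivity (change in relative occupancy per SD of climate)
#' with the climate trend (SD per year):
#' \deqn{\frac{d\psi}{dt} = \sum_{X^*}\frac{d\psi}{dX^*}
#'   \frac{dX^*}{dt}}
#' Masked variables (sensitivity `NA`) contribute 0.
#'
#' @param sens named numeric sensitivities per climate variable.
#' @param slopes named numeric climate slopes (SD/yr), same variables.
#' @return Expected relative occupancy change per year.
#' @export
expectedTrend <- function(sens, slopes) {
  sum(decomposeTrend(sens, slopes))
}

#' Per-variable decomposition of the expected trend
#'
#' @inheritParams expectedTrend
#' @return Named vector of per-variable contributions; sums exactly to
#'   [expectedTrend()].
#' @export
decomposeTrend <- function(sens, slopes) {
  vars <- intersect(names(sens), names(slopes))
  if (!length(vars)) {
    vars <- seq_along(sens)
    if (length(sens) != length(slopes))
      stop("sensitivities and slopes must align")
  }
  out <- sens[vars] * slopes[vars]
  out[is.na(out)] <- 0
  out
}

#' Simulate an occupancy trajectory under an annual climate series
#'
#' Deterministic propagation of expected occupancy
#' `psi_(t+1) = psi_t * phi_t + (1 - psi_t) * gamma_t` with year-specific
#' transitions `gamma_t = plogis(alpha + beta.X_t)`,
#' `phi_t = plogis(alpha + delta + beta.X_t)`; the direct-simulation
#' alternative to the chain-rule trend estimate. Starts at the equilibrium
#' of the first year's parameters unless `psi0` is given.
#'
#' @param alpha,delta auto-logistic parameters (logit scale).
#' @param xbeta numeric vector: total climate forcing `beta.X_t` per year.
#' @param psi0 optional starting occupancy.
#' @return list: `psi` (trajectory, length = length(xbeta) + 1), `trend`
#'   (OLS slope of the trajectory per year).
#' @export
simulateTrendTrajectory <- function(alpha, delta, xbeta, psi0 = NULL) {
  tp1 <- transitionProbs(alpha, delta, xbeta[1])
  if (is.null(psi0)) psi0 <- equilibriumOccupancy(tp1$gamma, tp1$phi)
  psi <- numeric(length(xbeta) + 1L)
  psi[1] <- psi0
  for (t in seq_along(xbeta)) {
    tp <- transitionProbs(alpha, delta, xbeta[t])
    psi[t + 1L] <- psi[t] * tp$phi + (1 - psi[t]) * tp$gamma
  }
  list(psi = psi, trend = climateTrend(psi))
}

#' Population-level trend attribution
#'
#' For every species-by-study-area population: the chain-rule expected
#' climate-driven trend, its per-variable decomposition, the
#' direct-simulation trend under the supplied anomaly drift, and summary
#' fractions. Annual percent change is reported as
#' `100 * (dpsi/dt) / psi*`.
#'
#' @param sensResult a [SensitivityResult-class] object.
#' @param slopes named numeric climate slopes (SD/yr) applied to every
#'   population, or a data.frame with columns `study_area`, `variable`,
#'   `slope` for area-specific slopes.
#' @return data.frame per population: `species`, `study_area`, `psi_star`,
#'   `expected_trend` (occupancy/yr), `pct_annual` (% of psi* per yr),
#'   per-variable contribution columns `contrib_<var>`; attribute
#'   `"frac_positive"` holds the fraction of populations with positive
#'   expected trend.
#' @export
attributeTrends <- function(sensResult, slopes) {
  tab <- sensitivityTable(sensResult)
  pops <- unique(tab[, c("species", "study_area")])
  rows <- lapply(seq_len(nrow(pops)), function(i) {
    sub <- tab[tab$species == pops$species[i] &
                 tab$study_area == pops$study_area[i], ]
    sens <- setNames(sub$sens_mean, sub$variable)
    sl <- if (is.data.frame(slopes)) {
      s <- slopes[slopes$study_area == pops$study_area[i], ]
      setNames(s$slope, s$variable)
    } else slopes
    contrib <- decomposeTrend(sens, sl)
    tot <- sum(contrib)
    # chain-rule sensitivity is relative (1/psi* inside), so dpsi/dt in
    # occupancy units multiplies back by psi*
    psi <- sub$psi_star[1]
    out <- data.frame(species = pops$species[i],
                      study_area = pops$study_area[i],
                      psi_star = psi,
                      expected_trend = tot * psi,
                      pct_annual = 100 * tot)
    for (v in names(contrib))
      out[[paste0("contrib_", v)]] <- contrib[[v]] * psi
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "frac_positive") <- mean(out$expected_trend > 0)
  out
}

#' Regression of observed on climate-predicted trends
#'
#' Measurement-error-aware hierarchical regression: observed trend_i ~
#' Normal(a + b * predicted_i, SE_i^2 + sigma^2), sampled by adaptive
#' Metropolis with vague priors (Normal(0, 10^2) on a and b, half-Normal(0,
#' 5) on sigma). Reports the posterior of the slope b and the Pearson
#' correlation of the point estimates.
#'
#' @param observed observed trend point estimates.
#' @param se standard errors of the observed trends (0 allowed).
#' @param predicted climate-predicted trends.
#' @param n_iter,n_burn MCMC lengths.
#' @param seed RNG seed.
#' @return list: `slope` (posterior mean), `slope_ci` (95%), `intercept`,
#'   `r` (correlation of point estimates), `draws` (matrix a, b, sigma).
#' @export
regressObservedOnPredicted <- function(observed, se, predicted,
                                       n_iter = 4000L, n_burn = 1000L,
                                       seed = 1L) {
  n <- length(observed)
  if (n < 3L) stop("need at least 3 populations")
  if (sd(predicted) < 1e-14) stop("degenerate predictor variance")
  se <- rep_len(se, n)
  set.seed(seed + 6L)
  loglik <- function(a, b, sig) {
    sum(dnorm(observed, a + b * predicted, sqrt(se^2 + sig^2), log = TRUE))
  }
  logpost <- function(th) {
    loglik(th[1], th[2], exp(th[3])) +
      dnorm(th[1], 0, 10, log = TRUE) + dnorm(th[2], 0, 10, log = TRUE) +
      dnorm(exp(th[3]), 0, 5, log = TRUE) + th[3]
  }
  ols <- lm(observed ~ predicted)
  init <- coef(ols)
  olsSE <- suppressWarnings(summary(ols)$coefficients[, 2])
  th <- c(init[1], init[2], log(max(sd(observed) / 2, 1e-3)))
  lp <- logpost(th)
  # per-coordinate proposal scales from the OLS fit; the adaptive factor
  # then only tunes the overall magnitude
  step <- c(max(olsSE[1], 1e-8), max(olsSE[2], 1e-8), 0.15)
  draws <- matrix(NA_real_, n_iter, 3L)
  acc <- 0; batch <- 0L
  for (it in seq_len(n_burn + n_iter)) {
    prop <- th + rnorm(3L) * step
    lpNew <- logpost(prop)
    if (log(runif(1)) < lpNew - lp) {
      th <- prop; lp <- lpNew; acc <- acc + 1
    }
    if (it <= n_burn && it %% 50L == 0L) {
      batch <- batch + 1L
      step <- step * exp((acc / 50 - 0.25) / sqrt(batch))
      acc <- 0
    }
    if (it > n_burn) draws[it - n_burn, ] <- c(th[1], th[2], exp(th[3]))
  }
  colnames(draws) <- c("intercept", "slope", "sigma")
  list(slope = mean(draws[, "slope"]),
       slope_ci = unname(quantile(draws[, "slope"], c(0.025, 0.975))),
       intercept = mean(draws[, "intercept"]),
       r = cor(observed, predicted),
       draws = draws)
}
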