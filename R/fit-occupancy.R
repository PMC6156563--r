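## MCMC engine for the hierarchical auto-logistic occupancy model.
## Latent occupancy is marginalized by the forward algorithm (C++ core);
## sampling is adaptive Metropolis-within-Gibbs with conjugate Gibbs steps
## for the random-effect means and a Bayesian-LASSO (Laplace) prior on the
## interaction coefficients.

#' MCMC settings
#'
#' Desk-scale defaults (3 chains, 2,000 kept iterations after 1,000
#' burn-in, no thinning) keep test-suite runtimes manageable;
#' `studyScale = TRUE` selects the study-scale settings (5,000 burn-in,
#' 20,000 iterations saving every 10th, 3 chains).
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter post-burn-in iterations per chain (before thinning).
#' @param n_burn burn-in iterations (adaptation happens here only).
#' @param thin keep every `thin`-th draw.
#' @param studyScale use the study-scale settings above.
#' @return list of settings.
#' @export
mcmcControl <- function(n_chains = 3L, n_iter = 2000L, n_burn = 1000L,
                        thin = 1L, studyScale = FALSE) {
  if (studyScale) {
    n_burn <- 5000L; n_iter <- 20000L; thin <- 10L; n_chains <- 3L
  }
  list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
       n_burn = as.integer(n_burn), thin = as.integer(thin))
}

# Robbins-Monro step-size adaptation toward a target acceptance rate
.adapt <- function(logStep, accRate, target, batch) {
  logStep + (accRate - target) / sqrt(batch)
}

#' Fit the hierarchical dynamic occupancy model
#'
#' Posterior sampling of the auto-logistic occupancy model with imperfect
#' detection: species-by-study-area random intercepts `alpha_jk` and
#' occupied-state effects `delta_jk` with Normal hyper-priors, logit
#' initial-occupancy random effects, detection probability varying by
#' (study area, species, year) with Normal hyper-structure on the logit
#' scale, and climate coefficients `beta`. Main climate effects and
#' random-effect hyper-parameters get vague priors (Normal(0, 10^2) on
#' means and coefficients, half-Normal(0, 5) on SDs); interaction
#' coefficients get a Laplace (double-exponential) LASSO prior whose global
#' scale has a half-Cauchy(0, 1) hyper-prior. The latent occupancy states
#' are marginalized exactly by the forward algorithm, so the sampler moves
#' only in parameter space.
#'
#' @param survey a [SurveyData-class] object.
#' @param design an [OccupancyDesign-class] covering every surveyed
#'   (site, species, year).
#' @param control see [mcmcControl()].
#' @param seed integer; chains use `seed * 1000 + chain`.
#' @param dropNeverDetected exclude species-by-study-area groups with zero
#'   detections in all years (the default, mirroring analyses restricted
#'   to observed program-species combinations).
#' @param interactionPrior `"lasso"` (Laplace, the default) or `"flat"`
#'   (Normal(0, 10^2), for comparison).
#' @return An [OccupancyFit-class]; `converged` is TRUE only if every
#'   monitored split Gelman--Rubin statistic is < 1.05, and a warning is
#'   emitted otherwise (never silent success).
#' @export
fitOccupancy <- function(survey, design, control = mcmcControl(),
                         seed = 1L, dropNeverDetected = TRUE,
                         interactionPrior = c("lasso", "flat")) {
  interactionPrior <- match.arg(interactionPrior)
  obs <- observations(survey)
  years <- sort(unique(obs$year))
  Tn <- length(years)
  ## per (site, species, year) detection summaries
  agg <- aggregate(cbind(ydet = obs$detected,
                         nvis = rep(1L, nrow(obs))),
                   by = list(site = obs$site, species = obs$species,
                             study_area = obs$study_area, year = obs$year),
                   FUN = sum)
  ser <- unique(agg[, c("site", "species", "study_area")])
  ser <- ser[order(ser$site, ser$species), ]
  rownames(ser) <- NULL
  ## groups = species x study area
  grpDet <- aggregate(list(det = agg$ydet),
                      by = list(species = agg$species,
                                study_area = agg$study_area), FUN = sum)
  if (dropNeverDetected) grpDet <- grpDet[grpDet$det > 0, ]
  groups <- grpDet[order(grpDet$species, grpDet$study_area),
                   c("species", "study_area")]
  rownames(groups) <- NULL
  ser <- ser[paste(ser$species, ser$study_area) %in%
               paste(groups$species, groups$study_area), ]
  S <- nrow(ser); G <- nrow(groups)
  if (S == 0L) stop("no series left to fit")
  ydet <- matrix(0L, S, Tn); nvis <- matrix(0L, S, Tn)
  ii <- match(paste(agg$site, agg$species), paste(ser$site, ser$species))
  jj <- match(agg$year, years)
  keep <- !is.na(ii)
  ydet[cbind(ii[keep], jj[keep])] <- agg$ydet[keep]
  nvis[cbind(ii[keep], jj[keep])] <- agg$nvis[keep]
  gidx <- match(paste(ser$species, ser$study_area),
                paste(groups$species, groups$study_area))
  ## design rows in series-major, year-within order
  dkey <- designKey(design)
  drows <- match(paste(rep(ser$site, each = Tn),
                       rep(ser$species, each = Tn),
                       rep(years, times = S)),
                 paste(dkey$site, dkey$species, dkey$year))
  if (anyNA(drows))
    stop("design does not cover all surveyed site-species-years")
  Xd <- designMatrix(design)[drows, , drop = FALSE]
  P <- ncol(Xd)
  shrink <- designTerms(design)$shrink
  useLasso <- interactionPrior == "lasso" && any(shrink)
  betaPriorLL <- function(beta, tau) {
    ll <- sum(dnorm(beta[!shrink], 0, 10, log = TRUE))
    if (any(shrink)) {
      if (useLasso)
        ll <- ll + sum(-log(2 * tau) - abs(beta[shrink]) / tau)
      else ll <- ll + sum(dnorm(beta[shrink], 0, 10, log = TRUE))
    }
    ll
  }
  llFun <- function(alpha, delta, psi1, lp, eta)
    cpp_series_loglik(ydet, nvis, gidx, alpha, delta, psi1, lp, eta)
  groupSum <- function(v) as.vector(rowsum(v, gidx, reorder = TRUE))
  ## naive initial values
  naiveP <- max(min(sum(ydet) / max(sum(nvis[ydet > 0]), 1), 0.9), 0.1)
  ctl <- control
  nKeep <- ctl$n_iter %/% ctl$thin
  parNames <- c(paste0("beta:", colnames(Xd)),
                "mu_alpha", "sigma_alpha", "mu_delta", "sigma_delta",
                "mu_p", "sigma_p", "mu_psi1", "sigma_psi1",
                if (useLasso) "lasso_scale",
                paste0("alpha[", groups$species, ",", groups$study_area, "]"),
                paste0("delta[", groups$species, ",", groups$study_area, "]"),
                paste0("psi1[", groups$species, ",", groups$study_area, "]"))
  chains <- vector("list", ctl$n_chains)
  for (ch in seq_len(ctl$n_chains)) {
    set.seed(seed * 1000L + ch)
    alpha <- rnorm(G, -0.5, 0.4)
    delta <- rnorm(G, 1.5, 0.4)
    psi1 <- rnorm(G, 0, 0.4)
    lp <- matrix(rnorm(G * Tn, qlogis(naiveP), 0.3), G, Tn)
    beta <- rnorm(P, 0, 0.05)
    muA <- -0.5; sgA <- 0.7; muD <- 1.5; sgD <- 0.7
    muP <- qlogis(naiveP); sgP <- 0.7; muQ <- 0; sgQ <- 0.7
    tau <- 0.5
    eta <- matrix(Xd %*% beta, S, Tn, byrow = TRUE)
    llS <- llFun(alpha, delta, psi1, lp, eta)
    stepA <- rep(-1, 1); stepD <- -1; stepQ <- -1; stepP <- -1
    stepB <- log(0.05); stepS <- -1.5
    accA <- accD <- accQ <- accP <- accB <- 0; nB <- 0
    batch <- 0L
    kept <- matrix(NA_real_, nKeep, length(parNames))
    kIdx <- 0L
    total <- ctl$n_burn + ctl$n_iter
    for (it in seq_len(total)) {
      adapting <- it <= ctl$n_burn
      ## --- alpha (parallel per-group random walk)
      prop <- alpha + rnorm(G) * exp(stepA)
      llNew <- llFun(prop, delta, psi1, lp, eta)
      dlp <- groupSum(llNew) - groupSum(llS) +
        dnorm(prop, muA, sgA, log = TRUE) -
        dnorm(alpha, muA, sgA, log = TRUE)
      acc <- log(runif(G)) < dlp
      alpha[acc] <- prop[acc]
      llS[acc[gidx]] <- llNew[acc[gidx]]
      accA <- accA + mean(acc)
      ## --- delta
      prop <- delta + rnorm(G) * exp(stepD)
      llNew <- llFun(alpha, prop, psi1, lp, eta)
      dlp <- groupSum(llNew) - groupSum(llS) +
        dnorm(prop, muD, sgD, log = TRUE) -
        dnorm(delta, muD, sgD, log = TRUE)
      acc <- log(runif(G)) < dlp
      delta[acc] <- prop[acc]
      llS[acc[gidx]] <- llNew[acc[gidx]]
      accD <- accD + mean(acc)
      ## --- psi1
      prop <- psi1 + rnorm(G) * exp(stepQ)
      llNew <- llFun(alpha, delta, prop, lp, eta)
      dlp <- groupSum(llNew) - groupSum(llS) +
        dnorm(prop, muQ, sgQ, log = TRUE) -
        dnorm(psi1, muQ, sgQ, log = TRUE)
      acc <- log(runif(G)) < dlp
      psi1[acc] <- prop[acc]
      llS[acc[gidx]] <- llNew[acc[gidx]]
      accQ <- accQ + mean(acc)
      ## --- detection, one year at a time (groups in parallel)
      for (t in seq_len(Tn)) {
        lpProp <- lp
        lpProp[, t] <- lp[, t] + rnorm(G) * exp(stepP)
        llNew <- llFun(alpha, delta, psi1, lpProp, eta)
        dlp <- groupSum(llNew) - groupSum(llS) +
          dnorm(lpProp[, t], muP, sgP, log = TRUE) -
          dnorm(lp[, t], muP, sgP, log = TRUE)
        acc <- log(runif(G)) < dlp
        lp[acc, t] <- lpProp[acc, t]
        llS[acc[gidx]] <- llNew[acc[gidx]]
        accP <- accP + mean(acc) / Tn
      }
      ## --- beta (joint random walk, two sweeps)
      for (r in 1:2) {
        prop <- beta + rnorm(P) * exp(stepB)
        etaNew <- matrix(Xd %*% prop, S, Tn, byrow = TRUE)
        llNew <- llFun(alpha, delta, psi1, lp, etaNew)
        dlp <- sum(llNew) - sum(llS) +
          betaPriorLL(prop, tau) - betaPriorLL(beta, tau)
        if (log(runif(1)) < dlp) {
          beta <- prop; eta <- etaNew; llS <- llNew
          accB <- accB + 0.5
        }
        nB <- nB + 0.5
      }
      ## --- hyper-parameters
      gibbsMu <- function(x, sg) {
        n <- length(x)
        v <- 1 / (n / sg^2 + 1 / 100)
        rnorm(1, v * sum(x) / sg^2, sqrt(v))
      }
      muA <- gibbsMu(alpha, sgA); muD <- gibbsMu(delta, sgD)
      muQ <- gibbsMu(psi1, sgQ); muP <- gibbsMu(as.vector(lp), sgP)
      mhSigma <- function(x, mu, sg) {
        prop <- sg * exp(rnorm(1, 0, exp(stepS)))
        dlp <- sum(dnorm(x, mu, prop, log = TRUE)) -
          sum(dnorm(x, mu, sg, log = TRUE)) +
          dnorm(prop, 0, 5, log = TRUE) - dnorm(sg, 0, 5, log = TRUE) +
          log(prop) - log(sg)  # log-scale proposal jacobian
        if (log(runif(1)) < dlp) prop else sg
      }
      sgA <- mhSigma(alpha, muA, sgA); sgD <- mhSigma(delta, muD, sgD)
      sgQ <- mhSigma(psi1, muQ, sgQ); sgP <- mhSigma(as.vector(lp), muP, sgP)
      if (useLasso) {
        bl <- abs(beta[shrink]); nl <- length(bl)
        prop <- tau * exp(rnorm(1, 0, 0.4))
        dlp <- (-nl * log(2 * prop) - sum(bl) / prop) -
          (-nl * log(2 * tau) - sum(bl) / tau) +
          log(2 / (pi * (1 + prop^2))) - log(2 / (pi * (1 + tau^2))) +
          log(prop) - log(tau)
        if (log(runif(1)) < dlp) tau <- prop
      }
      ## --- adaptation (burn-in only)
      if (adapting && it %% 50L == 0L) {
        batch <- batch + 1L
        stepA <- .adapt(stepA, accA / 50, 0.35, batch)
        stepD <- .adapt(stepD, accD / 50, 0.35, batch)
        stepQ <- .adapt(stepQ, accQ / 50, 0.35, batch)
        stepP <- .adapt(stepP, accP / 50, 0.35, batch)
        stepB <- .adapt(stepB, accB / nB, 0.25, batch)
        accA <- accD <- accQ <- accP <- accB <- 0; nB <- 0
      }
      ## --- save
      if (!adapting && (it - ctl$n_burn) %% ctl$thin == 0L) {
        kIdx <- kIdx + 1L
        kept[kIdx, ] <- c(beta, muA, sgA, muD, sgD, muP, sgP, muQ, sgQ,
                          if (useLasso) tau, alpha, delta, psi1)
      }
    }
    colnames(kept) <- parNames
    chains[[ch]] <- kept[seq_len(kIdx), , drop = FALSE]
  }
  rh <- vapply(parNames, function(pn) {
    tryCatch(gelmanRhat(lapply(chains, function(m) m[, pn])),
             error = function(e) NA_real_)
  }, numeric(1))
  allDraws <- do.call(rbind, chains)
  summ <- data.frame(
    parameter = parNames,
    mean = colMeans(allDraws),
    sd = apply(allDraws, 2, sd),
    lo = apply(allDraws, 2, quantile, 0.025),
    hi = apply(allDraws, 2, quantile, 0.975),
    rhat = unname(rh), row.names = NULL)
  conv <- all(rh < 1.05, na.rm = TRUE)
  if (!conv)
    warning("MCMC not converged: max split R-hat = ",
            round(max(rh, na.rm = TRUE), 3), call. = FALSE)
  new("OccupancyFit", draws = chains, summary = summ, rhat = rh,
      converged = conv, control = ctl, seed = as.integer(seed),
      meta = list(groups = groups, years = years, design = design,
                  betaNames = paste0("beta:", colnames(Xd)),
                  useLasso = useLasso))
}
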