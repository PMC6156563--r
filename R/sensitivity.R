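## Equilibrium occupancy and its sensitivity to standardized climate.

#' Equilibrium occupancy probability
#'
#' Fixed point of the occupancy recursion
#' `psi' = psi * phi + (1 - psi) * gamma` under constant colonization
#' `gamma` and persistence `phi`: `psi* = gamma / (gamma + 1 - phi)`.
#'
#' @param gamma colonization probability in \[0, 1\].
#' @param phi persistence probability in \[0, 1\]; the pair
#'   `gamma = 0, phi = 1` leaves every state fixed and has no unique
#'   equilibrium (error).
#' @return Equilibrium occupancy; vectorized.
#' @export
#' @examples
#' equilibriumOccupancy(0.1, 0.5)  # 1/6
equilibriumOccupancy <- function(gamma, phi) {
  if (any(gamma < 0 | gamma > 1 | phi < 0 | phi > 1))
    stop("gamma and phi must lie in [0, 1]")
  den <- gamma + 1 - phi
  if (any(den <= 0))
    stop("undefined equilibrium: gamma = 0 with phi = 1")
  gamma / den
}

#' Analytic sensitivity of relative equilibrium occupancy
#'
#' Rate of change of relative equilibrium occupancy per 1-SD change in a
#' standardized climate variable, by the chain rule through the two
#' transition parameters:
#' \deqn{\frac{d\psi}{dX^*} = \frac{1}{\psi^*}\sum_{T\in\{\gamma,\phi\}}
#'   \frac{d\psi^*}{dT}\frac{dT}{dX^*}}
#' with \eqn{d\psi^*/d\gamma = (1-\phi)/(\gamma+1-\phi)^2},
#' \eqn{d\psi^*/d\phi = \gamma/(\gamma+1-\phi)^2}, and logit-linear
#' transitions so \eqn{d\gamma/dX^* = \gamma(1-\gamma)\beta},
#' \eqn{d\phi/dX^* = \phi(1-\phi)\beta}; under the auto-logistic model the
#' same total effect `beta` enters both transitions.
#'
#' @param gamma,phi transition probabilities at the reference climate.
#' @param beta total logit-scale effect of the variable (main plus the
#'   group's interactions); `beta_gamma`/`beta_phi` may be supplied
#'   separately.
#' @param beta_gamma,beta_phi optional distinct effects on each transition.
#' @return Relative sensitivity (unitless per SD); vectorized.
#' @export
#' @examples
#' sensitivityChain(0.269, 0.731, beta = 0.1)  # ~ 0.0731
sensitivityChain <- function(gamma, phi, beta, beta_gamma = beta,
                             beta_phi = beta) {
  psi <- equilibriumOccupancy(gamma, phi)
  if (any(psi <= 0))
    stop("relative sensitivity undefined at psi* = 0")
  den2 <- (gamma + 1 - phi)^2
  dpsi_dgamma <- (1 - phi) / den2
  dpsi_dphi <- gamma / den2
  (dpsi_dgamma * gamma * (1 - gamma) * beta_gamma +
     dpsi_dphi * phi * (1 - phi) * beta_phi) / psi
}

#' Community (species-richness) sensitivity
#'
#' Average of per-species sensitivities across a local community; since
#' expected species richness is the sum of occupancy probabilities, the
#' mean relative sensitivity tracks the relative response of richness.
#'
#' @param sens numeric per-species sensitivities.
#' @param weights optional weights (default equal).
#' @return Weighted mean sensitivity.
#' @export
richnessSensitivity <- function(sens, weights = NULL) {
  if (!length(sens)) stop("empty community")
  if (is.null(weights)) weights <- rep(1, length(sens))
  sum(sens * weights) / sum(weights)
}

#' Posterior sensitivity per species and study area
#'
#' Evaluates [sensitivityChain()] per posterior draw at a reference climate
#' (default X = 0, each site's 30-year mean): for each species-by-study-area
#' group, `gamma = plogis(alpha_jk)`, `phi = plogis(alpha_jk + delta_jk)`,
#' and the variable's total logit effect is the main coefficient plus the
#' group's interaction terms ([groupClimateEffects()]). Masked variables
#' (snow and winter severity in warm areas, breeding water at terrestrial
#' sites) yield `NA`, not zero.
#'
#' @param fit an [OccupancyFit-class] object.
#' @param design the [OccupancyDesign-class] used to fit (default: the one
#'   stored in the fit).
#' @param mode `"draws"` (default) evaluates per posterior draw and
#'   summarizes; `"mean"` evaluates once at the posterior means.
#' @return A [SensitivityResult-class] object.
#' @export
posteriorSensitivity <- function(fit, design = NULL,
                                 mode = c("draws", "mean")) {
  mode <- match.arg(mode)
  if (is.null(design)) design <- fit@meta$design
  groups <- fit@meta$groups
  gmod <- design@moderators
  gi <- match(paste(groups$species, groups$study_area),
              paste(gmod$species, gmod$study_area))
  if (anyNA(gi)) stop("fit groups missing from design moderator table")
  allDraws <- do.call(rbind, posteriorDraws(fit))
  if (mode == "mean") allDraws <- t(colMeans(allDraws))
  bNames <- fit@meta$betaNames
  vars <- climateVariables()
  nD <- nrow(allDraws)
  ## total effect is linear in beta: precompute per-(group, variable)
  ## weights over the design columns, then one matrix product per fit
  terms <- designTerms(design)
  W <- matrix(0, nrow(gmod) * length(vars), nrow(terms))
  colnames(W) <- terms$column
  for (vi in seq_along(vars)) {
    v <- vars[vi]
    rows <- (seq_len(nrow(gmod)) - 1L) * length(vars) + vi
    W[rows, terms$column[terms$climate == v & terms$type == "main"]] <- 1
    it <- terms[terms$climate == v & terms$type == "interaction", ]
    if (nrow(it))
      W[rows, it$column] <- as.matrix(gmod[, it$moderator, drop = FALSE])
  }
  betaDraws <- t(allDraws[, bNames, drop = FALSE])   # P x nD
  TotAll <- W %*% betaDraws                          # (groups*5) x nD
  tab <- list(); drawsOut <- list()
  for (g in seq_len(nrow(groups))) {
    aCol <- paste0("alpha[", groups$species[g], ",",
                   groups$study_area[g], "]")
    dCol <- paste0("delta[", groups$species[g], ",",
                   groups$study_area[g], "]")
    gam <- plogis(allDraws[, aCol])
    phi <- plogis(allDraws[, aCol] + allDraws[, dCol])
    psi <- equilibriumOccupancy(gam, phi)
    totG <- t(TotAll[(gi[g] - 1L) * length(vars) + seq_along(vars), ,
                     drop = FALSE])                  # nD x 5
    sens <- matrix(NA_real_, nD, length(vars),
                   dimnames = list(NULL, vars))
    for (vi in seq_along(vars))
      sens[, vi] <- sensitivityChain(gam, phi, totG[, vi])
    inc <- unlist(gmod[gi[g], paste0("included_", vars)])
    sens[, !inc] <- NA_real_
    drawsOut[[g]] <- sens
    tab[[g]] <- data.frame(
      species = groups$species[g], study_area = groups$study_area[g],
      variable = vars, psi_star = mean(psi),
      sens_mean = colMeans(sens),
      sens_lo = apply(sens, 2, function(x)
        if (all(is.na(x))) NA_real_ else quantile(x, 0.025)),
      sens_hi = apply(sens, 2, function(x)
        if (all(is.na(x))) NA_real_ else quantile(x, 0.975)),
      included = unname(inc), row.names = NULL)
  }
  names(drawsOut) <- paste(groups$species, groups$study_area, sep = "|")
  new("SensitivityResult", table = do.call(rbind, tab), draws = drawsOut)
}
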