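## Marginal likelihood of one detection series, and the transition
## parameters implied by the auto-logistic formulation.

#' Colonization and persistence probabilities
#'
#' Under the auto-logistic transition model, colonization is
#' `gamma = plogis(alpha + beta.X)` (site empty last year, z = 0) and
#' persistence is `phi = plogis(alpha + delta + beta.X)` (site occupied,
#' z = 1).
#'
#' @param alpha intercept random effect (logit scale).
#' @param delta auto-logistic occupied-state effect (logit scale).
#' @param xbeta total climate forcing `beta . X` (logit scale); vectorized.
#' @return list with numeric `gamma` and `phi`.
#' @export
#' @examples
#' transitionProbs(-1, 2, 0)  # gamma ~ 0.269, phi ~ 0.731
transitionProbs <- function(alpha, delta, xbeta = 0) {
  list(gamma = plogis(alpha + xbeta), phi = plogis(alpha + delta + xbeta))
}

#' Marginal log-likelihood of one detection series
#'
#' Exact likelihood of a site-by-species detection history with the latent
#' occupancy states marginalized by the forward algorithm: initial
#' occupancy `plogis(psi1)`, auto-logistic transitions, and per-visit
#' Bernoulli emissions with year-specific detection probability (the
#' probability of the ordered visit outcomes; an unoccupied site can only
#' yield non-detections).
#'
#' @param detections list of integer 0/1 vectors, one per year (a year may
#'   have zero visits), or a years-by-visits matrix (NA = no visit).
#' @param psi1 logit-scale initial occupancy.
#' @param alpha,delta auto-logistic parameters (logit scale).
#' @param p per-year detection probability, length = number of years.
#' @param xbeta per-year total climate forcing on the transition INTO each
#'   year (first element unused), length = number of years.
#' @return Log of the marginal probability of the series.
#' @export
#' @examples
#' exp(siteLogLik(list(c(0, 0)), psi1 = 0, alpha = 0, delta = 0,
#'                p = 0.5, xbeta = 0))  # 0.625
siteLogLik <- function(detections, psi1, alpha, delta, p, xbeta = NULL) {
  if (is.matrix(detections))
    detections <- lapply(seq_len(nrow(detections)), function(i) {
      v <- detections[i, ]
      v[!is.na(v)]
    })
  Tn <- length(detections)
  if (Tn < 1L) stop("history must span at least 1 year")
  p <- rep_len(p, Tn)
  if (is.null(xbeta)) xbeta <- numeric(Tn)
  xbeta <- rep_len(xbeta, Tn)
  if (any(p < 0 | p > 1)) stop("detection probabilities outside [0, 1]")
  emis <- function(t) {
    y <- detections[[t]]
    if (!length(y)) return(c(1, 1))
    e1 <- prod(ifelse(y == 1L, p[t], 1 - p[t]))
    e0 <- as.numeric(all(y == 0L))
    c(e1, e0)
  }
  pr1 <- plogis(psi1)
  e <- emis(1L)
  f <- c(pr1 * e[1], (1 - pr1) * e[2])  # (occupied, empty)
  ll <- 0
  if (Tn > 1L) for (t in 2:Tn) {
    ct <- sum(f)
    if (ct <= 0) return(-Inf)
    ll <- ll + log(ct)
    f <- f / ct
    tp <- transitionProbs(alpha, delta, xbeta[t])
    g1 <- f[1] * tp$phi + f[2] * tp$gamma
    g0 <- f[1] * (1 - tp$phi) + f[2] * (1 - tp$gamma)
    e <- emis(t)
    f <- c(g1 * e[1], g0 * e[2])
  }
  tot <- sum(f)
  if (tot <= 0) -Inf else ll + log(tot)
}
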