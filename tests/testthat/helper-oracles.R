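# Independent oracles and small fixtures shared across tests.

# brute-force AFI: maximum over all ordered pairs (i <= j) of the
# cumulative-temperature curve (origin included) of curve[i] - curve[j]
afiBruteForce <- function(daily_tmean) {
  cum <- c(0, cumsum(daily_tmean))
  best <- 0
  for (i in seq_along(cum)) {
    later <- cum[i:length(cum)]
    best <- max(best, cum[i] - min(later))
  }
  best
}

# brute-force highest 10-day moving mean
tmax10BruteForce <- function(x) {
  max(vapply(seq_len(length(x) - 9L),
             function(i) mean(x[i:(i + 9L)]), numeric(1)))
}

# exact marginal likelihood by enumerating every latent occupancy path
enumLogLik <- function(detections, psi1, alpha, delta, p, xbeta = NULL) {
  Tn <- length(detections)
  p <- rep_len(p, Tn)
  if (is.null(xbeta)) xbeta <- numeric(Tn)
  xbeta <- rep_len(xbeta, Tn)
  paths <- as.matrix(expand.grid(rep(list(0:1), Tn)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    z <- paths[r, ]
    pr <- if (z[1] == 1) plogis(psi1) else 1 - plogis(psi1)
    if (Tn > 1) for (t in 2:Tn) {
      pt <- plogis(alpha + delta * z[t - 1] + xbeta[t])
      pr <- pr * if (z[t] == 1) pt else 1 - pt
    }
    for (t in seq_len(Tn)) {
      y <- detections[[t]]
      if (length(y)) {
        pr <- pr * if (z[t] == 1)
          prod(ifelse(y == 1, p[t], 1 - p[t]))
        else as.numeric(all(y == 0))
      }
    }
    tot <- tot + pr
  }
  unname(log(tot))
}

# random detection history: T years, 0..3 visits per year
randomHistory <- function(Tn, max_visits = 3L) {
  lapply(seq_len(Tn), function(t) {
    nv <- sample(0:max_visits, 1L)
    if (nv == 0L) integer() else sample(0:1, nv, replace = TRUE)
  })
}

# tiny simulated study shared by fitting tests
tinyStudy <- function(seed = 7L, ...) {
  cfg <- simConfig(n_study_areas = 2L, n_species = 3L,
                   n_sites_per_area = 12L, n_years = 6L, n_visits = 3L,
                   seed = seed, ...)
  simulateStudy(cfg)
}
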