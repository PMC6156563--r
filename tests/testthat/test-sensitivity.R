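test_that("equilibrium occupancy is the fixed point of the recursion", {
  expect_equal(equilibriumOccupancy(0.269, 0.731), 0.5)
  expect_equal(equilibriumOccupancy(0, 0.9), 0)
  expect_equal(equilibriumOccupancy(0.1, 0.5), 1 / 6, tolerance = 1e-12)
  expect_error(equilibriumOccupancy(0, 1), "undefined")
  expect_error(equilibriumOccupancy(-0.1, 0.5), "\\[0, 1\\]")
  # closed form vs long recursion across a grid
  for (g in seq(0.02, 0.98, length.out = 8)) {
    for (f in seq(0.02, 0.98, length.out = 8)) {
      psi <- 0.5
      for (i in 1:10000) psi <- psi * f + (1 - psi) * g
      expect_lt(abs(equilibriumOccupancy(g, f) - psi), 1e-10)
    }
  }
})

test_that("chain-rule sensitivity matches the central-difference oracle", {
  expect_equal(sensitivityChain(0.3, 0.7, 0), 0)
  expect_equal(sensitivityChain(0.269, 0.731, 0.1), 0.0731,
               tolerance = 1e-3)
  set.seed(601)
  h <- 1e-5
  for (r in 1:500) {
    a <- rnorm(1, -0.5, 1); d <- abs(rnorm(1, 1.5, 1)); b <- rnorm(1, 0, 0.5)
    psiAt <- function(x) {
      equilibriumOccupancy(plogis(a + b * x), plogis(a + d + b * x))
    }
    numeric_sens <- (psiAt(h) - psiAt(-h)) / (2 * h * psiAt(0))
    analytic <- sensitivityChain(plogis(a), plogis(a + d), b)
    expect_lt(abs(analytic - numeric_sens), 1e-6)
  }
})

test_that("sensitivity keeps the sign of the climate effect", {
  set.seed(602)
  for (r in 1:200) {
    g <- runif(1, 0.01, 0.99); f <- runif(1, 0.01, 0.99)
    b <- runif(1, 0.01, 1)
    expect_gt(sensitivityChain(g, f, b), 0)
    expect_lt(sensitivityChain(g, f, -b), 0)
  }
})

test_that("community sensitivity averages species", {
  expect_equal(richnessSensitivity(0.3), 0.3)
  expect_equal(richnessSensitivity(c(0.2, -0.2)), 0)
  expect_error(richnessSensitivity(numeric(0)), "empty")
  set.seed(603)
  for (r in 1:10) {
    x <- rnorm(7)
    expect_equal(richnessSensitivity(x), mean(x))
  }
})

test_that("deterministic long-horizon simulation matches the analytic chain", {
  grid <- scenarioGrid()
  expect_equal(nrow(grid), 36L)
  for (i in seq_len(nrow(grid))) {
    num <- runScenario(grid$gamma0[i], grid$phi0[i], "deterministic",
                       horizon = 1500, h = 1e-4)$sens
    ana <- sensitivityChain(grid$gamma0[i], grid$phi0[i], 1)
    expect_lt(abs(num - ana), 1e-3)
  }
})

# a hand-built fit object: 2 groups, mains-only design, controlled draws
syntheticFit <- function(betaDraws, alphaVal = -0.5, deltaVal = 1.7) {
  sites <- data.frame(site = c("s1", "s2"), study_area = c("A1", "A2"),
                      habitat = "wetland", ecoregion = "other",
                      norm_temp_c = 10, norm_precip_mm = 900)
  species <- data.frame(species = "sp01", taxon = "Anura")
  climate <- simulateAnomalies(sites$site, 1:3, 1)
  # mask snow for the second (warm) study area
  d <- climateTable(climate)
  d$swe_included[d$site == "s2"] <- FALSE
  d$swe_raw[d$site == "s2"] <- NA
  d$swe_anom[d$site == "s2"] <- NA
  climate <- new("ClimateAnnual", data = d, baselineYears = 1:3)
  des <- buildDesign(climate, sites, species, interactions = FALSE)
  nD <- nrow(betaDraws)
  groups <- data.frame(species = "sp01", study_area = c("A1", "A2"))
  parNames <- c(paste0("beta:", climateVariables()),
                "alpha[sp01,A1]", "delta[sp01,A1]", "psi1[sp01,A1]",
                "alpha[sp01,A2]", "delta[sp01,A2]", "psi1[sp01,A2]")
  m <- cbind(betaDraws,
             matrix(rep(c(alphaVal, deltaVal, 0, alphaVal, deltaVal, 0),
                        each = nD), nD))
  colnames(m) <- parNames
  new("OccupancyFit", draws = list(m, m),
      summary = data.frame(), rhat = setNames(rep(1, ncol(m)), parNames),
      converged = TRUE, control = mcmcControl(), seed = 1L,
      meta = list(groups = groups, years = 1:3, design = des,
                  betaNames = paste0("beta:", climateVariables()),
                  useLasso = FALSE))
}

test_that("posterior sensitivity summarizes draws and respects masks", {
  # point-mass posterior at beta = 0: every interval is exactly [0, 0]
  b0 <- matrix(0, 50, 5)
  sr <- posteriorSensitivity(syntheticFit(b0))
  tab <- sensitivityTable(sr)
  included <- tab[tab$included, ]
  expect_true(all(included$sens_mean == 0 & included$sens_lo == 0 &
                    included$sens_hi == 0))
  # masked snow variable in the warm study area: missing, not zero
  warmSwe <- tab[tab$study_area == "A2" & tab$variable == "swe", ]
  expect_false(warmSwe$included)
  expect_true(is.na(warmSwe$sens_mean))
  coldSwe <- tab[tab$study_area == "A1" & tab$variable == "swe", ]
  expect_true(coldSwe$included)
})

test_that("credible interval width scales with posterior spread", {
  set.seed(604)
  widths <- vapply(c(0.02, 0.05, 0.1), function(s) {
    b <- matrix(rnorm(500 * 5, 0.2, s), 500, 5)
    tab <- sensitivityTable(posteriorSensitivity(syntheticFit(b)))
    row <- tab[tab$study_area == "A1" & tab$variable == "afi", ]
    row$sens_hi - row$sens_lo
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("posterior-mean mode evaluates once at the mean coefficients", {
  set.seed(605)
  b <- matrix(rnorm(200 * 5, 0.3, 0.05), 200, 5)
  fit <- syntheticFit(b)
  tabM <- sensitivityTable(posteriorSensitivity(fit, mode = "mean"))
  row <- tabM[tabM$study_area == "A1" & tabM$variable == "afi", ]
  expected <- sensitivityChain(plogis(-0.5), plogis(1.2),
                               mean(b[, 1]))
  expect_equal(row$sens_mean, expected, tolerance = 1e-10)
  expect_equal(row$sens_lo, row$sens_hi)
})
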