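## Synthetic-data generators: detection histories with known truth, daily
## weather with seasonal structure, traits + phylogeny from the latent
## factor model.

#' Simulation configuration
#'
#' Study conditions for the survey generator. Defaults emulate the nested
#' monitoring design at desk scale: multiple study areas, sites nested in
#' areas, repeat visits within years, at least three years per study, with
#' climate effects beta = (0.4, -0.4, 0.2, 0, 0) on the logit scale per SD
#' of anomaly, moderate random-effect spread, and detection probability
#' around 0.62 per visit.
#'
#' @param n_study_areas,n_species,n_sites_per_area,n_years,n_visits design
#'   counts; all >= 1 and `n_years >= 3` (minimum study length).
#' @param true_beta length-5 climate effect vector (logit scale per SD),
#'   ordered as [climateVariables()].
#' @param mu_alpha,sigma_alpha hyper-parameters of the colonization
#'   intercept random effect alpha_jk ~ Normal(mu, sigma).
#' @param mu_delta,sigma_delta hyper-parameters of the auto-logistic
#'   (persistence minus colonization) random effect delta_jk.
#' @param mu_p,sigma_p hyper-parameters of logit detection probability,
#'   varying by (study area, species, year).
#' @param mu_psi1,sigma_psi1 hyper-parameters of the logit initial-occupancy
#'   random effect (species by study area).
#' @param seed integer RNG seed.
#' @return A validated list of class `simConfig`.
#' @export
simConfig <- function(n_study_areas = 5L, n_species = 8L,
                      n_sites_per_area = 40L, n_years = 10L, n_visits = 3L,
                      true_beta = c(0.4, -0.4, 0.2, 0, 0),
                      mu_alpha = -1, sigma_alpha = 0.5,
                      mu_delta = 2, sigma_delta = 0.5,
                      mu_p = 0.5, sigma_p = 0.75,
                      mu_psi1 = 0, sigma_psi1 = 0.5,
                      seed = 1L) {
  cfg <- list(n_study_areas = as.integer(n_study_areas),
              n_species = as.integer(n_species),
              n_sites_per_area = as.integer(n_sites_per_area),
              n_years = as.integer(n_years), n_visits = as.integer(n_visits),
              true_beta = as.numeric(true_beta),
              mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
              mu_delta = mu_delta, sigma_delta = sigma_delta,
              mu_p = mu_p, sigma_p = sigma_p,
              mu_psi1 = mu_psi1, sigma_psi1 = sigma_psi1,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_study_areas", "n_species", "n_sites_per_area",
                         "n_years", "n_visits")])
  if (any(counts < 1L)) stop("all design counts must be >= 1")
  if (cfg$n_years < 3L) stop("n_years must be >= 3 (minimum study length)")
  if (length(cfg$true_beta) != 5L)
    stop("true_beta must have length 5 (one per climate variable)")
  if (any(c(sigma_alpha, sigma_delta, sigma_p, sigma_psi1) < 0))
    stop("sigma parameters must be >= 0")
  class(cfg) <- "simConfig"
  cfg
}

#' Default site factor table for simulations
#'
#' Sites nested in study areas with habitat class, ecoregion, and 30-year
#' climate normals assigned from realistic ranges.
#'
#' @param n_study_areas,n_sites_per_area design counts.
#' @param seed RNG seed.
#' @return data.frame with columns `site`, `study_area`, `habitat`,
#'   `ecoregion`, `norm_temp_c`, `norm_precip_mm`.
#' @export
simulateSiteTable <- function(n_study_areas, n_sites_per_area, seed = 1L) {
  set.seed(seed)
  areas <- sprintf("A%02d", seq_len(n_study_areas))
  ecorg <- c("western montane", "western dry", "northeastern forest",
             "southeastern forest", "other")
  areaEco <- sample(ecorg, n_study_areas, replace = TRUE)
  areaTemp <- runif(n_study_areas, 2, 20)
  areaPrec <- runif(n_study_areas, 300, 1600)
  out <- do.call(rbind, lapply(seq_len(n_study_areas), function(j) {
    data.frame(
      site = sprintf("%s_S%03d", areas[j], seq_len(n_sites_per_area)),
      study_area = areas[j],
      habitat = sample(c("wetland", "stream", "terrestrial"),
                       n_sites_per_area, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15)),
      ecoregion = areaEco[j],
      norm_temp_c = round(areaTemp[j] + rnorm(n_sites_per_area, 0, 1), 2),
      norm_precip_mm = round(areaPrec[j] +
                               rnorm(n_sites_per_area, 0, 80), 1))
  }))
  rownames(out) <- NULL
  out
}

#' Default species table for simulations
#'
#' @param n_species number of species; roughly 60/40 frogs vs salamanders.
#' @param seed RNG seed.
#' @return data.frame with columns `species`, `taxon`.
#' @export
simulateSpeciesTable <- function(n_species, seed = 1L) {
  set.seed(seed + 1L)
  data.frame(species = sprintf("sp%02d", seq_len(n_species)),
             taxon = sample(c("Anura", "Caudata"), n_species,
                            replace = TRUE, prob = c(0.6, 0.4)))
}

#' Standard-normal climate anomalies for simulation
#'
#' Builds a [ClimateAnnual-class] object whose five anomalies are
#' independent standard-normal draws per (site, year) with all inclusion
#' masks on -- covariates already standardized, as the occupancy model
#' assumes. Raw values equal the anomalies (unit baseline).
#'
#' @param sites character vector of site ids (or a site table with a `site`
#'   column).
#' @param years integer vector of years.
#' @param seed RNG seed.
#' @return A [ClimateAnnual-class] object.
#' @export
simulateAnomalies <- function(sites, years, seed = 1L) {
  if (is.data.frame(sites)) sites <- sites$site
  set.seed(seed + 2L)
  key <- expand.grid(site = sites, year = as.integer(years),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  A <- matrix(rnorm(nrow(key) * 5L), ncol = 5L)
  colnames(A) <- climateVariables()
  d <- data.frame(key, setNames(as.data.frame(A),
                                paste0(climateVariables(), "_raw")),
                  setNames(as.data.frame(A),
                           paste0(climateVariables(), "_anom")),
                  afi_included = TRUE, swe_included = TRUE,
                  spei_included = TRUE)
  new("ClimateAnnual", data = d, baselineYears = as.integer(years))
}

#' Simulate detection histories under the auto-logistic occupancy model
#'
#' Generates latent occupancy and repeat-visit detections from the
#' hierarchical model: per species-by-study-area group, alpha_jk ~
#' Normal(mu_alpha, sigma_alpha), delta_jk ~ Normal(mu_delta, sigma_delta),
#' logit psi1_jk ~ Normal(mu_psi1, sigma_psi1); per group-year, logit
#' p_jkt ~ Normal(mu_p, sigma_p). Initial occupancy z_1 ~
#' Bernoulli(plogis(psi1)); transitions z_(t) | z_(t-1) ~
#' Bernoulli(plogis(alpha + delta z_(t-1) + beta . X_t)) where X_t are the
#' site's climate anomalies for year t (masked anomalies contribute 0);
#' detections are Bernoulli(z p) per visit.
#'
#' @param config a [simConfig()] list.
#' @param climate a [ClimateAnnual-class] covering every simulated
#'   site-year (errors name missing keys otherwise).
#' @param sites optional site table (default [simulateSiteTable()]).
#' @param species optional species table (default [simulateSpeciesTable()]).
#' @param inclusion optional logical matrix (species x study areas); FALSE
#'   drops that species from that program, emulating real-data sparsity.
#' @return A [SurveyData-class] with the generating truth attached
#'   (`surveyTruth()`): per-group `alpha`, `delta`, `psi1`, per-group-year
#'   `p`, the latent state table `z`, and `beta`.
#' @export
simulateSurveys <- function(config, climate, sites = NULL, species = NULL,
                            inclusion = NULL) {
  stopifnot(inherits(config, "simConfig"))
  if (is.null(sites))
    sites <- simulateSiteTable(config$n_study_areas,
                               config$n_sites_per_area, config$seed)
  if (is.null(species))
    species <- simulateSpeciesTable(config$n_species, config$seed)
  set.seed(config$seed)
  years <- seq_len(config$n_years)
  yrsAll <- sort(unique(climateTable(climate)$year))
  if (length(yrsAll) < config$n_years)
    stop("climate covers ", length(yrsAll), " years; config needs ",
         config$n_years)
  years <- yrsAll[seq_len(config$n_years)]
  nA <- config$n_study_areas; nK <- config$n_species
  areas <- unique(sites$study_area)
  if (length(areas) != nA) stop("site table has ", length(areas),
                                " study areas; config expects ", nA)
  # group = species x study area
  groups <- expand.grid(species = species$species, study_area = areas,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  G <- nrow(groups)
  groups$alpha <- rnorm(G, config$mu_alpha, config$sigma_alpha)
  groups$delta <- rnorm(G, config$mu_delta, config$sigma_delta)
  groups$psi1 <- rnorm(G, config$mu_psi1, config$sigma_psi1)
  lp <- matrix(rnorm(G * length(years), config$mu_p, config$sigma_p),
               G, length(years))
  if (is.null(inclusion)) {
    groups$included <- TRUE
  } else {
    groups$included <- inclusion[cbind(match(groups$species,
                                             species$species),
                                       match(groups$study_area, areas))]
  }
  # series = site x species
  series <- merge(sites[, c("site", "study_area")], groups,
                  by = "study_area", sort = FALSE)
  series <- series[series$included, ]
  series <- series[order(series$site, series$species), ]
  S <- nrow(series)
  Tn <- length(years)
  X <- designAnomalies(climate,
                       site = rep(series$site, each = Tn),
                       year = rep(years, times = S))
  eta <- matrix(as.vector(X %*% config$true_beta), nrow = S, byrow = TRUE)
  gidx <- match(paste(series$species, series$study_area),
                paste(groups$species, groups$study_area))
  z <- matrix(0L, S, Tn)
  z[, 1] <- rbinom(S, 1L, plogis(series$psi1))
  for (t in 2:Tn) {
    pr <- plogis(series$alpha + series$delta * z[, t - 1L] + eta[, t])
    z[, t] <- rbinom(S, 1L, pr)
  }
  pMat <- matrix(plogis(lp[gidx, ]), S, Tn)
  nv <- config$n_visits
  obs <- data.frame(
    study_area = rep(series$study_area, each = Tn * nv),
    site = rep(series$site, each = Tn * nv),
    species = rep(series$species, each = Tn * nv),
    year = rep(rep(years, each = nv), times = S),
    visit = rep(seq_len(nv), times = S * Tn))
  pv <- rep(as.vector(t(pMat * z)), each = nv)
  obs$detected <- rbinom(nrow(obs), 1L, pv)
  truth <- list(
    groups = groups,
    p = data.frame(groups[rep(seq_len(G), times = Tn),
                          c("species", "study_area")],
                   year = rep(years, each = G),
                   p = plogis(as.vector(lp))),
    z = data.frame(site = rep(series$site, each = Tn),
                   species = rep(series$species, each = Tn),
                   year = rep(years, times = S),
                   z = as.integer(t(z))),
    beta = config$true_beta, config = config)
  new("SurveyData", observations = obs,
      sites = sites, species = species, truth = truth)
}

#' Simulate a complete desk-scale study
#'
#' Convenience wrapper: site table, standard-normal climate anomalies, and
#' detection histories in one call.
#'
#' @param config a [simConfig()] list.
#' @return list with elements `survey` ([SurveyData-class]), `climate`
#'   ([ClimateAnnual-class]), `sites`, `species`.
#' @export
simulateStudy <- function(config = simConfig()) {
  sites <- simulateSiteTable(config$n_study_areas, config$n_sites_per_area,
                             config$seed)
  species <- simulateSpeciesTable(config$n_species, config$seed)
  climate <- simulateAnomalies(sites$site, seq_len(config$n_years),
                               config$seed)
  survey <- simulateSurveys(config, climate, sites = sites,
                            species = species)
  list(survey = survey, climate = climate, sites = sites, species = species)
}

#' Simulate daily weather and monthly snow/soil indices
#'
#' Per-site daily mean temperature with sinusoidal seasonality (peak in
#' mid-July), an optional linear warming trend, and Gaussian noise; daily
#' precipitation with weak seasonality; monthly snow-water-equivalent and
#' soil-moisture indices in \[0, 1\] derived from the within-site-month
#' distribution of winter temperature and water balance across years. The
#' year is a fixed 365-day calendar (no leap days).
#'
#' @param site_profiles data.frame with columns `site`, `mean_temp_c`,
#'   `seasonal_amp_c`, `precip_mean_mm` (mean daily precipitation), and
#'   optionally `latitude`, `trend_c_per_year` (default 0) and
#'   `noise_sd_c` (default 2).
#' @param n_years number of years to generate (>= 31: a 30-year baseline
#'   plus at least one analysis year).
#' @param start_year first calendar year label.
#' @param seed RNG seed.
#' @return list with `weather` (site, year, doy, tmean_c, precip_mm) and
#'   `indices` (site, year, month, swe_quantile, soil_moisture).
#' @export
simulateWeather <- function(site_profiles, n_years = 32L,
                            start_year = 1982L, seed = 1L) {
  if (n_years < 1L) stop("n_years must be positive")
  set.seed(seed + 3L)
  if (is.null(site_profiles$trend_c_per_year))
    site_profiles$trend_c_per_year <- 0
  if (is.null(site_profiles$noise_sd_c)) site_profiles$noise_sd_c <- 2
  if (is.null(site_profiles$latitude)) site_profiles$latitude <- 42
  years <- start_year + seq_len(n_years) - 1L
  doy <- 1:365
  seas <- cos(2 * pi * (doy - 197) / 365)  # peak at mid-July
  wx <- list(); ind <- list()
  for (si in seq_len(nrow(site_profiles))) {
    p <- site_profiles[si, ]
    tm <- outer(seq_len(n_years) - 1L, doy, function(yy, dd) {
      p$mean_temp_c + p$seasonal_amp_c * seas[dd] + p$trend_c_per_year * yy
    })
    if (p$noise_sd_c > 0)
      tm <- tm + matrix(rnorm(length(tm), 0, p$noise_sd_c), nrow(tm))
    pseas <- 1 + 0.3 * cos(2 * pi * (doy - 60) / 365)
    if (p$noise_sd_c > 0) {
      pr <- matrix(rgamma(n_years * 365L, shape = 0.8,
                          scale = p$precip_mean_mm / 0.8),
                   n_years, 365L) * matrix(pseas, n_years, 365L,
                                           byrow = TRUE)
    } else {
      pr <- matrix(p$precip_mean_mm * pseas, n_years, 365L, byrow = TRUE)
    }
    wx[[si]] <- data.frame(site = p$site,
                           year = rep(years, each = 365L),
                           doy = rep(doy, times = n_years),
                           tmean_c = round(as.vector(t(tm)), 3),
                           precip_mm = round(as.vector(t(pr)), 3))
    # monthly indices: quantile of (cold, wet) latent within site-month
    mo <- doyToMonth(doy)
    tmon <- t(apply(tm, 1, function(v) tapply(v, mo, mean)))
    pmon <- t(apply(pr, 1, function(v) tapply(v, mo, sum)))
    qcol <- function(latent) {
      apply(latent, 2, function(v) {
        s <- sd(v)
        if (!is.finite(s) || s < 1e-12) return(rep(0.5, length(v)))
        pnorm((v - mean(v)) / s)
      })
    }
    swe <- qcol(-tmon + 0.02 * pmon)
    soil <- qcol(pmon - 8 * pmax(tmon, 0))
    ind[[si]] <- data.frame(site = p$site,
                            year = rep(years, times = 12L),
                            month = rep(1:12, each = n_years),
                            swe_quantile = round(as.vector(swe), 4),
                            soil_moisture = round(as.vector(soil), 4))
  }
  list(weather = do.call(rbind, wx), indices = do.call(rbind, ind))
}

#' Simulate life-history traits on a phylogeny
#'
#' Two latent factors are drawn from mean-zero multivariate normals with
#' covariance `lambda * (1 - scaled patristic distance)` off the unit
#' diagonal; a lower-triangular 3x2 loading matrix maps the factors to
#' standardized snout--vent length, log clutch size, and development time,
#' observed with Gaussian error and rescaled to natural units. A fraction
#' of trait cells is masked as missing.
#'
#' @param n_species number of species (>= 3).
#' @param missing_fraction fraction of trait cells masked, in \[0, 1).
#' @param lambda_true phylogenetic signal in \[0, 1\].
#' @param seed RNG seed.
#' @return list with `traits` (species, svl_mm, log_clutch, dev_days, with
#'   `NA` for missing), `tree` (ape phylo), and `latent` truth (factors,
#'   loadings, complete standardized traits).
#' @export
simulateTraitsPhylo <- function(n_species, missing_fraction = 0.1,
                                lambda_true = 1, seed = 1L) {
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)")
  if (lambda_true < 0 || lambda_true > 1)
    stop("lambda_true must lie in [0, 1]")
  if (n_species < 3L) stop("need at least 3 species")
  set.seed(seed + 4L)
  tree <- ape::rcoal(n_species, tip.label = sprintf("sp%02d",
                                                    seq_len(n_species)))
  D <- phyloDistances(tree)
  C <- lambda_true * (1 - D)
  diag(C) <- 1
  L <- chol(C + diag(1e-8, n_species))
  Fm <- t(L) %*% matrix(rnorm(2L * n_species), n_species, 2L)
  Load <- matrix(c(0.9, 0, 0.5, 0.7, 0.4, -0.6), 3L, 2L, byrow = TRUE)
  Z <- Fm %*% t(Load) + matrix(rnorm(3L * n_species, 0, 0.3),
                               n_species, 3L)
  traits <- data.frame(
    species = tree$tip.label,
    svl_mm = round(80 + 25 * Z[, 1], 1),
    log_clutch = round(4 + 1 * Z[, 2], 3),
    dev_days = round(90 + 30 * Z[, 3], 1))
  if (missing_fraction > 0) {
    cells <- which(matrix(runif(n_species * 3L) < missing_fraction,
                          n_species, 3L), arr.ind = TRUE)
    for (r in seq_len(nrow(cells)))
      traits[cells[r, 1], cells[r, 2] + 1L] <- NA
  }
  list(traits = traits, tree = tree,
       latent = list(factors = Fm, loadings = Load, z = Z,
                     lambda = lambda_true))
}
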