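#' Climate variables tracked by the pipeline
#'
#' Short identifiers for the five annual climate drivers: `afi` (air-freezing
#' index, winter severity), `tmax10` (highest 10-day mean temperature),
#' `swe` (December--April snow-water-equivalent quantile), `spei` (3-month
#' SPEI ending at peak breeding, water availability), and `soil` (mean
#' June 15--August 31 soil moisture).
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' climateVariables()
climateVariables <- function() c("afi", "tmax10", "swe", "spei", "soil")

#' SurveyData: nested detection/non-detection records
#'
#' Holds long-format repeat-visit detection records (study area > site >
#' species > year > visit), per-site metadata, a species table, and (for
#' simulated data) the generating truth.
#'
#' @slot observations data.frame with columns `study_area`, `site`,
#'   `species`, `year`, `visit`, `detected` (0/1).
#' @slot sites data.frame with columns `site`, `study_area`, `habitat`
#'   (wetland/stream/terrestrial), `ecoregion`, `norm_temp_c`,
#'   `norm_precip_mm` (30-year climate normals).
#' @slot species data.frame with columns `species`, `taxon` (Anura/Caudata).
#' @slot truth list of generating values (latent states, realized random
#'   effects, true coefficients) or empty list for real data.
#' @export
setClass("SurveyData", representation(
  observations = "data.frame",
  sites = "data.frame",
  species = "data.frame",
  truth = "list"
))

setValidity("SurveyData", function(object) {
  obs <- object@observations
  msg <- character()
  need <- c("study_area", "site", "species", "year", "visit", "detected")
  if (!all(need %in% names(obs)))
    msg <- c(msg, paste("observations must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (!all(obs$detected %in% c(0L, 1L)))
      msg <- c(msg, "detected must be 0 or 1")
    map <- unique(obs[, c("site", "study_area")])
    if (anyDuplicated(map$site))
      msg <- c(msg, "sites must nest uniquely within study areas")
  }
  sneed <- c("site", "study_area", "habitat", "ecoregion")
  if (!all(sneed %in% names(object@sites)))
    msg <- c(msg, paste("sites must have columns:",
                        paste(sneed, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ClimateAnnual: standardized per-site-per-year climate anomalies
#'
#' Wide table of the five climate drivers per (site, year): raw values,
#' anomalies standardized by the site's 30-year baseline (mean 0, SD 1), and
#' inclusion masks. Masked variables carry `NA` raw/anomaly values, never
#' silent zeros; [designAnomalies()] converts masked anomalies to structural
#' zeros only when assembling a design matrix.
#'
#' @slot data data.frame with columns `site`, `year`, `<var>_raw`,
#'   `<var>_anom` for each of [climateVariables()], and logical masks
#'   `afi_included` (mean baseline AFI > 20), `swe_included`
#'   (mean baseline AFI > 200), `spei_included` (FALSE at terrestrial sites).
#' @slot baselineYears integer vector of baseline (normal-period) years.
#' @export
setClass("ClimateAnnual", representation(
  data = "data.frame",
  baselineYears = "integer"
))

setValidity("ClimateAnnual", function(object) {
  d <- object@data
  msg <- character()
  need <- c("site", "year",
            paste0(climateVariables(), "_raw"),
            paste0(climateVariables(), "_anom"),
            "afi_included", "swe_included", "spei_included")
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(need, names(d)), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' OccupancyDesign: climate main effects and factor interactions
#'
#' Design rows are keyed by (site, species, year); the covariates of a row
#' drive the transition into that year. Columns are the five climate-anomaly
#' mains plus, optionally, interaction columns with ecoregion, habitat,
#' climate normals, taxon, and taxon-specific life-history traits. Group
#' (species-by-study-area) moderator values are retained so that total
#' per-group climate effects can be reassembled from the coefficients.
#'
#' @slot X numeric design matrix, one row per key row.
#' @slot key data.frame with columns `site`, `study_area`, `species`, `year`.
#' @slot terms data.frame describing each column: `column`, `climate`,
#'   `moderator`, `type` (main/interaction), `shrink` (LASSO-penalized).
#' @slot moderators data.frame, one row per (species, study_area), holding
#'   the standardized moderator values entering the interactions plus
#'   group-level inclusion masks per climate variable.
#' @export
setClass("OccupancyDesign", representation(
  X = "matrix",
  key = "data.frame",
  terms = "data.frame",
  moderators = "data.frame"
))

setValidity("OccupancyDesign", function(object) {
  msg <- character()
  if (nrow(object@X) != nrow(object@key))
    msg <- c(msg, "X and key must have the same number of rows")
  if (ncol(object@X) != nrow(object@terms))
    msg <- c(msg, "one terms row per design column required")
  if (length(msg)) msg else TRUE
})

#' OccupancyFit: posterior sample of the dynamic occupancy model
#'
#' @slot draws list with one iterations-by-parameters matrix per chain
#'   (post burn-in, thinned).
#' @slot summary data.frame per parameter: posterior mean, sd, 2.5% and
#'   97.5% quantiles, split-chain Gelman--Rubin statistic.
#' @slot rhat named numeric vector of split-chain Gelman--Rubin statistics.
#' @slot converged logical; TRUE only if all monitored R-hat < 1.05.
#' @slot control list of MCMC settings (see [mcmcControl()]).
#' @slot seed integer seed the sampler was run with.
#' @slot meta list: group table (species-by-study-area), parameter index
#'   maps, design terms.
#' @export
setClass("OccupancyFit", representation(
  draws = "list",
  summary = "data.frame",
  rhat = "numeric",
  converged = "logical",
  control = "list",
  seed = "integer",
  meta = "list"
))

#' SensitivityResult: equilibrium-occupancy sensitivity to climate
#'
#' Per (species, study area, climate variable): relative sensitivity
#' d(psi)/d(X*) of equilibrium occupancy to a 1-SD change in the climate
#' anomaly, with posterior mean and 95% credible interval, the equilibrium
#' occupancy psi*, and the inclusion flag (masked variables are `NA`,
#' not zero).
#'
#' @slot table data.frame: `species`, `study_area`, `variable`, `psi_star`,
#'   `sens_mean`, `sens_lo`, `sens_hi`, `included`.
#' @slot draws list of per-group sensitivity draw matrices (draws x
#'   variables), kept for trend attribution.
#' @export
setClass("SensitivityResult", representation(
  table = "data.frame",
  draws = "list"
))

#' ScenarioResult: assumption-testing simulation grid
#'
#' Sensitivities of 10-year ending occupancy over the 36 colonization-by-
#' persistence baseline scenarios under deterministic-stationary, stochastic,
#' or non-stationary (drifting) dynamics.
#'
#' @slot table data.frame: `scenario_id`, `gamma0`, `phi0`, `mode`,
#'   `variant`, `sens`, `se`.
#' @slot settings list of simulation settings (horizon, perturbation,
#'   replicates, seed).
#' @export
setClass("ScenarioResult", representation(
  table = "data.frame",
  settings = "list"
))
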