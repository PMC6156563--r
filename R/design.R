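## Climate-by-factor design builder for the transition model.

.ECOREGIONS <- c("western montane", "western dry", "northeastern forest",
                 "southeastern forest")

#' Build the climate-by-factor design matrix
#'
#' One row per (site, species, year), in canonical (site, species, year)
#' order; the covariates of a row drive the transition into that year.
#' Columns are the five standardized climate-anomaly mains and, when
#' `interactions = TRUE`, their interactions with ecoregion (reference
#' "other"), habitat (reference wetland), standardized 30-year climate
#' normals (mean annual temperature and precipitation), taxon (reference
#' Anura), and taxon-specific standardized life-history traits (log clutch
#' size, development time, snout--vent length for each of Anura and
#' Caudata). Categorical interactions use treatment coding so a group's
#' climate effect is the main effect plus its interaction terms. Masked
#' climate anomalies enter as structural zeros with the mask recorded on
#' the group moderator table.
#'
#' @param climate a [ClimateAnnual-class] covering every (site, year).
#' @param sites site factor table: `site`, `study_area`, `habitat`,
#'   `ecoregion`, `norm_temp_c`, `norm_precip_mm`.
#' @param species species table: `species`, `taxon`.
#' @param traits complete trait table (`species`, `svl_mm`, `log_clutch`,
#'   `dev_days`); required when `interactions = TRUE` (impute first).
#' @param years years to include (default: all years in `climate`).
#' @param interactions include the factor-interaction columns.
#' @return An [OccupancyDesign-class] object.
#' @export
buildDesign <- function(climate, sites, species, traits = NULL,
                        years = NULL, interactions = TRUE) {
  if (is.null(years)) years <- sort(unique(climateTable(climate)$year))
  key <- expand.grid(site = sites$site, species = species$species,
                     year = as.integer(years), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  key <- key[order(key$site, key$species, key$year), ]
  rownames(key) <- NULL
  key$study_area <- sites$study_area[match(key$site, sites$site)]
  key <- key[, c("site", "study_area", "species", "year")]
  A <- designAnomalies(climate, key$site, key$year)
  vars <- climateVariables()
  cols <- list()
  terms <- list()
  addCol <- function(name, values, climate_var, moderator, type, shrink) {
    cols[[length(cols) + 1L]] <<- values
    terms[[length(terms) + 1L]] <<- data.frame(
      column = name, climate = climate_var, moderator = moderator,
      type = type, shrink = shrink)
    names(cols)[length(cols)] <<- name
  }
  for (v in vars) addCol(v, A[, v], v, "", "main", FALSE)
  modNames <- character(0)
  M <- NULL
  if (interactions) {
    si <- match(key$site, sites$site)
    if (anyNA(sites$habitat[unique(si)]))
      stop("habitat missing for sites: ",
           paste(sites$site[is.na(sites$habitat)], collapse = ", "))
    ki <- match(key$species, species$species)
    if (is.null(traits))
      stop("traits are required when interactions = TRUE")
    tmiss <- traits$species[!complete.cases(
      traits[, c("svl_mm", "log_clutch", "dev_days")])]
    if (length(tmiss))
      stop("missing trait values for species (impute first): ",
           paste(tmiss, collapse = ", "))
    zcol <- function(x) {
      s <- sd(x)
      if (!is.finite(s) || s < 1e-12) rep(0, length(x)) else
        (x - mean(x)) / s
    }
    ntz <- zcol(sites$norm_temp_c)[si]
    npz <- zcol(sites$norm_precip_mm)[si]
    ti <- match(key$species, traits$species)
    if (anyNA(ti))
      stop("species missing from trait table: ",
           paste(unique(key$species[is.na(ti)]), collapse = ", "))
    svlz <- zcol(traits$svl_mm)[ti]
    cluz <- zcol(traits$log_clutch)[ti]
    devz <- zcol(traits$dev_days)[ti]
    isCau <- as.numeric(species$taxon[ki] == "Caudata")
    isAnu <- 1 - isCau
    mods <- list()
    for (e in .ECOREGIONS)
      mods[[paste0("eco:", e)]] <-
        as.numeric(sites$ecoregion[si] == e)
    mods[["hab:stream"]] <- as.numeric(sites$habitat[si] == "stream")
    mods[["hab:terrestrial"]] <-
      as.numeric(sites$habitat[si] == "terrestrial")
    mods[["norm_temp"]] <- ntz
    mods[["norm_precip"]] <- npz
    mods[["taxon:Caudata"]] <- isCau
    mods[["Anura:clutch"]] <- isAnu * cluz
    mods[["Anura:dev"]] <- isAnu * devz
    mods[["Anura:svl"]] <- isAnu * svlz
    mods[["Caudata:clutch"]] <- isCau * cluz
    mods[["Caudata:dev"]] <- isCau * devz
    mods[["Caudata:svl"]] <- isCau * svlz
    modNames <- names(mods)
    M <- do.call(cbind, mods)
    for (v in vars)
      for (m in modNames)
        addCol(paste0(v, "|", m), A[, v] * M[, colnames(M) == m],
               v, m, "interaction", TRUE)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  ## group-level moderator summary for sensitivity assembly
  grp <- unique(key[, c("species", "study_area")])
  grp <- grp[order(grp$species, grp$study_area), ]
  rownames(grp) <- NULL
  inc <- attr(A, "included")
  if (interactions) {
    gm <- matrix(0, nrow(grp), length(modNames),
                 dimnames = list(NULL, modNames))
    for (g in seq_len(nrow(grp))) {
      rows <- key$species == grp$species[g] &
        key$study_area == grp$study_area[g]
      gm[g, ] <- colMeans(M[rows, , drop = FALSE])
    }
    grp <- cbind(grp, as.data.frame(gm, check.names = FALSE))
  }
  for (v in vars) {
    grp[[paste0("included_", v)]] <- vapply(seq_len(nrow(grp)), function(g) {
      rows <- key$species == grp$species[g] &
        key$study_area == grp$study_area[g]
      mean(inc[rows, v]) > 0.5
    }, logical(1))
  }
  new("OccupancyDesign", X = X, key = key,
      terms = do.call(rbind, terms), moderators = grp)
}

#' Total per-group climate effect from a coefficient vector
#'
#' Assembles the group-specific (species-by-study-area) total logit-scale
#' effect of each climate variable: the main effect plus the group's
#' interaction terms weighted by its moderator values (categorical group
#' effects are recovered as main + interaction, matching the treatment
#' coding).
#'
#' @param beta named coefficient vector indexed like the design columns.
#' @param design the [OccupancyDesign-class] the coefficients belong to.
#' @return Matrix (groups x 5 climate variables); rows follow
#'   `design@moderators`.
#' @export
groupClimateEffects <- function(beta, design) {
  terms <- design@terms
  grp <- design@moderators
  vars <- climateVariables()
  out <- matrix(0, nrow(grp), length(vars),
                dimnames = list(NULL, vars))
  for (v in vars) {
    main <- terms$column[terms$climate == v & terms$type == "main"]
    tot <- rep(beta[main], nrow(grp))
    it <- terms[terms$climate == v & terms$type == "interaction", ]
    if (nrow(it))
      tot <- tot + as.matrix(grp[, it$moderator, drop = FALSE]) %*%
        beta[it$column]
    out[, v] <- tot
  }
  out
}
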