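## Phylogenetic latent-factor imputation of life-history traits.

#' Scaled patristic distances from a phylogeny
#'
#' Pairwise patristic (branch-length path sum) distances scaled to \[0, 1\]
#' by the maximum pair.
#'
#' @param tree an `ape` phylo object, or a path to a newick file.
#' @param species optional species names to order/subset by; an error names
#'   any species absent from the tree.
#' @return Symmetric matrix with zero diagonal and maximum entry 1.
#' @export
phyloDistances <- function(tree, species = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  D <- ape::cophenetic.phylo(tree)
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(D))
    if (length(missing))
      stop("species absent from tree: ", paste(missing, collapse = ", "))
    D <- D[species, species, drop = FALSE]
  }
  mx <- max(D)
  if (mx <= 0) stop("tree has no positive branch lengths")
  D / mx
}

#' Phylogenetic trait covariance
#'
#' Unit-diagonal species covariance controlled by the signal parameter
#' lambda: off-diagonal entries are `lambda * (1 - scaled distance)`, so
#' close relatives are the most correlated, consistent with Brownian trait
#' evolution; `lambda = 0` gives the identity. `literal = TRUE` instead uses
#' `lambda * scaled distance` (distant species more correlated), provided
#' for comparison only.
#'
#' @param D scaled distance matrix from [phyloDistances()].
#' @param lambda signal strength in \[0, 1\].
#' @param literal use the distance-proportional (inverted) form.
#' @return Covariance matrix with unit diagonal.
#' @export
phyloCovariance <- function(D, lambda, literal = FALSE) {
  C <- if (literal) lambda * D else lambda * (1 - D)
  diag(C) <- 1
  C
}

#' Fit the phylogenetic latent-factor trait model
#'
#' Standardized traits (snout--vent length, log clutch size, development
#' time) are modeled as linear combinations of two latent factors observed
#' with Gaussian error. Each factor is mean-zero multivariate normal across
#' species with covariance [phyloCovariance()] at a jointly estimated (or
#' fixed) lambda; the 3x2 loading matrix is lower triangular with positive
#' diagonal for identifiability. Sampling is Gibbs for factors, loadings,
#' error variances and missing trait cells, Metropolis for lambda.
#'
#' @param traits data.frame: `species`, `svl_mm`, `log_clutch`, `dev_days`
#'   with `NA` for missing cells; at least 2 traits observed for >= 3
#'   species.
#' @param tree phylo object (or newick path) containing all species.
#' @param n_iter,n_burn iterations kept / discarded.
#' @param fix_lambda optional value to hold lambda at.
#' @param literal_covariance see [phyloCovariance()].
#' @param seed RNG seed.
#' @return An object of class `traitFactorFit`: draws of `lambda`,
#'   loadings, error SDs, predictions for missing cells, log-posterior
#'   trace and the index of the highest-posterior draw.
#' @export
fitTraitFactorModel <- function(traits, tree, n_iter = 1500L,
                                n_burn = 500L, fix_lambda = NULL,
                                literal_covariance = FALSE, seed = 1L) {
  Y0 <- as.matrix(traits[, c("svl_mm", "log_clutch", "dev_days")])
  K <- nrow(Y0)
  obs <- !is.na(Y0)
  if (all(!obs)) stop("all traits missing for every species")
  if (sum(rowSums(obs) >= 2) < 3L)
    stop("need at least 2 observed traits for at least 3 species")
  D <- phyloDistances(tree, species = traits$species)
  ctr <- colMeans(Y0, na.rm = TRUE)
  scl <- apply(Y0, 2, sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Y <- sweep(sweep(Y0, 2, ctr), 2, scl, "/")
  miss <- which(!obs, arr.ind = TRUE)
  Y[!obs] <- 0
  set.seed(seed + 5L)
  nf <- 2L
  Fm <- matrix(rnorm(K * nf, 0, 0.5), K, nf)
  Load <- matrix(c(1, 0, 0.5, 1, 0.5, 0.5), 3L, nf, byrow = TRUE)
  sig2 <- rep(0.5, 3L)
  lam <- if (is.null(fix_lambda)) 0.5 else fix_lambda
  lamStep <- 0.8
  freeIdx <- list(1L, c(1L, 2L), c(1L, 2L))  # factors loading each trait
  chol_Sig <- function(l) chol(phyloCovariance(D, l, literal_covariance) +
                                 diag(1e-8, K))
  Rchol <- chol_Sig(lam)
  factorPriorLL <- function(Fmat, R) {
    # sum over factors of MVN(0, Sigma) log density
    z <- backsolve(R, Fmat, transpose = TRUE)
    -sum(z^2) / 2 - nf * sum(log(diag(R))) - nf * K * log(2 * pi) / 2
  }
  nm <- nrow(miss)
  draws <- list(lambda = numeric(n_iter),
                load = array(NA_real_, c(n_iter, 3L, nf)),
                sigma = matrix(NA_real_, n_iter, 3L),
                pred = matrix(NA_real_, n_iter, max(nm, 1L)),
                logpost = numeric(n_iter))
  total <- n_burn + n_iter
  for (it in seq_len(total)) {
    ## augment missing cells
    if (nm) {
      mu <- Fm %*% t(Load)
      Y[miss] <- mu[miss] + rnorm(nm, 0, sqrt(sig2[miss[, 2]]))
    }
    ## factors: joint Gaussian over vec(F), factor-major ordering
    Sinv <- chol2inv(Rchol)
    A <- t(Load) %*% (Load / sig2)        # nf x nf, shared across species
    P <- kronecker(diag(nf), Sinv) + kronecker(A, diag(K))
    B <- (Y / matrix(sig2, K, 3L, byrow = TRUE)) %*% Load  # K x nf
    Rp <- chol(P)
    mean_v <- backsolve(Rp, backsolve(Rp, as.vector(B), transpose = TRUE))
    Fv <- mean_v + backsolve(Rp, rnorm(K * nf))
    Fm <- matrix(Fv, K, nf)
    ## loadings: conjugate regression per trait on its free factors
    for (j in 1:3) {
      fi <- freeIdx[[j]]
      Xf <- Fm[, fi, drop = FALSE]
      Pj <- crossprod(Xf) / sig2[j] + diag(length(fi))
      bj <- crossprod(Xf, Y[, j]) / sig2[j]
      Rj <- chol(Pj)
      mj <- backsolve(Rj, backsolve(Rj, bj, transpose = TRUE))
      lj <- mj + backsolve(Rj, rnorm(length(fi)))
      Load[j, ] <- 0
      Load[j, fi] <- lj
    }
    ## sign constraint: positive diagonal
    for (f in seq_len(nf)) {
      if (Load[f, f] < 0) {
        Load[, f] <- -Load[, f]
        Fm[, f] <- -Fm[, f]
      }
    }
    ## error variances
    res <- Y - Fm %*% t(Load)
    for (j in 1:3)
      sig2[j] <- 1 / rgamma(1, 2 + K / 2, 0.5 + sum(res[, j]^2) / 2)
    ## lambda
    if (is.null(fix_lambda)) {
      prop <- plogis(qlogis(pmin(pmax(lam, 1e-6), 1 - 1e-6)) +
                       rnorm(1, 0, lamStep))
      Rprop <- tryCatch(chol_Sig(prop), error = function(e) NULL)
      if (!is.null(Rprop)) {
        # uniform prior on lambda; include logit-transform jacobian
        cur <- factorPriorLL(Fm, Rchol) +
          log(lam * (1 - lam) + 1e-12)
        new <- factorPriorLL(Fm, Rprop) +
          log(prop * (1 - prop) + 1e-12)
        if (log(runif(1)) < new - cur) {
          lam <- prop
          Rchol <- Rprop
        }
      }
    }
    if (it > n_burn) {
      k <- it - n_burn
      draws$lambda[k] <- lam
      draws$load[k, , ] <- Load
      draws$sigma[k, ] <- sqrt(sig2)
      mu <- Fm %*% t(Load)
      if (nm) draws$pred[k, seq_len(nm)] <- mu[miss]
      lp <- factorPriorLL(Fm, Rchol) +
        sum(dnorm(Y[obs], mu[obs], sqrt(sig2[col(Y)[obs]]), log = TRUE)) +
        sum(dnorm(Load[cbind(rep(1:3, lengths(freeIdx)),
                             unlist(freeIdx))], 0, 1, log = TRUE)) +
        sum(-3 * log(sig2) - 0.5 / sig2)
      draws$logpost[k] <- lp
    }
  }
  structure(list(draws = draws, best = which.max(draws$logpost),
                 miss = miss, center = ctr, scale = scl,
                 species = traits$species,
                 lambda_median = median(draws$lambda)),
            class = "traitFactorFit")
}

#' Impute missing traits from a fitted factor model
#'
#' Missing cells are replaced by the model's predicted (fitted-mean) values
#' at the highest-log-posterior draw, back-transformed to natural units;
#' observed cells are untouched.
#'
#' @param fit a `traitFactorFit` from [fitTraitFactorModel()].
#' @param traits the trait table the model was fitted to.
#' @return Completed trait data.frame.
#' @export
imputeTraits <- function(fit, traits) {
  out <- traits
  miss <- fit$miss
  if (!nrow(miss)) return(out)
  predz <- fit$draws$pred[fit$best, seq_len(nrow(miss))]
  vals <- predz * fit$scale[miss[, 2]] + fit$center[miss[, 2]]
  cols <- c("svl_mm", "log_clutch", "dev_days")
  for (r in seq_len(nrow(miss)))
    out[miss[r, 1], cols[miss[r, 2]]] <- vals[r]
  out
}
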