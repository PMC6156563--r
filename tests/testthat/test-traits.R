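test_that("patristic distances scale correctly on known trees", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  D2 <- phyloDistances(t2)
  expect_equal(unname(diag(D2)), c(0, 0))
  expect_equal(unname(D2["A", "B"]), 1)
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D3 <- phyloDistances(t3)
  # raw path sums 2, 4, 4 scale to 0.5, 1, 1
  expect_equal(unname(D3["A", "B"]), 0.5)
  expect_equal(unname(D3["A", "C"]), 1)
  expect_equal(unname(D3["B", "C"]), 1)
  expect_error(phyloDistances(t3, species = c("A", "Z")), "Z")
})

test_that("phylogenetic covariance honours the lambda limits", {
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- phyloDistances(t3)
  expect_equal(phyloCovariance(D, 0), diag(3), ignore_attr = TRUE)
  C1 <- phyloCovariance(D, 1)
  expect_equal(unname(C1["A", "B"]), 0.5)  # close pair most correlated
  expect_equal(unname(C1["A", "C"]), 0)
  expect_true(all(eigen(C1, only.values = TRUE)$values > -1e-10))
  # the literal (inverted) reading is available but not the default
  Cl <- phyloCovariance(D, 1, literal = TRUE)
  expect_equal(unname(Cl["A", "C"]), 1)
})

test_that("duplicated traits load on a shared factor with equal loadings", {
  set.seed(501)
  n <- 24
  tree <- ape::rcoal(n, tip.label = sprintf("sp%02d", 1:n))
  base <- rnorm(n)
  tr <- data.frame(species = tree$tip.label,
                   svl_mm = 50 + 10 * base,
                   log_clutch = 3 + 2 * base,   # same signal, rescaled
                   dev_days = 80 + 15 * rnorm(n))
  fit <- fitTraitFactorModel(tr, tree, n_iter = 600, n_burn = 300,
                             seed = 2)
  l1 <- mean(fit$draws$load[, 1, 1])
  l2 <- mean(fit$draws$load[, 2, 1])
  expect_equal(l2 / l1, 1, tolerance = 0.2)
  expect_gt(l1, 0)  # sign-aligned by the positive-diagonal constraint
})

test_that("the factor model fit is reproducible and validates inputs", {
  g <- simulateTraitsPhylo(10, missing_fraction = 0.2, seed = 3)
  f1 <- fitTraitFactorModel(g$traits, g$tree, n_iter = 100, n_burn = 50,
                            seed = 9)
  f2 <- fitTraitFactorModel(g$traits, g$tree, n_iter = 100, n_burn = 50,
                            seed = 9)
  expect_identical(f1$draws$lambda, f2$draws$lambda)
  allNA <- g$traits
  allNA[, c("svl_mm", "log_clutch", "dev_days")] <- NA
  expect_error(fitTraitFactorModel(allNA, g$tree), "missing")
})

test_that("lambda is recovered low when traits carry no phylogenetic signal", {
  hits <- vapply(1:10, function(r) {
    g <- simulateTraitsPhylo(20, missing_fraction = 0,
                             lambda_true = 0, seed = 600 + r)
    fit <- fitTraitFactorModel(g$traits, g$tree, n_iter = 500,
                               n_burn = 250, seed = r)
    median(fit$draws$lambda) < 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("imputation leaves observed cells alone and uses relatives", {
  g <- simulateTraitsPhylo(12, missing_fraction = 0, seed = 11)
  fit <- fitTraitFactorModel(g$traits, g$tree, n_iter = 200, n_burn = 100,
                             seed = 4)
  expect_identical(imputeTraits(fit, g$traits), g$traits)
  # full phylogenetic signal with a sister pair at near-zero distance and
  # low trait observation error: the imputed value should land nearer the
  # sister's value than the grand mean does
  hits <- vapply(1:12, function(r) {
    set.seed(900 + r)
    tree <- ape::rcoal(12, tip.label = sprintf("sp%02d", 1:12))
    D0 <- ape::cophenetic.phylo(tree); diag(D0) <- Inf
    pair <- rownames(D0)[which(D0 == min(D0), arr.ind = TRUE)[1, ]]
    tipE <- match(match(pair, tree$tip.label), tree$edge[, 2])
    tree$edge.length[tipE] <- 1e-8    # collapse the cherry
    D <- phyloDistances(tree)
    C <- phyloCovariance(D, 1)
    L <- chol(C + diag(1e-8, 12))
    Fm <- t(L) %*% matrix(rnorm(24), 12, 2)
    Load <- matrix(c(0.9, 0, 0.5, 0.7, 0.4, -0.6), 3, 2, byrow = TRUE)
    Z <- Fm %*% t(Load) + matrix(rnorm(36, 0, 0.15), 12, 3)
    tr <- data.frame(species = tree$tip.label, svl_mm = 80 + 25 * Z[, 1],
                     log_clutch = 4 + Z[, 2], dev_days = 90 + 30 * Z[, 3])
    i1 <- match(pair[1], tr$species); i2 <- match(pair[2], tr$species)
    tr$svl_mm[i1] <- NA
    fit <- fitTraitFactorModel(tr, tree, n_iter = 500, n_burn = 250,
                               seed = r)
    imp <- imputeTraits(fit, tr)$svl_mm[i1]
    gm <- mean(tr$svl_mm, na.rm = TRUE)
    sister <- tr$svl_mm[i2]
    abs(imp - sister) < abs(gm - sister)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the true phylogeny imputes better than a permuted one", {
  set.seed(502)
  rmse <- vapply(1:6, function(r) {
    g <- simulateTraitsPhylo(20, missing_fraction = 0, lambda_true = 1,
                             seed = 800 + r)
    tr <- g$traits
    cells <- which(matrix(runif(20 * 3) < 0.1, 20, 3), arr.ind = TRUE)
    if (!nrow(cells)) return(c(0, 0))
    truthVals <- mapply(function(i, j) tr[i, j + 1L],
                        cells[, 1], cells[, 2])
    trNA <- tr
    for (k in seq_len(nrow(cells))) trNA[cells[k, 1], cells[k, 2] + 1L] <- NA
    perm <- g$tree
    perm$tip.label <- sample(perm$tip.label)
    err <- vapply(list(g$tree, perm), function(tw) {
      fit <- fitTraitFactorModel(trNA, tw, n_iter = 400, n_burn = 200,
                                 seed = r)
      imp <- imputeTraits(fit, trNA)
      impVals <- mapply(function(i, j) imp[i, j + 1L],
                        cells[, 1], cells[, 2])
      # standardize per trait so traits pool on one scale
      scl <- apply(tr[, -1], 2, sd)
      sqrt(mean(((impVals - truthVals) / scl[cells[, 2]])^2))
    }, numeric(1))
    err
  }, numeric(2))
  expect_lt(mean(rmse[1, ]), mean(rmse[2, ]))
})

test_that("imputed tables satisfy the design builder's contract", {
  g <- simulateTraitsPhylo(8, missing_fraction = 0.1, seed = 21)
  expect_true(anyNA(g$traits))
  fit <- fitTraitFactorModel(g$traits, g$tree, n_iter = 150, n_burn = 100,
                             seed = 5)
  done <- imputeTraits(fit, g$traits)
  expect_false(anyNA(done))
  sites <- simulateSiteTable(1, 5, 21)
  species <- data.frame(species = sort(g$traits$species),
                        taxon = rep(c("Anura", "Caudata"), 4))
  climate <- simulateAnomalies(sites$site, 1:3, 21)
  expect_s4_class(buildDesign(climate, sites, species, done),
                  "OccupancyDesign")
})
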