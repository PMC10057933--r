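test_that("Mann-Whitney U handles symmetry and complete separation", {
  res <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p, 1)
  sep <- mannWhitneyU(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$estimates$U_A, 0)
  expect_equal(sep$estimates$U_B, 9)
})

test_that("the exact Mann-Whitney branch matches enumeration oracles", {
  # tie-free case: cross-check against wilcox.test's exact distribution
  withr::with_seed(21, {
    for (i in 1:10) {
      a <- rnorm(6)
      b <- rnorm(6) + 0.5
      got <- mannWhitneyU(a, b)
      ref <- wilcox.test(a, b, exact = TRUE)
      expect_equal(got$p, ref$p.value, tolerance = 1e-12)
      expect_equal(got$estimates$U_A, unname(ref$statistic))
    }
  })
  # with ties: independent enumeration over assignments of pooled data
  a <- c(1, 2, 2)
  b <- c(2, 3, 4)
  got <- mannWhitneyU(a, b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  combs <- combn(6, 3)
  Us <- colSums(matrix(rk[combs], nrow = 3)) - 6
  U1 <- sum(rk[1:3]) - 6
  expect_equal(got$p, mean(abs(Us - 4.5) >= abs(U1 - 4.5)))
})

test_that("large samples switch to the normal approximation", {
  withr::with_seed(3, {
    a <- rnorm(30)
    b <- rnorm(35) + 0.4
  })
  got <- mannWhitneyU(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_identical(got$details$method, "normal approximation")
  expect_error(mannWhitneyU(numeric(0), b), "non-empty")
})

test_that("interaction model reports matching standardized coefficients", {
  tab <- simulatePropertyTable(300, seed = 5)
  res <- fitInteractionGLM(tab, "gamma", "<70")
  est <- res$estimates
  expect_setequal(est$term,
                  c("(Intercept)", "age", "sexF", "age_x_sexF",
                    "n_nodes", "scanner"))
  # pre-z-scored response and predictors: unstandardized == standardized
  sub <- tab[tab$age < 70, ]
  z <- function(x) (x - mean(x)) / sd(x)
  tab2 <- data.frame(id = sub$id,
                     age = z(sub$age),
                     sex = sub$sex, scanner = sub$scanner,
                     n_nodes = z(sub$n_nodes), gamma = z(sub$gamma))
  res2 <- fitInteractionGLM(tab2, "gamma", "all")
  e2 <- res2$estimates
  noInt <- e2$term %in% c("age", "n_nodes")
  expect_equal(e2$beta[noInt], e2$beta_std[noInt], tolerance = 1e-10)
})

test_that("a known negative late-life female slope is recovered", {
  hits <- vapply(1:30, function(s) {
    tab <- simulatePropertyTable(150, seed = 4000 + s,
                                 ageRange = c(70, 85.1),
                                 gammaInteraction = -0.008)
    res <- fitInteractionGLM(tab, "gamma", ">=70")
    res$estimates$beta[res$estimates$term == "age_x_sexF"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rank-deficient designs fail naming the collinear column", {
  tab <- simulatePropertyTable(100, seed = 6)
  tab$scanner <- "scannerA"                # constant column
  expect_error(fitInteractionGLM(tab, "gamma", "all"), "scanner")
  expect_error(ancovaSexContrast(tab, "gamma", "all"), "scanner")
  tab2 <- simulatePropertyTable(50, seed = 7)
  expect_error(fitInteractionGLM(tab2[tab2$sex == "F", ], "gamma", "all"),
               "both sexes")
  expect_error(fitInteractionGLM(tab2, "gamma", "<70", splitAge = 0),
               "empty")
})

test_that("ANCOVA recovers an injected additive sex offset", {
  delta <- 0.06
  ok <- vapply(1:30, function(s) {
    tab <- simulatePropertyTable(200, seed = 900 + s, gammaSexOffset = delta,
                                 gammaInteraction = 0, changepoint = NA)
    res <- ancovaSexContrast(tab, "gamma", "all")
    e <- res$estimates
    diffFM <- e$adjusted_mean[e$sex == "F"] - e$adjusted_mean[e$sex == "M"]
    se <- sqrt(sum(e$se^2))
    abs(diffFM - delta) < 2 * se
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("ANCOVA is well behaved for constant responses", {
  tab <- simulatePropertyTable(60, seed = 8)
  tab$gamma <- 1.7
  res <- suppressWarnings(ancovaSexContrast(tab, "gamma", "all"))
  expect_equal(res$estimates$adjusted_mean, c(1.7, 1.7), tolerance = 1e-12)
  expect_lt(max(res$estimates$se), 1e-10)
})

test_that("partial correlation reduces to Pearson without covariates", {
  withr::with_seed(9, {
    x <- rnorm(50)
    y <- 0.5 * x + rnorm(50)
  })
  res <- partialCorrelation(x, y)
  expect_identical(res$estimates$r, cor(x, y))
  ref <- cor.test(x, y)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("partial correlation matches the residual-regression oracle", {
  withr::with_seed(10, {
    for (i in 1:10) {
      n <- 40
      Z <- data.frame(a = rnorm(n), b = runif(n))
      x <- rnorm(n) + Z$a
      y <- rnorm(n) - 0.5 * Z$a + 0.3 * Z$b
      got <- partialCorrelation(x, y, Z)
      expect_equal(got$estimates$r, as.numeric(oraclePartialCor(x, y, Z)),
                   tolerance = 1e-10)
    }
  })
})

test_that("partialling out a perfect covariate relation zeroes r", {
  withr::with_seed(11, {
    Z <- data.frame(a = rnorm(5000), b = rnorm(5000))
    x <- rnorm(5000)
    y <- 2 * Z$a - Z$b            # y is exactly linear in the covariates
  })
  expect_warning(res <- partialCorrelation(x, y, Z), "constant")
  expect_true(is.na(res$estimates$r))
  y2 <- y + rnorm(5000, sd = 1e-3)
  res2 <- partialCorrelation(x, y2, Z)
  expect_lt(abs(res2$estimates$r), 0.05)
})

test_that("equal dependent correlations give Z = 0 and p = 1", {
  res <- compareDependentCorrelations(0.4, 0.4, 0.5, n = 100)
  expect_equal(res$estimates$Z, 0)
  expect_equal(res$p, 1)
})

test_that("|Z| grows with the gap between the compared correlations", {
  gaps <- seq(0, 0.4, by = 0.1)
  zs <- vapply(gaps, function(g)
    abs(compareDependentCorrelations(0.3, 0.3 + g, 0.5,
                                     n = 150)$estimates$Z),
    numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_error(compareDependentCorrelations(1, 0.5, 0.5, 100), "strictly")
  expect_error(compareDependentCorrelations(0.3, 0.4, 0.5, 5), "n >= 10")
})

test_that("both dependent-correlation variants are near-nominal (quick)", {
  # trivariate normal null: rho_jk = rho_jh = 0.4, rho_kh = 0.5
  R <- matrix(c(1, .4, .4, .4, 1, .5, .4, .5, 1), 3)
  L <- chol(R)
  nrep <- 1500
  n <- 100
  rej <- withr::with_seed(12, {
    vapply(seq_len(nrep), function(i) {
      X <- matrix(rnorm(n * 3), n) %*% L
      cs <- cor(X)
      c(compareDependentCorrelations(cs[1, 2], cs[1, 3], cs[2, 3], n)$p,
        compareDependentCorrelations(cs[1, 2], cs[1, 3], cs[2, 3], n,
                                     method = "steiger")$p)
    }, numeric(2))
  })
  expect_lt(abs(mean(rej[1, ] < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(rej[2, ] < 0.05) - 0.05), 0.02)
})

test_that("GAM trajectories recover a linear trend and flat lines", {
  tab <- simulatePropertyTable(400, seed = 13, gammaSD = 0.02,
                               gammaInteraction = 0, changepoint = NA)
  tr <- fitAgeTrajectory(tab, "gamma")
  expect_setequal(unique(tr$sex), c("F", "M"))
  trueLine <- function(a, f) 1.85 - 0.0035 * (a - 25) + 0.026 * f
  for (g in c("F", "M")) {
    sub <- tr[tr$sex == g, ]
    inside <- mean(trueLine(sub$age, g == "F") >= sub$lower &
                     trueLine(sub$age, g == "F") <= sub$upper)
    expect_gt(inside, 0.9)
  }
  tab$gamma <- 1.5
  flat <- fitAgeTrajectory(tab, "gamma", bySex = FALSE)
  expect_lt(max(flat$fit) - min(flat$fit), 1e-6)
  expect_error(fitAgeTrajectory(tab[1:15, ], "gamma"), ">= 20")
})

test_that("the full analysis emits the four table analogues", {
  tab <- simulatePropertyTable(250, seed = 14)
  res <- runFullAnalysis(tab)
  expect_named(res, c("demographics", "interactions", "sexContrasts",
                      "correlations", "manifest"))
  expect_setequal(unique(res$interactions$property),
                  c("gamma", "lambda", "sigma"))
  expect_setequal(unique(res$correlations$stratum), c("<70", ">=70"))
  # alphas follow the Bonferroni conventions
  expect_equal(unique(res$demographics$alpha[
    res$demographics$variable %in% c("gamma", "lambda", "sigma")]),
    0.05 / 3)
  expect_equal(unique(res$demographics$alpha[
    res$demographics$variable == "age"]), 0.05)
  expect_equal(unique(res$correlations$alpha), 0.05 / 2)
  expect_error(runFullAnalysis(tab[, setdiff(names(tab), "gamma")]),
               "missing column")
})

test_that("the analysis runs chronological-only when brain age is absent", {
  tab <- simulatePropertyTable(150, seed = 15)
  tab$predicted_age <- NULL
  tab$brain_pad <- NULL
  expect_warning(res <- runFullAnalysis(tab), "chronological")
  expect_true(all(is.na(res$correlations$r_brain)))
  expect_false(anyNA(res$correlations$r_chron))
})

test_that("the stratum boundary age belongs to the upper stratum", {
  tab <- simulatePropertyTable(200, seed = 16)
  tab$age[1] <- 70
  sub <- sgmnet:::subsetStratum(tab, ">=70", 70)
  expect_true(tab$id[1] %in% sub$id)
  sub2 <- sgmnet:::subsetStratum(tab, "<70", 70)
  expect_false(tab$id[1] %in% sub2$id)
})
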