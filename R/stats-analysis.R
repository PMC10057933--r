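# Statistical stage: group comparisons, age-by-sex interaction models in
# age strata, covariate-adjusted sex contrasts, partial correlations,
# dependent-correlation comparison, GAM age trajectories, and the
# orchestrated full analysis.
#
# Bonferroni conventions: alpha 0.05 for demographics, 0.05/3 for the
# three network properties, 0.05/2 for the two (chronological, brain)
# age correlations per property.

statResult <- function(test, estimates, p, alphaUsed, covariates = character(),
                       details = list()) {
  structure(list(test = test, estimates = estimates, p = p,
                 alphaUsed = alphaUsed, covariates = covariates,
                 details = details),
            class = "sgmStatResult")
}

#' @export
#' @noRd
print.sgmStatResult <- function(x, ...) {
  cat(sprintf("%s\n", x$test))
  if (is.data.frame(x$estimates)) print(x$estimates, digits = 4)
  else print(unlist(x$estimates), digits = 4)
  cat(sprintf("p = %.4g (alpha = %.4g)\n", x$p, x$alphaUsed))
  if (length(x$covariates))
    cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

# ---- Mann-Whitney U ----------------------------------------------------

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with tie handling. For combined sample sizes
#' up to \code{exactMax} (default 12) the p-value is computed by exact
#' enumeration of all group assignments of the pooled ranks (valid under
#' ties, where the classical exact distribution is not); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. Extremeness in the exact branch is measured by the distance of
#' U from its null expectation.
#'
#' @param groupA,groupB numeric vectors (non-empty).
#' @param alpha significance level to report alongside p (default 0.05;
#'   pass 0.05/3 for the Bonferroni-corrected network-property
#'   comparisons).
#' @param exactMax switch point for exact enumeration.
#' @return an \code{sgmStatResult} with U statistics for both groups.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(10, 11, 12))
#' @export
mannWhitneyU <- function(groupA, groupB, alpha = 0.05, exactMax = 12) {
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  n1 <- length(groupA); n2 <- length(groupB)
  pooled <- c(groupA, groupB)
  rk <- rank(pooled)
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  EU <- n1 * n2 / 2
  if (n1 + n2 <= exactMax) {
    combs <- combn(n1 + n2, n1)
    Us <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - EU) >= abs(U1 - EU) - 1e-9)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(groupA, groupB, exact = FALSE,
                         correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  statResult(
    "Mann-Whitney U test (two-sided)",
    data.frame(U_A = U1, U_B = U2, n_A = n1, n_B = n2),
    p = p, alphaUsed = alpha, details = list(method = method))
}

# ---- Interaction GLM ---------------------------------------------------

subsetStratum <- function(table, stratum, splitAge) {
  stratum <- match.arg(stratum, c("<70", ">=70", "all"))
  if (stratum == "<70") table[table$age < splitAge, , drop = FALSE]
  else if (stratum == ">=70") table[table$age >= splitAge, , drop = FALSE]
  else table
}

checkFullRank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
}

# fit y ~ design (data.frame of numeric columns) and return the coef table
lmCoefTable <- function(y, design) {
  d <- data.frame(y = y, design)
  fit <- lm(y ~ ., data = d)
  s <- summary(fit)$coefficients
  fit$coefTable <- s
  fit
}

#' Age-by-sex interaction model for a network property
#'
#' Within one age stratum (ages below, or at and above, the split age;
#' the boundary age belongs to the upper stratum), fits the linear model
#' \code{response ~ age + sex + age:sex + n_nodes + scanner} (Gaussian
#' family, identity link) and reports per term the unstandardized
#' coefficient, its standard error, the standardized coefficient
#' (obtained by refitting with every variable — response, predictors and
#' the interaction product — z-scored) and the p-value. When the
#' interaction is not significant at 0.05 the main-effects model
#' \code{response ~ age + sex + n_nodes + scanner} is additionally fitted
#' and reported, to test the main effects of age and sex.
#'
#' @param table subject table with columns age, sex ("F"/"M"), scanner,
#'   n_nodes and the response.
#' @param response column name of the property (e.g. "gamma").
#' @param stratum \code{"<70"}, \code{">=70"} or \code{"all"}.
#' @param splitAge stratification age, years (default 70).
#' @param alpha reported alongside p (default 0.05/3, the Bonferroni
#'   level for three network properties).
#' @return an \code{sgmStatResult}; \code{estimates} holds the
#'   interaction-model coefficient table, \code{details$mainEffects} the
#'   main-effects table (NULL when the interaction was significant), and
#'   \code{details$interactionP} the interaction p-value.
#' @export
fitInteractionGLM <- function(table, response, stratum = "all",
                              splitAge = 70, alpha = 0.05 / 3) {
  sub <- subsetStratum(table, stratum, splitAge)
  if (!nrow(sub)) stop("stratum is empty")
  if (length(unique(sub$sex)) < 2)
    stop("both sexes must be present in the stratum")
  y <- sub[[response]]
  if (is.null(y)) stop("unknown response column: ", response)
  design <- data.frame(
    age = sub$age,
    sexF = as.numeric(sub$sex == "F"),
    age_x_sexF = sub$age * as.numeric(sub$sex == "F"),
    n_nodes = as.numeric(sub$n_nodes),
    scanner = as.numeric(factor(sub$scanner)) - 1
  )
  checkFullRank(cbind(`(Intercept)` = 1, as.matrix(design)))
  fit <- lmCoefTable(y, design)
  zdesign <- as.data.frame(lapply(design, zscore))
  zfit <- lmCoefTable(zscore(y), zdesign)
  terms <- rownames(fit$coefTable)
  tab <- data.frame(
    term = terms,
    beta = fit$coefTable[, "Estimate"],
    se = fit$coefTable[, "Std. Error"],
    beta_std = zfit$coefTable[terms, "Estimate"],
    p = fit$coefTable[, "Pr(>|t|)"],
    row.names = NULL
  )
  pInt <- tab$p[tab$term == "age_x_sexF"]
  main <- NULL
  if (pInt >= 0.05) {
    md <- design[, c("age", "sexF", "n_nodes", "scanner")]
    mfit <- lmCoefTable(y, md)
    mz <- lmCoefTable(zscore(y), as.data.frame(lapply(md, zscore)))
    mterms <- rownames(mfit$coefTable)
    main <- data.frame(
      term = mterms,
      beta = mfit$coefTable[, "Estimate"],
      se = mfit$coefTable[, "Std. Error"],
      beta_std = mz$coefTable[mterms, "Estimate"],
      p = mfit$coefTable[, "Pr(>|t|)"],
      row.names = NULL
    )
  }
  statResult(
    sprintf("age x sex interaction model for %s (stratum %s)", response,
            stratum),
    tab, p = pInt, alphaUsed = alpha,
    covariates = c("n_nodes", "scanner"),
    details = list(interactionP = pInt, mainEffects = main,
                   n = nrow(sub), stratum = stratum))
}

# ---- ANCOVA sex contrast -----------------------------------------------

#' Covariate-adjusted sex contrast (ANCOVA)
#'
#' Within one age stratum, compares women and men on a network property
#' by analysis of covariance: \code{response ~ sex + age + n_nodes +
#' scanner}, reporting the adjusted group means (estimated marginal means
#' at the covariate means) with standard errors and the p-value of the
#' sex effect.
#'
#' @inheritParams fitInteractionGLM
#' @return an \code{sgmStatResult}; \code{estimates} has one row per sex
#'   with adjusted mean and SE.
#' @export
ancovaSexContrast <- function(table, response, stratum = "all",
                              splitAge = 70, alpha = 0.05 / 3) {
  sub <- subsetStratum(table, stratum, splitAge)
  if (!nrow(sub)) stop("stratum is empty")
  if (length(unique(sub$sex)) < 2)
    stop("both sexes must be present in the stratum")
  d <- data.frame(
    y = sub[[response]],
    sex = factor(sub$sex, levels = c("F", "M")),
    age = sub$age,
    n_nodes = as.numeric(sub$n_nodes),
    scanner = as.numeric(factor(sub$scanner)) - 1
  )
  checkFullRank(stats::model.matrix(~ sex + age + n_nodes + scanner, d))
  fit <- lm(y ~ sex + age + n_nodes + scanner, data = d)
  emm <- as.data.frame(emmeans::emmeans(fit, "sex"))
  pSex <- summary(fit)$coefficients["sexM", "Pr(>|t|)"]
  statResult(
    sprintf("ANCOVA sex contrast for %s (stratum %s)", response, stratum),
    data.frame(sex = emm$sex, adjusted_mean = emm$emmean, se = emm$SE),
    p = pSex, alphaUsed = alpha,
    covariates = c("age", "n_nodes", "scanner"),
    details = list(n = nrow(sub), stratum = stratum))
}

# ---- Partial correlation -----------------------------------------------

#' Partial correlation
#'
#' Correlation between x and y after removing the linear effect of the
#' covariates from both (correlation of the two residual vectors). With
#' no covariates this reduces exactly to the Pearson correlation. The
#' p-value uses the t distribution with \code{n - 2 - k} degrees of
#' freedom, k the number of covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame (or NULL) of covariate columns; factors
#'   are expanded to indicators.
#' @param alpha reported alongside p (default 0.05/2, the Bonferroni
#'   level for the two age correlations per property).
#' @return an \code{sgmStatResult} with estimate r and df.
#' @export
partialCorrelation <- function(x, y, covariates = NULL, alpha = 0.05 / 2) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || !NCOL(covariates)) {
    k <- 0L
    rx <- x; ry <- y
  } else {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    mm <- stats::model.matrix(~ ., data = covariates)
    k <- ncol(mm) - 1L
    if (n <= k + 2) stop("need n > number of covariates + 2")
    rx <- stats::lm.fit(mm, x)$residuals
    ry <- stats::lm.fit(mm, y)$residuals
  }
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    warning("constant residuals; partial correlation undefined")
    return(statResult("partial correlation",
                      data.frame(r = NA_real_, df = n - 2L - k),
                      p = NA_real_, alphaUsed = alpha,
                      covariates = colnames(covariates)))
  }
  r <- cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  statResult("partial correlation",
             data.frame(r = r, df = df, t = tstat),
             p = p, alphaUsed = alpha,
             covariates = if (k) colnames(covariates) else character())
}

# ---- Dependent overlapping correlations --------------------------------

#' Compare two dependent overlapping correlations
#'
#' Tests whether a variable j (here: a network property) correlates
#' equally with two overlapping variables k and h (here: chronological
#' age and predicted brain age), given the correlation between k and h.
#' The default statistic is the Hittner-style modification of Dunn and
#' Clark's z for dependent overlapping correlations: both correlations
#' are Fisher-z transformed, their null covariance is estimated with the
#' back-transformed average correlation, and
#' \deqn{Z = (z_{jk} - z_{jh}) \sqrt{(n - 3) / (2 - 2 c)}}
#' is referred to the standard normal (two-sided). \code{"steiger"}
#' instead plugs the plain average of the two squared correlations into
#' the covariance term.
#'
#' @param rJK correlation of the property with chronological age.
#' @param rJH correlation of the property with brain age.
#' @param rKH correlation between chronological and brain age.
#' @param n sample size (>= 10).
#' @param method \code{"hittner"} (default) or \code{"steiger"}.
#' @param alpha reported alongside p (default 0.05).
#' @return an \code{sgmStatResult} with Z.
#' @examples
#' compareDependentCorrelations(-0.28, -0.63, 0.9, n = 200)
#' @export
compareDependentCorrelations <- function(rJK, rJH, rKH, n,
                                         method = c("hittner", "steiger"),
                                         alpha = 0.05) {
  method <- match.arg(method)
  rs <- c(rJK, rJH, rKH)
  if (any(abs(rs) >= 1)) stop("correlations must lie strictly in (-1, 1)")
  if (n < 10) stop("need n >= 10")
  z1 <- atanh(rJK)
  z2 <- atanh(rJH)
  rm2 <- switch(method,
    hittner = tanh((z1 + z2) / 2)^2,
    steiger = (rJK^2 + rJH^2) / 2)
  covTerm <- (rKH * (1 - 2 * rm2) - 0.5 * rm2 * (1 - 2 * rm2 - rKH^2)) /
    (1 - rm2)^2
  Z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * covTerm))
  p <- 2 * pnorm(abs(Z), lower.tail = FALSE)
  statResult(
    sprintf("dependent overlapping correlation comparison (%s)", method),
    data.frame(Z = Z, r_jk = rJK, r_jh = rJH, r_kh = rKH, n = n),
    p = p, alphaUsed = alpha)
}

# ---- GAM age trajectories ----------------------------------------------

#' Age-trajectory curves (GAM)
#'
#' Fits a penalized spline of the property on age (generalized additive
#' model), controlling for node count and scanner as linear terms,
#' separately per sex when \code{bySex} is TRUE. Returns fitted values
#' on an age grid, evaluated at the covariate means, with pointwise
#' approximate 95\% intervals.
#'
#' @param table subject table (needs >= 20 subjects per fitted group).
#' @param response property column name.
#' @param bySex fit separate curves for women and men (default TRUE).
#' @param gridLength points on the age grid (default 100).
#' @return data.frame with columns sex, age, fit, se, lower, upper.
#' @export
fitAgeTrajectory <- function(table, response, bySex = TRUE,
                             gridLength = 100) {
  groups <- if (bySex) split(table, table$sex) else list(all = table)
  out <- lapply(names(groups), function(g) {
    d0 <- groups[[g]]
    if (nrow(d0) < 20)
      stop("need >= 20 subjects per group for the trajectory fit")
    d <- data.frame(y = d0[[response]], age = d0$age,
                    n_nodes = as.numeric(d0$n_nodes),
                    scanner = as.numeric(factor(d0$scanner)) - 1)
    k <- max(3, min(10, length(unique(d$age)) - 1))
    fit <- mgcv::gam(y ~ s(age, k = k) + n_nodes + scanner, data = d)
    grid <- data.frame(
      age = seq(min(d$age), max(d$age), length.out = gridLength),
      n_nodes = mean(d$n_nodes), scanner = mean(d$scanner))
    pr <- mgcv::predict.gam(fit, grid, se.fit = TRUE)
    data.frame(sex = g, age = grid$age, fit = as.numeric(pr$fit),
               se = as.numeric(pr$se.fit),
               lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
               upper = as.numeric(pr$fit + 1.96 * pr$se.fit))
  })
  do.call(rbind, out)
}

# ---- Full analysis orchestration ---------------------------------------

networkProperties3 <- c("gamma", "lambda", "sigma")

#' Run the full statistical analysis
#'
#' Orchestrates the statistical stage on a per-subject table and emits
#' four table analogues plus a run manifest:
#' \describe{
#'   \item{demographics}{sex comparison (Mann-Whitney) of age, predicted
#'     age, brain-PAD, node count (alpha 0.05) and of the three network
#'     properties (Bonferroni alpha 0.05/3).}
#'   \item{interactions}{age-by-sex interaction models per property in
#'     the two age strata (split at 70 years; the boundary belongs to
#'     the upper stratum), with main-effect fits when the interaction is
#'     absent.}
#'   \item{sexContrasts}{covariate-adjusted (age, node count, scanner)
#'     sex contrasts per property and stratum.}
#'   \item{correlations}{partial correlations (controlling sex, node
#'     count, scanner; alpha 0.05/2) of each property with chronological
#'     and predicted brain age per stratum, and the dependent-correlation
#'     comparison between the two (alpha 0.05).}
#' }
#' When predicted ages are missing the correlation stage runs
#' chronological-age-only analyses with a warning.
#'
#' @param table per-subject data.frame with columns id, age, sex,
#'   scanner, n_nodes, gamma, lambda, sigma and optionally
#'   predicted_age, brain_pad.
#' @param splitAge stratification age (default 70).
#' @param outDir optional directory; when given, each table analogue is
#'   written as CSV and the manifest as JSON.
#' @param method passed to [compareDependentCorrelations()].
#' @return list with data.frames \code{demographics},
#'   \code{interactions}, \code{sexContrasts}, \code{correlations} and a
#'   \code{manifest} list.
#' @export
runFullAnalysis <- function(table, splitAge = 70, outDir = NULL,
                            method = "hittner") {
  required <- c("id", "age", "sex", "scanner", "n_nodes",
                networkProperties3)
  missingCols <- setdiff(required, names(table))
  if (length(missingCols))
    stop("missing column(s): ", paste(missingCols, collapse = ", "))
  hasBrainAge <- "predicted_age" %in% names(table) &&
    !all(is.na(table$predicted_age))
  if (!hasBrainAge)
    warning("no predicted ages; running chronological-age-only analyses")

  isF <- table$sex == "F"
  demoVars <- c(age = "age",
                if (hasBrainAge) c(predicted_age = "predicted_age",
                                   brain_pad = "brain_pad"),
                n_nodes = "n_nodes")
  demo <- do.call(rbind, lapply(names(demoVars), function(v) {
    col <- table[[demoVars[[v]]]]
    res <- mannWhitneyU(col[isF], col[!isF], alpha = 0.05)
    data.frame(variable = v, mean_F = mean(col[isF]), sd_F = sd(col[isF]),
               mean_M = mean(col[!isF]), sd_M = sd(col[!isF]),
               U = res$estimates$U_A, p = res$p, alpha = res$alphaUsed)
  }))
  demoNet <- do.call(rbind, lapply(networkProperties3, function(v) {
    col <- table[[v]]
    res <- mannWhitneyU(col[isF], col[!isF], alpha = 0.05 / 3)
    data.frame(variable = v, mean_F = mean(col[isF]), sd_F = sd(col[isF]),
               mean_M = mean(col[!isF]), sd_M = sd(col[!isF]),
               U = res$estimates$U_A, p = res$p, alpha = res$alphaUsed)
  }))
  demographics <- rbind(demo, demoNet)

  strata <- c("<70", ">=70")
  interactions <- do.call(rbind, lapply(strata, function(st) {
    do.call(rbind, lapply(networkProperties3, function(v) {
      res <- fitInteractionGLM(table, v, st, splitAge)
      tab <- res$estimates
      tab <- tab[tab$term %in% c("age_x_sexF", "age", "sexF"), ]
      model <- "interaction"
      if (!is.null(res$details$mainEffects)) {
        mt <- res$details$mainEffects
        mt <- mt[mt$term %in% c("age", "sexF"), ]
        mt$term <- paste0(mt$term, "_main")
        tab <- rbind(tab, mt)
        model <- "interaction+main"
      }
      cbind(stratum = st, property = v, tab, alpha = res$alphaUsed,
            model = model)
    }))
  }))

  sexContrasts <- do.call(rbind, lapply(strata, function(st) {
    do.call(rbind, lapply(networkProperties3, function(v) {
      res <- ancovaSexContrast(table, v, st, splitAge)
      e <- res$estimates
      data.frame(stratum = st, property = v,
                 adj_mean_F = e$adjusted_mean[e$sex == "F"],
                 se_F = e$se[e$sex == "F"],
                 adj_mean_M = e$adjusted_mean[e$sex == "M"],
                 se_M = e$se[e$sex == "M"],
                 p = res$p, alpha = res$alphaUsed)
    }))
  }))

  correlations <- do.call(rbind, lapply(strata, function(st) {
    sub <- subsetStratum(table, st, splitAge)
    covs <- data.frame(sexF = as.numeric(sub$sex == "F"),
                       n_nodes = as.numeric(sub$n_nodes),
                       scanner = as.numeric(factor(sub$scanner)) - 1)
    do.call(rbind, lapply(networkProperties3, function(v) {
      rc <- partialCorrelation(sub[[v]], sub$age, covs)
      row <- data.frame(stratum = st, property = v,
                        r_chron = rc$estimates$r, p_chron = rc$p,
                        r_brain = NA_real_, p_brain = NA_real_,
                        p_compare = NA_real_, alpha = rc$alphaUsed)
      if (hasBrainAge) {
        rb <- partialCorrelation(sub[[v]], sub$predicted_age, covs)
        rkh <- partialCorrelation(sub$age, sub$predicted_age, covs)
        cmp <- compareDependentCorrelations(
          rc$estimates$r, rb$estimates$r, rkh$estimates$r,
          n = nrow(sub) - ncol(covs), method = method)
        row$r_brain <- rb$estimates$r
        row$p_brain <- rb$p
        row$p_compare <- cmp$p
      }
      row
    }))
  }))

  manifest <- list(
    n_subjects = nrow(table),
    split_age = splitAge,
    alphas = list(demographics = 0.05, network_properties = 0.05 / 3,
                  correlations = 0.05 / 2, comparison = 0.05),
    formulas = list(
      interaction = "property ~ age + sex + age:sex + n_nodes + scanner",
      main = "property ~ age + sex + n_nodes + scanner",
      ancova = "property ~ sex + age + n_nodes + scanner",
      partial = "cor(property, age | sex, n_nodes, scanner)"),
    dependent_correlation_method = method,
    has_brain_age = hasBrainAge
  )
  out <- list(demographics = demographics, interactions = interactions,
              sexContrasts = sexContrasts, correlations = correlations,
              manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("demographics", "interactions", "sexContrasts",
                 "correlations"))
      utils::write.csv(out[[nm]], file.path(outDir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
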