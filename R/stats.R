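# Statistical layer: PCA/Hotelling T2 outlier exclusion, random-intercept
# linear mixed models over genotype x state x trial, the
# interaction-dropping refit rule for two-factor analyses, Welch t post
# hocs and Benjamini-Hochberg FDR.

#' Hotelling T2 outlier mask
#'
#' Computes principal-component scores of the (scaled) observation matrix,
#' the Hotelling T2 statistic per point over the components explaining at
#' least \code{varExplained} of the variance, and flags points whose T2
#' exceeds the F-distribution 95\% reference bound
#' \eqn{k(n-1)/(n-k) \, F_{k, n-k, 1-\alpha}}. The mask is returned, never
#' applied.
#'
#' @param x numeric matrix (points x measures) or vector (univariate).
#' @param alpha exclusion level (default 0.05).
#' @param varExplained cumulative variance fraction retained in the PCA
#'   (default 0.95).
#' @return logical vector, TRUE = keep; the T2 values and bound are
#'   attached as attributes \code{t2} and \code{bound}.
#' @export
hotellingOutliers <- function(x, alpha = 0.05, varExplained = 0.95) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 points for a covariance estimate")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0) || ncol(x) == 1) {
    # singular covariance: univariate z rule on the informative columns
    if (ncol(x) > 1) {
      warning("singular covariance; falling back to univariate z-rule")
    }
    keepCols <- which(sds > 0)
    if (!length(keepCols)) {
      mask <- rep(TRUE, n)
      attr(mask, "t2") <- rep(0, n)
      attr(mask, "bound") <- Inf
      return(mask)
    }
    z <- scale(x[, keepCols, drop = FALSE])
    t2 <- rowSums(z^2)
    bound <- stats::qchisq(1 - alpha, df = length(keepCols))
  } else {
    pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
    ev <- pc$sdev^2
    k <- which(cumsum(ev) / sum(ev) >= varExplained - 1e-12)[1]
    k <- min(k, n - 2L)  # keep the F reference bound defined
    scores <- pc$x[, seq_len(k), drop = FALSE]
    t2 <- rowSums(sweep(scores^2, 2, ev[seq_len(k)], "/"))
    bound <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
  }
  mask <- t2 <= bound
  attr(mask, "t2") <- t2
  attr(mask, "bound") <- bound
  mask
}

#' Grouped T2 outlier mask on a long observation table
#'
#' Applies [hotellingOutliers()] separately within each group (default
#' genotype x state x trial), building each group's multivariate rows from
#' its measures (subjects x measures, wide). Groups too small for a
#' covariance estimate are kept whole.
#'
#' @param table long-format data.frame with columns \code{subject},
#'   \code{measure}, \code{value} and the grouping columns.
#' @param groupBy grouping columns (default genotype, state, trial; columns
#'   absent from the table are ignored).
#' @param alpha exclusion level.
#' @return logical vector along \code{table} rows, TRUE = keep.
#' @export
t2OutlierMask <- function(table, groupBy = c("genotype", "state", "trial"),
                          alpha = 0.05) {
  groupBy <- intersect(groupBy, names(table))
  key <- interaction(table[groupBy], drop = TRUE)
  keep <- rep(TRUE, nrow(table))
  for (g in levels(key)) {
    rows <- which(key == g)
    sub <- table[rows, , drop = FALSE]
    wide <- stats::reshape(
      sub[, c("subject", "measure", "value")], direction = "wide",
      idvar = "subject", timevar = "measure")
    m <- as.matrix(wide[, -1, drop = FALSE])
    if (nrow(m) < 3 || anyNA(m)) next
    mask <- hotellingOutliers(m, alpha = alpha)
    dropped <- wide$subject[!mask]
    if (length(dropped)) keep[rows][sub$subject %in% dropped] <- FALSE
  }
  keep
}

# build an analysis data.frame with treatment-coded factors; reference
# levels: WT, exploration, trial 1
.lmmData <- function(table, fixed) {
  d <- as.data.frame(table)
  refs <- c(genotype = "WT", state = "exploration", trial = "1")
  for (f in fixed) {
    lev <- unique(as.character(d[[f]]))
    ref <- if (f %in% names(refs) && refs[[f]] %in% lev) refs[[f]] else lev[1]
    d[[f]] <- stats::relevel(factor(as.character(d[[f]])), ref = ref)
  }
  d$subject <- factor(d$subject)
  d
}

#' Random-intercept linear mixed model
#'
#' Fits \code{value ~ <fixed factors with all interactions> + (1 |
#' subject)} by REML with treatment coding (reference WT / exploration /
#' trial 1), and extracts main-effect and interaction p-values (type-III
#' F tests, Satterthwaite degrees of freedom). A constant response or a
#' non-convergent fit is flagged, never an error.
#'
#' @param table data.frame with columns \code{subject}, \code{value} and
#'   the fixed-effect columns.
#' @param fixed fixed-effect factor names (default genotype, state,
#'   trial); all interactions are included.
#' @param response response column name (default \code{"value"}).
#' @param reml logical (default TRUE).
#' @return object of class \code{"LmmResult"}: list with \code{model},
#'   \code{coefficients} (estimates, SE, df, t, p), \code{effects}
#'   (per-term F and p), \code{randomInterceptSd}, \code{residualSd},
#'   \code{converged}, \code{degenerate}, \code{dfMethod}.
#' @export
fitLmm <- function(table, fixed = c("genotype", "state", "trial"),
                   response = "value", reml = TRUE) {
  fixed <- intersect(fixed, names(table))
  for (f in fixed) {
    if (length(unique(table[[f]])) < 2) fixed <- setdiff(fixed, f)
  }
  if (!length(fixed)) stop("no fixed effect with >= 2 levels")
  d <- .lmmData(table, fixed)
  d$.y <- d[[response]]
  rhs <- paste(fixed, collapse = " * ")
  fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | subject)"))

  if (stats::var(d$.y) == 0) {
    # degenerate: constant response; intercept = the constant, all effects 0
    lmFit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
    co <- suppressWarnings(summary(lmFit)$coefficients)
    coefs <- data.frame(term = rownames(co), estimate = co[, 1],
                        se = co[, 2], df = NA_real_, t = NA_real_,
                        p = NA_real_, row.names = NULL)
    coefs$estimate <- c(d$.y[1], rep(0, nrow(coefs) - 1))
    return(structure(list(
      model = lmFit, coefficients = coefs,
      effects = data.frame(term = character(), F = numeric(),
                           p = numeric()),
      randomInterceptSd = 0, residualSd = 0, converged = TRUE,
      degenerate = TRUE, dfMethod = "none", fixed = fixed,
      data = d), class = "LmmResult"))
  }

  fit <- tryCatch(
    lmerTest::lmer(fml, data = d, REML = reml),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(model = NULL, coefficients = NULL,
                          effects = NULL, randomInterceptSd = NA_real_,
                          residualSd = NA_real_, converged = FALSE,
                          degenerate = FALSE,
                          message = conditionMessage(fit),
                          dfMethod = "Satterthwaite", fixed = fixed,
                          data = d),
                     class = "LmmResult"))
  }
  # a singular (boundary) fit is a valid REML solution with zero
  # random-intercept variance, not a convergence failure
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  conv <- !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  co <- stats::coef(summary(fit))
  coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], df = co[, "df"],
                      t = co[, "t value"], p = co[, "Pr(>|t|)"],
                      row.names = NULL)
  an <- suppressMessages(stats::anova(fit, type = 3))
  effects <- data.frame(term = rownames(an), F = an[, "F value"],
                        p = an[, "Pr(>F)"], row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    model = fit, coefficients = coefs, effects = effects,
    randomInterceptSd = vc$sdcor[vc$grp == "subject"][1],
    residualSd = vc$sdcor[vc$grp == "Residual"][1],
    converged = conv, degenerate = FALSE, dfMethod = "Satterthwaite",
    fixed = fixed, data = d), class = "LmmResult")
}

#' @export
print.LmmResult <- function(x, ...) {
  cat("Random-intercept linear mixed model\n")
  if (!x$converged && is.null(x$model)) {
    cat("  fit failed:", x$message, "\n")
    return(invisible(x))
  }
  if (isTRUE(x$degenerate)) cat("  (degenerate constant response)\n")
  if (!x$converged) cat("  (convergence warnings)\n")
  cat(sprintf("  random intercept SD %.4g, residual SD %.4g (%s df)\n",
              x$randomInterceptSd, x$residualSd, x$dfMethod))
  if (!is.null(x$effects) && nrow(x$effects)) {
    cat("  effects:\n")
    print(x$effects, digits = 4)
  }
  invisible(x)
}

#' Interaction-dropping refit rule for two-factor analyses
#'
#' For the genotype x trial analyses (PAC, occurrence ratio, whole-trial
#' behavior): when the interaction term is not significant at \code{alpha},
#' the interaction is removed and the additive model's main-effect p-values
#' are reported; otherwise the full model is kept.
#'
#' @param result an \code{"LmmResult"} from [fitLmm()] with two fixed
#'   factors.
#' @param table the observation table the model was fit on.
#' @param alpha significance level for the interaction (default 0.05).
#' @return an \code{"LmmResult"}; \code{reduced} indicates whether the
#'   additive refit is being reported.
#' @export
refitWithoutInteraction <- function(result, table, alpha = 0.05) {
  stopifnot(inherits(result, "LmmResult"))
  fixed <- result$fixed
  if (length(fixed) != 2) {
    stop("the interaction-dropping rule applies to two-factor models")
  }
  intTerm <- grep(":", result$effects$term, value = TRUE)
  pInt <- result$effects$p[result$effects$term == intTerm[1]]
  if (length(pInt) && is.finite(pInt) && pInt < alpha) {
    result$reduced <- FALSE
    return(result)
  }
  d <- .lmmData(table, fixed)
  d$.y <- d[[if (!is.null(result$response)) result$response else "value"]]
  fml <- stats::as.formula(paste(".y ~", paste(fixed, collapse = " + "),
                                 "+ (1 | subject)"))
  fit <- lmerTest::lmer(fml, data = d, REML = TRUE)
  co <- stats::coef(summary(fit))
  an <- suppressMessages(stats::anova(fit, type = 3))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    model = fit,
    coefficients = data.frame(term = rownames(co),
                              estimate = co[, "Estimate"],
                              se = co[, "Std. Error"], df = co[, "df"],
                              t = co[, "t value"], p = co[, "Pr(>|t|)"],
                              row.names = NULL),
    effects = data.frame(term = rownames(an), F = an[, "F value"],
                         p = an[, "Pr(>F)"], row.names = NULL),
    randomInterceptSd = vc$sdcor[vc$grp == "subject"][1],
    residualSd = vc$sdcor[vc$grp == "Residual"][1],
    converged = !any(grepl("failed to converge",
                           unlist(fit@optinfo$conv$lme4$messages),
                           ignore.case = TRUE)),
    degenerate = FALSE, dfMethod = "Satterthwaite", fixed = fixed,
    data = d, reduced = TRUE), class = "LmmResult")
}

#' Benjamini-Hochberg FDR
#'
#' Step-up q-values: with \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j}, capped at 1. Rejects
#' where \eqn{q \le \alpha}.
#'
#' @param p p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with \code{q} (same order as \code{p}) and \code{reject}
#'   (logical).
#' @export
bhFdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(ranked)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  list(q = out, reject = out <= alpha)
}

#' Pairwise Welch t post hocs with BH correction
#'
#' Welch two-sample t-tests on subject-level values between the two levels
#' of \code{factor}, within each stratum defined by \code{within}, followed
#' by Benjamini-Hochberg correction across the strata of this measure
#' family.
#'
#' @param table data.frame with \code{value}, the comparison factor and
#'   stratification columns.
#' @param factor name of the two-level comparison column (e.g.
#'   \code{"genotype"}).
#' @param within stratification columns (default none: one overall test).
#' @param alpha FDR level.
#' @return data.frame with one row per stratum: the stratum labels,
#'   \code{t}, \code{df}, \code{p}, \code{q}, \code{reject}.
#' @export
posthocContrasts <- function(table, factor = "genotype", within = NULL,
                             alpha = 0.05) {
  lev <- unique(as.character(table[[factor]]))
  if (length(lev) != 2) stop("the comparison factor must have two levels")
  strata <- if (length(within)) {
    unique(table[within])
  } else {
    data.frame(.all = "all")[, 0, drop = FALSE]
  }
  if (!nrow(strata)) strata <- data.frame(row.names = 1)
  rows <- lapply(seq_len(max(1, nrow(strata))), function(i) {
    sel <- rep(TRUE, nrow(table))
    for (cn in names(strata)) sel <- sel & table[[cn]] == strata[i, cn]
    a <- table$value[sel & table[[factor]] == lev[1]]
    b <- table$value[sel & table[[factor]] == lev[2]]
    if (length(a) < 2 || length(b) < 2) {
      return(cbind(strata[i, , drop = FALSE],
                   data.frame(t = NA_real_, df = NA_real_, p = NA_real_)))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    cbind(strata[i, , drop = FALSE],
          data.frame(t = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$reject <- NA
  if (any(ok)) {
    fdr <- bhFdr(out$p[ok], alpha)
    out$q[ok] <- fdr$q
    out$reject[ok] <- fdr$reject
  }
  out
}

#' Build a long-format observation table
#'
#' @param subject,genotype,state,trial,measure,value parallel vectors (the
#'   \code{state} column may be omitted for whole-trial measures by passing
#'   NULL).
#' @return validated long-format data.frame.
#' @export
observationTable <- function(subject, genotype, trial, measure, value,
                             state = NULL) {
  n <- length(value)
  d <- data.frame(subject = rep_len(as.character(subject), n),
                  genotype = rep_len(as.character(genotype), n),
                  trial = rep_len(as.character(trial), n),
                  measure = rep_len(as.character(measure), n),
                  value = as.numeric(value),
                  stringsAsFactors = FALSE)
  if (!is.null(state)) d$state <- rep_len(as.character(state), n)
  if (anyNA(d$genotype)) stop("genotype may not be missing")
  d
}
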