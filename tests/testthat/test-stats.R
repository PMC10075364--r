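# Statistical layer: T2 outliers, mixed models, interaction rule, FDR and
# post hocs.

makeBalancedTable <- function(seed = 2, nPerGroup = 10, effect = 0) {
  set.seed(seed)
  d <- expand.grid(subject = paste0("s", seq_len(2 * nPerGroup)),
                   state = c("exploration", "wake_immobility"),
                   trial = c("1", "2"), stringsAsFactors = FALSE)
  d$genotype <- ifelse(as.integer(sub("s", "", d$subject)) <= nPerGroup,
                       "WT", "TG")
  d$value <- rnorm(nrow(d)) + effect * (d$genotype == "TG")
  d
}

test_that("Hotelling T2 flags a gross outlier and keeps tight clusters", {
  set.seed(3)
  x <- rbind(cbind(rnorm(9, 0, 0.1), rnorm(9, 0, 0.1)), c(3, 3))
  mask <- hotellingOutliers(x)
  expect_identical(which(!mask), 10L)
  # oracle: T2 from the definition on standardized PC scores
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  k <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  t2 <- rowSums(sweep(pc$x[, 1:k, drop = FALSE]^2, 2, ev[1:k], "/"))
  expect_equal(unname(attr(mask, "t2")), unname(t2), tolerance = 1e-9)
  # identical points: nothing excluded, with the singular-covariance
  # fallback announced
  same <- matrix(1, nrow = 6, ncol = 2)
  expect_warning(m0 <- hotellingOutliers(same), "singular")
  expect_true(all(m0))
  # monotone rerun: re-applying to retained points drops no more than before
  m2 <- hotellingOutliers(x[mask, , drop = FALSE])
  expect_lte(sum(!m2), sum(!mask))
  expect_error(hotellingOutliers(x[1:2, ]), "at least 3")
})

test_that("grouped T2 masking works per genotype-state-trial cell", {
  d <- makeBalancedTable(seed = 4)
  d$measure <- "m1"
  d2 <- d
  d2$measure <- "m2"
  d2$value <- rnorm(nrow(d2))
  tab <- rbind(d, d2)
  # implant one absurd subject in one cell
  sel <- tab$subject == "s1" & tab$state == "exploration" & tab$trial == "1"
  tab$value[sel] <- 50
  keep <- t2OutlierMask(tab)
  expect_false(all(keep[sel]))
  expect_true(all(keep[!sel]))
})

test_that("LMM fixed effects match OLS on balanced data", {
  d <- makeBalancedTable(seed = 2)
  # with no subject structure the intercept variance sits on the
  # boundary; the singular-fit note is expected
  fit <- suppressMessages(suppressWarnings(fitLmm(d)))
  expect_true(fit$converged)
  dd <- within(d, {
    genotype <- relevel(factor(genotype), "WT")
    state <- relevel(factor(state), "exploration")
    trial <- relevel(factor(trial), "1")
  })
  ols <- lm(value ~ genotype * state * trial, data = dd)
  expect_equal(fit$coefficients$estimate,
               unname(coef(ols)[fit$coefficients$term]),
               tolerance = 1e-6)
  # treatment coding with the WT/exploration/trial-1 reference
  expect_true("(Intercept)" %in% fit$coefficients$term)
  expect_true(any(grepl("genotypeTG", fit$coefficients$term)))
})

test_that("LMM recovers an injected genotype effect with subject structure", {
  covered <- 0L
  nRep <- 40
  for (r in seq_len(nRep)) {
    set.seed(100 + r)
    d <- expand.grid(subject = paste0("s", 1:40),
                     trial = c("1", "2"), stringsAsFactors = FALSE)
    d$genotype <- ifelse(as.integer(sub("s", "", d$subject)) <= 20,
                         "WT", "TG")
    subjEff <- rnorm(40, sd = 0.5)
    names(subjEff) <- paste0("s", 1:40)
    d$value <- 1.0 * (d$genotype == "TG") + subjEff[d$subject] +
      rnorm(nrow(d), sd = 0.5)
    fit <- suppressMessages(fitLmm(d, fixed = c("genotype", "trial")))
    co <- fit$coefficients
    row <- co[grepl("genotypeTG$", co$term), ]
    ci <- row$estimate + c(-1.96, 1.96) * row$se
    if (ci[1] <= 1.0 && 1.0 <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered / nRep, 0.9)
})

test_that("constant responses give a degenerate flagged fit, not a crash", {
  d <- makeBalancedTable(seed = 5)
  d$value <- 5
  fit <- fitLmm(d)
  expect_true(fit$degenerate)
  expect_equal(fit$coefficients$estimate[1], 5)
  expect_true(all(fit$coefficients$estimate[-1] == 0))
})

test_that("the interaction-dropping rule follows the significance gate", {
  # strong interaction: full model retained
  set.seed(6)
  d <- expand.grid(subject = paste0("s", 1:20), trial = c("1", "2"),
                   stringsAsFactors = FALSE)
  d$genotype <- ifelse(as.integer(sub("s", "", d$subject)) <= 10,
                       "WT", "TG")
  d$value <- rnorm(nrow(d), sd = 0.2) +
    2 * (d$genotype == "TG") * (d$trial == "2")
  full <- suppressMessages(fitLmm(d, fixed = c("genotype", "trial")))
  out <- suppressMessages(refitWithoutInteraction(full, d))
  expect_false(out$reduced)
  # null interaction: reduced model reported
  d$value <- rnorm(nrow(d))
  full0 <- suppressMessages(fitLmm(d, fixed = c("genotype", "trial")))
  out0 <- suppressMessages(refitWithoutInteraction(full0, d))
  expect_true(out0$reduced)
  expect_false(any(grepl(":", out0$effects$term)))
})

test_that("BH q-values match hand-computed and brute-force oracles", {
  # single p: q = p
  expect_equal(bhFdr(0.03)$q, 0.03)
  # hand-computed step-up: 4*.01/1, min(4*.02/2, ...) ... all 0.04
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  expect_true(all(bhFdr(c(0.01, 0.02, 0.03, 0.04))$reject))
  # degenerate: all ones
  expect_equal(bhFdr(rep(1, 5))$q, rep(1, 5))
  expect_false(any(bhFdr(rep(1, 5))$reject))
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
  # 1000 random vectors against the literal double-loop implementation
  set.seed(7)
  for (i in seq_len(1000)) {
    p <- runif(sample(1:12, 1))
    got <- bhFdr(p)
    want <- bruteForceBH(p)
    expect_identical(round(got$q, 12), round(want$q, 12))
    expect_identical(got$reject, want$reject)
  }
  # and against the standard step-up adjustment
  set.seed(8)
  p <- runif(50)
  expect_equal(bhFdr(p)$q, p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("q is never below p and post hocs stratify correctly", {
  set.seed(9)
  p <- runif(20)
  expect_true(all(bhFdr(p)$q >= p - 1e-12))
  d <- makeBalancedTable(seed = 10, effect = 2)
  ph <- posthocContrasts(d, factor = "genotype",
                         within = c("state", "trial"))
  expect_identical(nrow(ph), 4L)
  expect_true(all(ph$q >= ph$p - 1e-12))
  expect_true(all(ph$reject))
})
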