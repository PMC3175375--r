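test_that("two-rater fits agree with an independent Poisson GLM oracle", {
  set.seed(202)
  for (i in 1:10) {
    tab <- random_table(K = 2, C = 3, n = 400)
    for (m in c("independence", "homogeneous", "nonhomogeneous")) {
      fit <- agree_loglin(tab, m, agree_coding = "dummy")
      oracle <- glm_oracle_2x(tab, switch(m, independence = "none",
                                          homogeneous = "shared",
                                          "by_category"))
      expect_equal(fit$deviance, stats::deviance(oracle), tolerance = 1e-7)
      expect_equal(unname(fit$fitted), unname(stats::fitted(oracle)),
                   tolerance = 1e-6)
      expect_identical(fit$df.residual, stats::df.residual(oracle))
    }
    # dummy-coded agreement estimates and SEs match the oracle's
    fit <- agree_loglin(tab, "homogeneous", agree_coding = "dummy")
    oracle <- glm_oracle_2x(tab, "shared")
    sm <- summary(oracle)$coefficients
    expect_equal(unname(fit$coefficients["agree(R1:R2)"]),
                 unname(sm["I", "Estimate"]), tolerance = 1e-5)
    expect_equal(unname(sqrt(diag(fit$vcov))["agree(R1:R2)"]),
                 unname(sm["I", "Std. Error"]), tolerance = 1e-5)
  }
})

test_that("independence fitted counts equal the product-of-margins closed form", {
  set.seed(303)
  for (i in 1:10) {
    tab <- random_table(K = sample(2:3, 1), C = sample(2:3, 1), n = 300)
    fit <- agree_loglin(tab, "independence")
    cells <- as.data.frame(tab)
    n <- sum(tab)
    closed <- rep(n^(1 - length(raters(tab))), nrow(cells))
    for (r in raters(tab))
      closed <- closed * marginalize(tab, r)[as.character(cells[[r]])]
    expect_equal(unname(fit$fitted), unname(closed), tolerance = 1e-8)
  }
})

test_that("Poisson ML moment conditions hold for any fitted spec", {
  set.seed(404)
  tab <- random_table(K = 3, C = 3, n = 600)
  sp <- agreement_spec("pairwise_nonhomogeneous", raters(tab),
                       categories(tab))
  fit <- agree_loglin(tab, spec = sp)
  expect_equal(sum(fit$fitted), sum(tab), tolerance = 1e-8)
  # fitted margins match observed margins for every rater
  for (r in raters(tab)) {
    cells <- as.data.frame(tab)
    obs <- marginalize(tab, r)
    fitm <- tapply(fit$fitted, cells[[r]], sum)
    expect_equal(as.vector(fitm[names(obs)]), unname(obs), tolerance = 1e-6)
  }
  # fitted all-agree totals match observed totals per agreement column
  X <- agreement_design(sp, agree_coding = "dummy")
  y <- cell_counts(tab)
  fit_d <- agree_loglin(tab, spec = sp, agree_coding = "dummy")
  for (j in grep("^agree\\(", colnames(X)))
    expect_equal(sum(X[, j] * fit_d$fitted), sum(X[, j] * y),
                 tolerance = 1e-6)
})

test_that("estimates are invariant to the coding conventions", {
  set.seed(505)
  for (i in 1:5) {
    tab <- random_table(K = 2, C = 3, n = 500)
    agr <- function(f) f$coefficients[grep("^agree", names(f$coefficients))]
    f_ref <- agree_loglin(tab, "nonhomogeneous", main_coding = "reference")
    f_sum <- agree_loglin(tab, "nonhomogeneous", main_coding = "sum")
    expect_equal(f_ref$deviance, f_sum$deviance, tolerance = 1e-6)
    expect_equal(agr(f_ref), agr(f_sum), tolerance = 1e-6)
    se <- function(f) sqrt(diag(f$vcov))[grep("^agree", names(f$coefficients))]
    expect_equal(se(f_ref), se(f_sum), tolerance = 1e-6)
    # dummy-coded agreement estimates are exactly twice the effect-coded ones
    f_dum <- agree_loglin(tab, "nonhomogeneous", agree_coding = "dummy")
    expect_equal(f_dum$deviance, f_ref$deviance, tolerance = 1e-6)
    expect_equal(unname(agr(f_dum)), unname(2 * agr(f_ref)),
                 tolerance = 1e-6)
  }
})

test_that("fits are equivariant under category relabelling", {
  set.seed(606)
  tab <- random_table(K = 2, C = 3, n = 500)
  perm <- c(2, 3, 1)
  a <- unclass(tab)[perm, perm]
  tab_p <- rating_table(a, raters(tab), categories(tab)[perm])
  f <- agree_loglin(tab, "nonhomogeneous")
  f_p <- agree_loglin(tab_p, "nonhomogeneous")
  expect_equal(f$deviance, f_p$deviance, tolerance = 1e-8)
  for (m in categories(tab)) {
    lab <- paste0("agree(R1:R2)=", m)
    expect_equal(f$coefficients[[lab]], f_p$coefficients[[lab]],
                 tolerance = 1e-6)
  }
})

test_that("unsupported agreement patterns are reported as divergent", {
  # the by-category diagonal indicator for c2 covers only an empty cell,
  # so its ML estimate runs to -infinity
  tab <- rating_table(c(20, 5, 5, 5, 0, 5, 5, 5, 20),
                      c("A", "B"), c("c1", "c2", "c3"))
  expect_error(agree_loglin(tab, "nonhomogeneous"), "diverging")
})

test_that("degenerate inputs are rejected", {
  tab0 <- rating_table(rep(0, 9), c("A", "B"), c("x", "y", "z"))
  expect_error(agree_loglin(tab0, "independence"), "empty")
  tab <- table1()
  sp_bad <- agreement_spec("independence", c("X", "Y"), categories(tab))
  expect_error(agree_loglin(tab, spec = sp_bad), "match")
})

test_that("squared deviance residuals add up to the deviance", {
  tab <- table1()
  fit <- agree_loglin(tab, "homogeneous")
  expect_equal(sum(residuals(fit, "deviance")^2), fit$deviance,
               tolerance = 1e-8)
  # pearson residuals have the familiar (y - mu)/sqrt(mu) form
  y <- cell_counts(tab)
  expect_equal(unname(residuals(fit, "pearson")),
               unname((y - fit$fitted) / sqrt(fit$fitted)))
})

test_that("likelihood-ratio tests compare nested fits on the same table", {
  tab <- table1()
  f0 <- agree_loglin(tab, "independence")
  f1 <- agree_loglin(tab, "homogeneous")
  f2 <- agree_loglin(tab, "nonhomogeneous")
  t01 <- lr_test(f0, f1)
  expect_equal(t01$statistic, f0$deviance - f1$deviance)
  expect_identical(t01$df, 1L)
  t12 <- lr_test(f1, f2)
  expect_identical(t12$df, 2L)
  expect_lt(t12$p.value, 0.001)
  expect_error(lr_test(f1, f1), "degenerate")
  expect_error(lr_test(f2, f1), "not nested")
  other <- random_table(K = 2, C = 3, n = 100)
  expect_error(lr_test(agree_loglin(other, "independence"), f1),
               "same table")
})

test_that("single-parameter Wald tests square the coefficient z-test", {
  tab <- table1()
  fit <- agree_loglin(tab, "nonhomogeneous")
  lab <- "agree(RENEX:consensus)=equivocal"
  w <- wald_test(fit, stats::setNames(1, lab))
  z <- fit$coefficients[[lab]] / sqrt(diag(fit$vcov))[[lab]]
  expect_equal(w$statistic, z^2, tolerance = 1e-10)
  expect_identical(w$df, 1L)
  # and the two-sided z p-value equals the chi-square(1) upper tail
  expect_equal(w$p.value, 2 * stats::pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("malformed Wald constraints are rejected", {
  fit <- agree_loglin(table1(), "nonhomogeneous")
  expect_error(wald_test(fit, stats::setNames(0, names(coef(fit))[1])),
               "all-zero")
  expect_error(wald_test(fit, stats::setNames(1, "no_such_parameter")),
               "unknown")
  L2 <- matrix(c(1, -1, 2, -2), 2, 2, byrow = TRUE,
               dimnames = list(NULL, names(coef(fit))[6:7]))
  expect_error(wald_test(fit, L2), "dependent")
})
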