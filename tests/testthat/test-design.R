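cats3 <- c("non-obstructed", "equivocal", "obstructed")
panel4 <- c("E1", "E2", "E3", "CAD")

test_that("residual df bookkeeping reproduces the two-rater ladder", {
  two <- c("RENEX", "consensus")
  sp_ind <- agreement_spec("independence", two, cats3)
  sp_hom <- agreement_spec("homogeneous", two, cats3)
  sp_non <- agreement_spec("nonhomogeneous", two, cats3)
  expect_identical(residual_df(sp_ind), 4L)
  expect_identical(residual_df(sp_hom), 3L)
  expect_identical(residual_df(sp_non), 1L)
  expect_identical(dim(agreement_design(sp_ind)), c(9L, 5L))
  expect_identical(dim(agreement_design(sp_hom)), c(9L, 6L))
  expect_identical(n_parameters(sp_ind), 1L + 2L * 2L)
  # category-specific pair term contributes one column per category
  X <- agreement_design(sp_non)
  expect_length(grep("^agree\\(", colnames(X)), 3L)
})

test_that("residual df bookkeeping reproduces the four-rater designs", {
  dfs <- c(independence = 72L, pairwise_homogeneous = 66L,
           pairwise_nonhomogeneous = 54L, threeway_homogeneous = 68L,
           threeway_nonhomogeneous = 60L)
  for (m in names(dfs)) {
    sp <- agreement_spec(m, panel4, cats3)
    expect_identical(residual_df(sp), dfs[[m]])
    X <- agreement_design(sp)
    expect_identical(nrow(X), 81L)
    expect_identical(81L - ncol(X), dfs[[m]])
    expect_identical(qr(X)$rank, ncol(X))  # full column rank
  }
  # three-way category-specific: 4 triples x 3 categories, no pair columns
  X3 <- agreement_design(agreement_spec("threeway_nonhomogeneous",
                                        panel4, cats3))
  expect_length(grep("^agree\\(", colnames(X3)), 12L)
})

test_that("agreement indicators sit exactly on the all-agree cells", {
  sp <- agreement_spec("pairwise_nonhomogeneous", panel4, cats3)
  X <- agreement_design(sp, agree_coding = "dummy")
  cells <- attr(X, "cells")
  col <- X[, "agree(E1:CAD)=equivocal"]
  manual <- as.numeric(cells$E1 == "equivocal" & cells$CAD == "equivocal")
  expect_equal(col, manual, ignore_attr = TRUE)
  # effect coding is the +/-1 recoding of the same indicator
  Xe <- agreement_design(sp, agree_coding = "effect")
  expect_equal(Xe[, "agree(E1:CAD)=equivocal"], 2 * manual - 1,
               ignore_attr = TRUE)
})

test_that("ladder names validate rater counts", {
  expect_error(agreement_spec("pairwise_homogeneous", c("A", "B"), cats3),
               "at least 3")
  expect_error(agreement_spec("threeway_nonhomogeneous", c("A", "B"), cats3),
               "at least 3")
  expect_error(agreement_spec("custom", c("A", "B"), cats3,
                              terms = list(list(subset = "A"))),
               ">= 2 raters")
})

test_that("nesting is decided by column-space containment", {
  two <- c("RENEX", "consensus")
  ind <- agreement_spec("independence", two, cats3)
  hom <- agreement_spec("homogeneous", two, cats3)
  non <- agreement_spec("nonhomogeneous", two, cats3)
  expect_true(nested(ind, hom))
  expect_true(nested(hom, non))  # equal strengths recover the shared model
  expect_false(nested(non, hom))

  p_hom <- agreement_spec("pairwise_homogeneous", panel4, cats3)
  p_non <- agreement_spec("pairwise_nonhomogeneous", panel4, cats3)
  t_non <- agreement_spec("threeway_nonhomogeneous", panel4, cats3)
  ind4 <- agreement_spec("independence", panel4, cats3)
  expect_true(nested(ind4, p_hom))
  expect_true(nested(p_hom, p_non))
  expect_false(nested(p_non, t_non))  # triples replace pairs, not extend
})

test_that("binary scale: by-category agreement is one parameter beyond shared, and saturates", {
  two <- c("A", "B")
  hom <- agreement_spec("homogeneous", two, c("neg", "pos"))
  non <- agreement_spec("nonhomogeneous", two, c("neg", "pos"))
  expect_identical(residual_df(hom) - residual_df(non), 1L)
  # with two categories the second diagonal indicator is a linear
  # combination of intercept, main effects and the first indicator, so the
  # by-category design is rank deficient and refused by construction
  expect_error(agreement_design(non), "rank deficient")
})

test_that("specs serialize to JSON and back", {
  sp <- agreement_spec("pairwise_nonhomogeneous", panel4, cats3)
  sp2 <- spec_from_json(spec_to_json(sp))
  expect_equal(sp2$raters, sp$raters)
  expect_equal(sp2$categories, sp$categories)
  expect_equal(length(sp2$terms), length(sp$terms))
  expect_identical(agreement_design(sp2), agreement_design(sp))
})
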