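#' CAD-versus-reference-reader agreement analysis
#'
#' The two-rater workflow: fits the nested ladder independence ->
#' homogeneous -> non-homogeneous diagonal agreement, selects the simplest
#' adequate model at `selection_alpha`, tests each category-specific
#' agreement coefficient of the non-homogeneous fit at the more
#' conservative `test_alpha` (multiple comparisons), and computes the
#' classical comparators: per-category percent agreement against the
#' second (reference) rater and unweighted/linear-weighted kappa.
#'
#' @param table a two-rater [rating_table()] whose second rater is the
#'   reference reading.
#' @param selection_alpha model-selection level (default 0.05).
#' @param test_alpha coefficient-test level (default 0.01).
#' @param ... passed to [agree_loglin()].
#' @return object of class `consensus_analysis`.
#' @export
consensus_analysis <- function(table, selection_alpha = 0.05,
                               test_alpha = 0.01, ...) {
  if (length(raters(table)) != 2L)
    stop("consensus analysis needs a two-rater table")
  ladder <- model_ladder(table,
                         c("independence", "homogeneous", "nonhomogeneous"),
                         selection_alpha = selection_alpha, ...)
  nh <- ladder$fits[["nonhomogeneous"]]
  sm <- suppressWarnings(summary(nh))$coefficients
  agr <- grep("^agree\\(", rownames(sm))
  coefs <- data.frame(
    category = sub(".*=", "", rownames(sm)[agr]),
    estimate = sm[agr, "Estimate"],
    se = sm[agr, "Std. Error"],
    p.value = sm[agr, "Pr(>|z|)"],
    stringsAsFactors = FALSE)
  coefs$significant <- coefs$p.value < test_alpha
  rownames(coefs) <- NULL
  structure(list(
    ladder = ladder,
    coefficients = coefs,
    percent_agreement = percent_agreement(table),
    kappa = cohen_kappa(table, "none"),
    kappa_linear = cohen_kappa(table, "linear"),
    selection_alpha = selection_alpha, test_alpha = test_alpha),
    class = "consensus_analysis")
}

#' @export
print.consensus_analysis <- function(x, ...) {
  print(x$ladder)
  cat("\nCategory-specific agreement (non-homogeneous model, alpha =",
      format(x$test_alpha), "):\n")
  co <- x$coefficients
  co$estimate <- round(co$estimate, 2)
  co$se <- round(co$se, 2)
  co$p.value <- signif(co$p.value, 2)
  print(co, row.names = FALSE)
  cat("\nPercent agreement with the reference reading:\n")
  pa <- x$percent_agreement
  pa$proportion <- round(pa$proportion, 2)
  print(pa, row.names = FALSE)
  cat("\n")
  print(x$kappa)
  print(x$kappa_linear)
  invisible(x)
}

#' Multi-rater panel analysis: is the CAD reader equivalent to an expert?
#'
#' Fits the independence -> homogeneous -> non-homogeneous ladder of
#' pairwise (or three-way) agreement models on the K-rater table, selects
#' at `selection_alpha`, and — when the category-specific rung is selected
#' — runs the named expert-equivalence Wald tests of
#' [equivalence_tests()] at `test_alpha`.
#'
#' @param table a [rating_table()] with K >= 3 raters.
#' @param cad_rater identifier of the CAD reader in `raters(table)`.
#' @param mode `"pairwise"` or `"threeway"` agreement structure.
#' @inheritParams consensus_analysis
#' @return object of class `panel_analysis`.
#' @export
panel_analysis <- function(table, cad_rater,
                           mode = c("pairwise", "threeway"),
                           selection_alpha = 0.05, test_alpha = 0.01, ...) {
  mode <- match.arg(mode)
  if (length(raters(table)) < 3L)
    stop("panel analysis needs at least 3 raters")
  if (!cad_rater %in% raters(table))
    stop("`", cad_rater, "` is not a rater of this table")
  models <- c("independence", paste0(mode, "_homogeneous"),
              paste0(mode, "_nonhomogeneous"))
  ladder <- model_ladder(table, models, selection_alpha = selection_alpha,
                         ...)
  equiv <- NULL
  if (ladder$selected == paste0(mode, "_nonhomogeneous"))
    equiv <- equivalence_tests(ladder$fit, cad_rater)
  if (!is.null(equiv)) equiv$significant <- equiv$p.value < test_alpha
  structure(list(ladder = ladder, mode = mode, cad_rater = cad_rater,
                 equivalence = equiv,
                 selection_alpha = selection_alpha, test_alpha = test_alpha),
            class = "panel_analysis")
}

#' @export
print.panel_analysis <- function(x, ...) {
  print(x$ladder)
  if (is.null(x$equivalence)) {
    cat("\nEquivalence tests skipped: the category-specific model was not",
        "selected.\n")
  } else {
    cat(sprintf("\nExpert-equivalence tests (CAD reader: %s, alpha = %s):\n",
                x$cad_rater, format(x$test_alpha)))
    eq <- x$equivalence
    eq$statistic <- round(eq$statistic, 2)
    eq$p.value <- signif(eq$p.value, 2)
    print(eq, row.names = FALSE)
  }
  invisible(x)
}
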