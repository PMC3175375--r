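#' Likelihood-ratio test between nested agreement models
#'
#' The improvement-in-fit test: statistic = G2(reduced) - G2(full) on
#' df(reduced) - df(full), referred to the chi-square upper tail.  Nesting
#' is verified via [nested()] and both fits must be on the same table.
#'
#' @param fit_reduced,fit_full [agree_loglin()] fits of nested specs on
#'   the same table.
#' @return an `agree_htest`: list with `kind`, `statistic`, `df`,
#'   `p.value`, `constraint`.
#' @export
lr_test <- function(fit_reduced, fit_full) {
  if (!identical(unclass(fit_reduced$table), unclass(fit_full$table)))
    stop("fits are not on the same table")
  if (!nested(fit_reduced$spec, fit_full$spec))
    stop("`", fit_reduced$spec$model, "` is not nested in `",
         fit_full$spec$model, "`")
  df <- fit_reduced$df.residual - fit_full$df.residual
  if (df < 1L)
    stop("degenerate comparison: the models have the same dimension")
  stat <- max(fit_reduced$deviance - fit_full$deviance, 0)
  new_htest("likelihood_ratio", stat, df,
            sprintf("%s vs %s", fit_reduced$spec$model, fit_full$spec$model))
}

new_htest <- function(kind, stat, df, constraint) {
  structure(list(kind = kind, statistic = stat, df = as.integer(df),
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 constraint = constraint),
            class = "agree_htest")
}

#' @export
print.agree_htest <- function(x, ...) {
  cat(sprintf("%s test: %s\n  chi-square = %.3f, df = %d, p = %.3g\n",
              x$kind, x$constraint, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Wald test of linear hypotheses on fitted coefficients
#'
#' Tests `L beta = 0` with statistic
#' `(L b)' (L V L')^{-1} (L b) ~ chi-square(rows of L)`.  A hypothesis that
#' three strengths are equal is encoded as two independent difference rows.
#'
#' @param fit an [agree_loglin()] fit.
#' @param L named numeric vector (one constraint row; names are coefficient
#'   labels, unnamed coefficients count as 0) or a matrix with one row per
#'   constraint and columns named after coefficients.
#' @param constraint optional human-readable description.
#' @return an `agree_htest`.
#' @examples
#' tab <- rating_table(c(101, 7, 1, 14, 13, 2, 5, 9, 33),
#'                     raters = c("RENEX", "consensus"),
#'                     categories = c("non-obstructed", "equivocal", "obstructed"))
#' fit <- agree_loglin(tab, "nonhomogeneous")
#' wald_test(fit, c("agree(RENEX:consensus)=equivocal" = 1))
#' @export
wald_test <- function(fit, L, constraint = NULL) {
  b <- fit$coefficients
  if (is.vector(L)) L <- matrix(L, nrow = 1L, dimnames = list(NULL, names(L)))
  if (is.null(colnames(L))) stop("constraint columns must be named")
  unknown <- setdiff(colnames(L), names(b))
  if (length(unknown))
    stop("unknown parameter(s) in constraint: ",
         paste(unknown, collapse = ", "))
  Lfull <- matrix(0, nrow(L), length(b), dimnames = list(NULL, names(b)))
  Lfull[, colnames(L)] <- L
  if (any(rowSums(abs(Lfull)) == 0))
    stop("degenerate constraint: a row has all-zero coefficients")
  if (qr(Lfull)$rank < nrow(Lfull))
    stop("constraint rows are linearly dependent")
  Lb <- drop(Lfull %*% b)
  M <- Lfull %*% fit$vcov %*% t(Lfull)
  Minv <- tryCatch(solve(M), error = function(e)
    stop("singular constraint covariance (collinear constraint): ",
         paste(apply(L, 1L, function(r)
           paste(sprintf("%+g*%s", r[r != 0],
                         colnames(L)[r != 0]), collapse = " ")),
           collapse = "; "), call. = FALSE))
  stat <- drop(t(Lb) %*% Minv %*% Lb)
  if (is.null(constraint))
    constraint <- paste(apply(Lfull, 1L, function(r)
      paste(sprintf("%+g*%s", r[r != 0], names(b)[r != 0]),
            collapse = " ")), "= 0", collapse = "; ")
  new_htest("wald", stat, nrow(Lfull), constraint)
}

# rows encoding a1 = a2 = ... = ak as k-1 adjacent differences
equality_rows <- function(labels) {
  k <- length(labels)
  L <- matrix(0, k - 1L, k, dimnames = list(NULL, labels))
  for (i in seq_len(k - 1L)) {
    L[i, i] <- 1; L[i, i + 1L] <- -1
  }
  L
}

#' Expert-equivalence hypothesis tests for a CAD reader
#'
#' Given a category-specific pairwise or three-way fit and the identity of
#' the CAD rater, partitions the agreement terms into "within experts"
#' (subsets excluding the CAD rater) and "involving CAD", and emits, per
#' category m:
#'
#' * pairwise specs — `experts_equal` (all within-expert pair strengths
#'   equal), `cad_pairs_equal` (all CAD-expert pair strengths equal), and
#'   `experts_vs_cad` (sum of within-expert strengths = sum of CAD-expert
#'   strengths);
#' * three-way specs — `triple_vs_cad_triples` (the all-expert triple
#'   strength equals the mean of the CAD-containing triple strengths).
#'
#' Non-rejection of `experts_vs_cad` / `triple_vs_cad_triples` is the
#' operational meaning of "the CAD system is equivalent to an expert":
#' agreement is statistically unchanged when the CAD reader replaces an
#' expert in a pair or triple.
#'
#' @param fit a `pairwise_nonhomogeneous` or `threeway_nonhomogeneous`
#'   [agree_loglin()] fit.
#' @param cad_rater rater identifier of the CAD system.
#' @return data.frame with columns `category`, `hypothesis`, `statistic`,
#'   `df`, `p.value`; the underlying `agree_htest` objects are in
#'   attribute `"tests"`.
#' @export
equivalence_tests <- function(fit, cad_rater) {
  spec <- fit$spec
  if (!cad_rater %in% spec$raters)
    stop("`", cad_rater, "` is not a rater of this fit")
  if (!spec$model %in% c("pairwise_nonhomogeneous",
                         "threeway_nonhomogeneous"))
    stop("equivalence tests need a category-specific pairwise or ",
         "three-way fit (got `", spec$model, "`)")
  has_cad <- vapply(spec$terms, function(t) cad_rater %in% t$subset,
                    logical(1))
  lab <- function(t, m)
    paste0("agree(", paste(t$subset, collapse = ":"), ")=", m)
  tests <- list()
  rows <- list()
  for (m in spec$categories) {
    d_lab <- vapply(spec$terms[!has_cad], lab, character(1), m = m)
    t_lab <- vapply(spec$terms[has_cad], lab, character(1), m = m)
    if (spec$model == "pairwise_nonhomogeneous") {
      hyps <- list(
        experts_equal = wald_test(fit, equality_rows(d_lab),
          sprintf("[%s] equal within-expert pair strengths", m)),
        cad_pairs_equal = wald_test(fit, equality_rows(t_lab),
          sprintf("[%s] equal CAD-expert pair strengths", m)),
        experts_vs_cad = wald_test(fit,
          stats::setNames(c(rep(1, length(d_lab)), rep(-1, length(t_lab))),
                          c(d_lab, t_lab)),
          sprintf("[%s] sum of expert pair strengths = sum of CAD pair strengths",
                  m)))
    } else {
      hyps <- list(
        triple_vs_cad_triples = wald_test(fit,
          stats::setNames(c(rep(1, length(d_lab)),
                            rep(-1 / length(t_lab), length(t_lab))),
                          c(d_lab, t_lab)),
          sprintf("[%s] expert triple strength = mean CAD triple strength",
                  m)))
    }
    for (h in names(hyps)) {
      tests[[paste(m, h, sep = ".")]] <- hyps[[h]]
      rows[[paste(m, h, sep = ".")]] <- data.frame(
        category = m, hypothesis = h,
        statistic = hyps[[h]]$statistic, df = hyps[[h]]$df,
        p.value = hyps[[h]]$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  out
}

#' Fit a nested ladder of agreement models and select the simplest
#' adequate one
#'
#' Fits the named models in order (each must be nested in the next),
#' computes the goodness-of-fit p-value of each rung, and selects the
#' first whose p-value is at or above `selection_alpha` — the simplest
#' model that adequately describes the agreement structure.  If no rung is
#' adequate the last one is returned, flagged inadequate.
#'
#' @param table a [rating_table()].
#' @param models character vector of ladder-model names, simplest first.
#' @param selection_alpha adequacy threshold for the goodness-of-fit
#'   p-value (default 0.05).
#' @param ... passed to [agree_loglin()].
#' @return an `agree_ladder`: list with `trace` (data.frame of model, G2,
#'   df, p.value, adequate), `selected` (model name), `fit` (the selected
#'   fit), `fits` (all fits), `adequate` (logical).
#' @examples
#' tab <- rating_table(c(101, 7, 1, 14, 13, 2, 5, 9, 33),
#'                     raters = c("RENEX", "consensus"),
#'                     categories = c("non-obstructed", "equivocal", "obstructed"))
#' model_ladder(tab, c("independence", "homogeneous", "nonhomogeneous"))
#' @export
model_ladder <- function(table,
                         models = c("independence", "homogeneous",
                                    "nonhomogeneous"),
                         selection_alpha = 0.05, ...) {
  fits <- lapply(models, function(m) agree_loglin(table, model = m, ...))
  names(fits) <- models
  for (i in seq_along(models)[-1L])
    if (!nested(fits[[i - 1L]]$spec, fits[[i]]$spec))
      stop("ladder is not nested at rung `", models[i], "`")
  gof <- suppressWarnings(lapply(fits, goodness_of_fit))
  trace <- data.frame(
    model = models,
    G2 = vapply(gof, `[[`, numeric(1), "statistic"),
    df = vapply(gof, `[[`, integer(1), "df"),
    p.value = vapply(gof, `[[`, numeric(1), "p.value"),
    stringsAsFactors = FALSE)
  trace$adequate <- trace$p.value >= selection_alpha
  sel <- if (any(trace$adequate)) which(trace$adequate)[1L] else length(models)
  sparse <- mean(fits[[sel]]$fitted < 5)
  if (sparse > 0.2)
    warning(sprintf(
      "%.0f%% of fitted counts under the selected model are below 5; G2 p-values rely on a doubtful chi-square approximation",
      100 * sparse), call. = FALSE)
  structure(list(trace = trace, selected = models[sel], fit = fits[[sel]],
                 fits = fits, adequate = trace$adequate[sel],
                 selection_alpha = selection_alpha),
            class = "agree_ladder")
}

#' @export
print.agree_ladder <- function(x, ...) {
  cat("Nested agreement-model ladder:\n")
  tr <- x$trace
  tr$G2 <- sprintf("%.2f", tr$G2)
  tr$p.value <- signif(tr$p.value, 2)
  print(tr, row.names = FALSE)
  cat(sprintf("Selected (goodness-of-fit p >= %.2g): %s%s\n",
              x$selection_alpha, x$selected,
              if (x$adequate) "" else " [no adequate rung; last returned]"))
  invisible(x)
}
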