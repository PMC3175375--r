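#' Per-category percent agreement against a reference reader
#'
#' For a two-rater table whose *second* rater is the reference (e.g. the
#' expert consensus), the proportion of the reference reader's
#' category-m subjects that the first rater also called m: diagonal cell
#' over reference margin.
#'
#' @param table a two-rater [rating_table()].
#' @param category a category label, or `NULL` for all categories.
#' @return data.frame with `category`, `agree` (numerator), `total`
#'   (reference-margin denominator), `proportion` (`NA` when the
#'   denominator is zero).
#' @examples
#' tab <- rating_table(c(101, 7, 1, 14, 13, 2, 5, 9, 33),
#'                     raters = c("RENEX", "consensus"),
#'                     categories = c("non-obstructed", "equivocal", "obstructed"))
#' percent_agreement(tab)  # 101/120, 13/29, 33/36
#' @export
percent_agreement <- function(table, category = NULL) {
  if (length(raters(table)) != 2L)
    stop("percent agreement is defined for two-rater tables")
  cats <- categories(table)
  if (is.null(category)) category <- cats
  if (!all(category %in% cats))
    stop("unknown category: ", paste(setdiff(category, cats), collapse = ", "))
  a <- unclass(table)
  ref_margin <- colSums(a)  # second rater indexes the columns
  idx <- match(category, cats)
  agree <- diag(a)[idx]
  total <- ref_margin[idx]
  data.frame(category = category, agree = unname(agree),
             total = unname(total),
             proportion = unname(ifelse(total > 0, agree / total, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Cohen's kappa and weighted kappa
#'
#' Chance-corrected agreement for a two-rater table:
#' `kappa = (po - pe) / (1 - pe)` with
#' `po = sum(w_ij p_ij)` and `pe = sum(w_ij p_i. p_.j)`.
#' Weights on the declared category *order*:
#' `none` w = 1 on the diagonal, 0 off;
#' `linear` `w = 1 - |i-j|/(C-1)`; `quadratic` `w = 1 - (|i-j|/(C-1))^2`.
#'
#' @param table a two-rater [rating_table()] with n >= 1.
#' @param weighting `"none"`, `"linear"` or `"quadratic"`.
#' @return object of class `kappa_result`: list with `estimate`,
#'   `weighting`, `observed_agreement`, `expected_agreement`.  When the
#'   margins are degenerate (`pe = 1`) the estimate is `NA` and
#'   `degenerate = TRUE`.
#' @examples
#' tab <- rating_table(c(101, 7, 1, 14, 13, 2, 5, 9, 33),
#'                     raters = c("RENEX", "consensus"),
#'                     categories = c("non-obstructed", "equivocal", "obstructed"))
#' cohen_kappa(tab)                       # ~0.62
#' cohen_kappa(tab, "linear")             # ~0.71
#' @export
cohen_kappa <- function(table, weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  if (length(raters(table)) != 2L)
    stop("kappa is defined for two-rater tables")
  a <- unclass(table)
  n <- sum(a)
  if (n < 1) stop("table is empty")
  C <- ncol(a)
  d <- abs(outer(seq_len(C), seq_len(C), `-`)) / (C - 1)
  w <- switch(weighting,
              none = (d == 0) + 0,
              linear = 1 - d,
              quadratic = 1 - d^2)
  p <- a / n
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  degenerate <- abs(1 - pe) < 1e-12
  est <- if (degenerate) NA_real_ else (po - pe) / (1 - pe)
  structure(list(estimate = est, weighting = weighting,
                 observed_agreement = po, expected_agreement = pe,
                 degenerate = degenerate, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("kappa (%s weights): %s\n", x$weighting,
              if (x$degenerate) "undefined (degenerate margins)"
              else sprintf("%.3f", x$estimate)))
  cat(sprintf("  observed agreement %.3f, expected by chance %.3f, n = %d\n",
              x$observed_agreement, x$expected_agreement, as.integer(x$n)))
  invisible(x)
}
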