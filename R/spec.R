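#' Declarative agreement-model specifications
#'
#' An `agreement_spec` names the chance (main-effect) structure shared by
#' every model and a collection of beyond-chance agreement terms.  Each term
#' is an unordered rater subset plus a flag: `category_specific = FALSE`
#' gives one shared agreement strength for the subset, `TRUE` one strength
#' per category.  The built-in ladder:
#'
#' * `independence` — no agreement terms (chance only)
#' * `homogeneous` / `nonhomogeneous` — a single term on the full rater set
#'   (the two-rater diagonal-agreement models)
#' * `pairwise_homogeneous` / `pairwise_nonhomogeneous` — one term per
#'   unordered rater pair (requires K >= 3)
#' * `threeway_homogeneous` / `threeway_nonhomogeneous` — one term per
#'   unordered rater triple, *replacing* the pairwise terms (K >= 3)
#' * `custom` — caller-supplied `terms`
#'
#' @param model one of the ladder names above.
#' @param raters,categories as in [rating_table()].
#' @param terms for `model = "custom"`: list of
#'   `list(subset = <raters>, category_specific = <flag>)`.
#' @return an object of class `agreement_spec`.
#' @examples
#' agreement_spec("nonhomogeneous", c("CAD", "consensus"), c("neg", "eq", "pos"))
#' @export
agreement_spec <- function(model = c("independence", "homogeneous",
                                     "nonhomogeneous",
                                     "pairwise_homogeneous",
                                     "pairwise_nonhomogeneous",
                                     "threeway_homogeneous",
                                     "threeway_nonhomogeneous", "custom"),
                           raters, categories, terms = NULL) {
  model <- match.arg(model)
  raters <- as.character(raters); categories <- as.character(categories)
  K <- length(raters)
  if (K < 2L) stop("need at least 2 raters")
  if (length(categories) < 2L) stop("need at least 2 categories")
  spec_cs <- grepl("nonhomogeneous", model)
  if (model == "independence") {
    terms <- list()
  } else if (model %in% c("homogeneous", "nonhomogeneous")) {
    terms <- list(list(subset = raters, category_specific = spec_cs))
  } else if (grepl("^pairwise", model)) {
    if (K < 3L)
      stop("pairwise models need at least 3 raters; ",
           "with 2 raters use homogeneous/nonhomogeneous")
    terms <- lapply(utils::combn(raters, 2L, simplify = FALSE), function(s)
      list(subset = s, category_specific = spec_cs))
  } else if (grepl("^threeway", model)) {
    if (K < 3L) stop("three-way models need at least 3 raters")
    terms <- lapply(utils::combn(raters, 3L, simplify = FALSE), function(s)
      list(subset = s, category_specific = spec_cs))
  } else {
    if (is.null(terms)) stop("custom specs need `terms`")
    terms <- lapply(terms, function(t) {
      t$subset <- as.character(t$subset)
      if (length(t$subset) < 2L || !all(t$subset %in% raters))
        stop("each term subset must be >= 2 raters drawn from `raters`")
      t$category_specific <- isTRUE(t$category_specific)
      t
    })
  }
  structure(list(model = model, raters = raters, categories = categories,
                 terms = terms),
            class = "agreement_spec")
}

#' @export
print.agreement_spec <- function(x, ...) {
  cat(sprintf("agreement_spec: %s (K = %d raters, C = %d categories)\n",
              x$model, length(x$raters), length(x$categories)))
  for (t in x$terms)
    cat(sprintf("  agree(%s)%s\n", paste(t$subset, collapse = ","),
                if (t$category_specific) " by category" else " shared"))
  invisible(x)
}

#' @rdname agreement_spec
#' @param x an `agreement_spec`.
#' @export
n_parameters <- function(x) {
  C <- length(x$categories)
  1L + length(x$raters) * (C - 1L) +
    sum(vapply(x$terms, function(t) if (t$category_specific) C else 1L,
               integer(1)))
}

#' @rdname agreement_spec
#' @return `residual_df()`: cells minus free parameters, `C^K - p`.
#' @export
residual_df <- function(x) {
  as.integer(length(x$categories)^length(x$raters)) - n_parameters(x)
}

#' Design matrix of an agreement model
#'
#' Encodes a spec over the C^K cells (rows in canonical order, see
#' [cell_grid()]).  Columns: intercept; K*(C-1) main-effect columns; one
#' agreement column per (term, category) or per term.  Main effects use
#' reference coding against the last category by default, or sum-to-zero
#' coding; agreement indicators use effect coding (+1 where all raters in
#' the subset read the category, -1 elsewhere) by default, matching the
#' parameterization under which the published two-rater estimates
#' (e.g. 1.57 for non-obstructed CAD-consensus agreement) are reported,
#' or plain 0/1 dummies.  Deviance, fitted counts and every contrast test
#' are invariant to either choice; dummy-coded agreement estimates are
#' exactly twice the effect-coded ones.
#'
#' @param spec an [agreement_spec()].
#' @param main_coding `"reference"` (last category baseline) or `"sum"`.
#' @param agree_coding `"effect"` (+1/-1) or `"dummy"` (1/0).
#' @return numeric matrix with labelled columns and attribute `"cells"`
#'   (the [cell_grid()] data.frame).
#' @export
agreement_design <- function(spec, main_coding = c("reference", "sum"),
                             agree_coding = c("effect", "dummy")) {
  main_coding <- match.arg(main_coding)
  agree_coding <- match.arg(agree_coding)
  cats <- spec$categories
  C <- length(cats); K <- length(spec$raters)
  cells <- cell_grid(spec$raters, cats)
  ncell <- C^K
  cols <- list(`(Intercept)` = rep(1, ncell))
  for (r in spec$raters) {
    rc <- as.character(cells[[r]])
    for (m in cats[-C]) {
      v <- as.numeric(rc == m)
      if (main_coding == "sum") v <- v - as.numeric(rc == cats[C])
      cols[[paste0(r, "=", m)]] <- v
    }
  }
  for (t in spec$terms) {
    sub <- cells[t$subset]
    lab <- paste0("agree(", paste(t$subset, collapse = ":"), ")")
    if (t$category_specific) {
      for (m in cats) {
        v <- as.numeric(Reduce(`&`, lapply(sub, function(cl) cl == m)))
        if (agree_coding == "effect") v <- 2 * v - 1
        cols[[paste0(lab, "=", m)]] <- v
      }
    } else {
      idx <- vapply(sub, as.integer, integer(ncell))
      v <- as.numeric(apply(idx, 1L, function(z) all(z == z[1L])))
      if (agree_coding == "effect") v <- 2 * v - 1
      cols[[lab]] <- v
    }
  }
  X <- do.call(cbind, cols)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dep <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qr_X$pivot[seq_len(qr_X$rank)])]
    stop("design is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  attr(X, "cells") <- cells
  attr(X, "main_coding") <- main_coding
  attr(X, "agree_coding") <- agree_coding
  X
}

#' Is one agreement model nested in another?
#'
#' TRUE when every design column of `spec_a` lies in the column space of
#' `spec_b`'s design (checked by projection residual), so that the
#' likelihood-ratio test of `spec_a` against `spec_b` is valid.
#'
#' @param spec_a,spec_b [agreement_spec()] objects on the same raters and
#'   categories.
#' @export
nested <- function(spec_a, spec_b) {
  if (!identical(spec_a$raters, spec_b$raters) ||
      !identical(spec_a$categories, spec_b$categories))
    stop("specs must share raters and categories")
  A <- agreement_design(spec_a)
  B <- agreement_design(spec_b)
  resid <- A - B %*% qr.coef(qr(B), A)
  max(abs(resid)) < 1e-8
}

#' Serialize / deserialize a spec as JSON
#'
#' @param spec an [agreement_spec()].
#' @param path optional file; when omitted the JSON string is returned.
#' @export
spec_to_json <- function(spec, path = NULL) {
  doc <- list(model = spec$model, raters = spec$raters,
              categories = spec$categories,
              terms = lapply(spec$terms, function(t)
                list(subset = t$subset,
                     category_specific = t$category_specific)))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname spec_to_json
#' @param json JSON string or file path.
#' @export
spec_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  agreement_spec(doc$model %||% "custom", doc$raters, doc$categories,
                 terms = doc$terms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
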