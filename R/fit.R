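#' Fit a log-linear agreement model by Poisson maximum likelihood
#'
#' The expected count in each cell of the K-way table is modelled as
#' `log mu = X beta`, where X is the design of [agreement_design()]:
#' an overall effect, per-rater main effects (the chance component), and
#' beyond-chance agreement terms.  Estimation is Newton scoring on the
#' Poisson log-likelihood `sum(y * log(mu) - mu)` with step-halving,
#' started from the closed-form independence fit (log product-of-margins
#' expected counts, floored at a small positive constant).  The parameter
#' covariance is the inverse Fisher information at the optimum, and the
#' goodness-of-fit deviance is `G2 = 2 * sum(y * log(y / mu))` over
#' non-empty cells, referred to a chi-square on `C^K - p` residual df.
#'
#' Sampling zeros are kept with their structural role; when the data give
#' an agreement parameter no support (e.g. every cell its indicator covers
#' is empty) the likelihood has no finite maximizer and the fit aborts
#' naming the runaway parameter.
#'
#' @param table a [rating_table()].
#' @param model ladder-model name passed to [agreement_spec()]; ignored
#'   when `spec` is given.
#' @param spec an [agreement_spec()] (overrides `model`).
#' @param main_coding,agree_coding see [agreement_design()].
#' @param control list: `max_iter` (default 100), `tol_score` (1e-8,
#'   largest absolute score component allowed at convergence),
#'   `tol_loglik` (1e-10, relative log-likelihood change).  Convergence
#'   also triggers when the Newton step falls below 1e-10 in every
#'   coordinate, which covers large tables whose score cannot reach the
#'   absolute tolerance in double precision.
#' @return an object of class `agree_loglin` with components
#'   `coefficients`, `vcov`, `fitted` (cell counts, canonical order),
#'   `deviance` (G2), `df.residual`, `converged`, `iter`, `spec`,
#'   `table`, `design`.
#' @examples
#' tab <- rating_table(c(101, 7, 1, 14, 13, 2, 5, 9, 33),
#'                     raters = c("RENEX", "consensus"),
#'                     categories = c("non-obstructed", "equivocal", "obstructed"))
#' fit <- agree_loglin(tab, "nonhomogeneous")
#' summary(fit)
#' @export
agree_loglin <- function(table, model = "nonhomogeneous", spec = NULL,
                         main_coding = c("reference", "sum"),
                         agree_coding = c("effect", "dummy"),
                         control = list()) {
  stopifnot(inherits(table, "rating_table"))
  if (is.null(spec))
    spec <- agreement_spec(model, raters(table), categories(table))
  if (!identical(spec$raters, raters(table)) ||
      !identical(spec$categories, categories(table)))
    stop("spec raters/categories do not match the table")
  y <- cell_counts(table)
  n <- sum(y)
  if (n < 1) stop("table is empty")
  X <- agreement_design(spec, match.arg(main_coding), match.arg(agree_coding))
  # an agreement indicator whose active cells are all empty (or all
  # occupied while the rest are empty) has no finite ML estimate
  for (j in grep("^agree\\(", colnames(X))) {
    active <- X[, j] == max(X[, j])
    if (sum(y[active]) == 0 || sum(y[!active]) == 0)
      stop("estimate for `", colnames(X)[j], "` is diverging: ",
           "its indicator covers ",
           if (sum(y[active]) == 0) "only empty cells"
           else "all non-empty cells", call. = FALSE)
  }
  ctrl <- utils::modifyList(
    list(max_iter = 100L, tol_score = 1e-8, tol_loglik = 1e-10), control)

  # start: closed-form independence expected counts
  mu0 <- independence_fitted(table)
  beta <- qr.coef(qr(X), log(pmax(mu0, 1e-8)))
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  ll <- sum(y * eta - mu)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(ctrl$max_iter)) {
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X, X * mu)
    step <- tryCatch(solve(info, score), error = function(e) {
      stop("Fisher information is singular at iteration ", iter,
           "; the model is not estimable on this table", call. = FALSE)
    })
    # step-halving on the log-likelihood
    fac <- 1
    repeat {
      beta_new <- beta + fac * step
      eta_new <- drop(X %*% beta_new)
      mu_new <- exp(eta_new)
      ll_new <- sum(y * eta_new - mu_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10)
        stop("step-halving failed to improve the likelihood at iteration ",
             iter, call. = FALSE)
    }
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    beta <- beta_new; eta <- eta_new; mu <- mu_new; ll <- ll_new
    if (max(abs(beta)) > 30) {
      runaway <- colnames(X)[which.max(abs(beta))]
      stop("estimate for `", runaway, "` is diverging ",
           "(its indicator pattern has no support in the data)",
           call. = FALSE)
    }
    score <- drop(crossprod(X, y - mu))
    # score test is absolute (count units); the step test is the scale-free
    # escape for large n, where rounding noise keeps the score above
    # tolerance even at the fixed point
    if ((max(abs(score)) < ctrl$tol_score ||
         max(abs(fac * step)) < 1e-10) && rel < ctrl$tol_loglik) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop(sprintf(
      "no convergence in %d iterations (max |score| = %.3g); last estimates: %s",
      ctrl$max_iter, max(abs(drop(crossprod(X, y - mu)))),
      paste(sprintf("%s=%.3g", colnames(X), beta), collapse = ", ")),
      call. = FALSE)
  vc <- solve(crossprod(X, X * mu))
  dimnames(vc) <- list(colnames(X), colnames(X))
  g2 <- 2 * sum(y[y > 0] * log(y[y > 0] / mu[y > 0]))
  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    vcov = vc,
    fitted = stats::setNames(mu, apply(attr(X, "cells"), 1L, paste,
                                       collapse = ",")),
    deviance = g2,
    df.residual = length(y) - ncol(X),
    converged = converged,
    iter = iter,
    spec = spec,
    table = table,
    design = X,
    n = n
  ), class = "agree_loglin")
}

# closed-form expected counts under independence: product of the K observed
# margins over n^(K-1)
independence_fitted <- function(table) {
  y <- cell_counts(table)
  n <- sum(y)
  cells <- cell_grid(raters(table), categories(table))
  mu <- rep(n^(1 - length(raters(table))), length(y))
  for (r in raters(table)) {
    marg <- marginalize(table, r)
    mu <- mu * marg[as.integer(cells[[r]])]
  }
  unname(mu)
}

#' @export
print.agree_loglin <- function(x, ...) {
  cat(sprintf("Log-linear agreement model: %s\n", x$spec$model))
  cat(sprintf("  G2 = %.2f on %d df (p = %.3g), n = %d, %d iterations\n",
              x$deviance, x$df.residual,
              stats::pchisq(x$deviance, x$df.residual, lower.tail = FALSE),
              as.integer(x$n), x$iter))
  agr <- grep("^agree\\(", names(x$coefficients))
  if (length(agr)) {
    cat("Agreement coefficients:\n")
    print(round(x$coefficients[agr], 3))
  }
  invisible(x)
}

#' @export
summary.agree_loglin <- function(object, ...) {
  est <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
                 `Pr(>|z|)` = p)
  gof <- goodness_of_fit(object)
  structure(list(coefficients = coefs, gof = gof, spec = object$spec,
                 n = object$n),
            class = "summary.agree_loglin")
}

#' @export
print.summary.agree_loglin <- function(x, ...) {
  cat(sprintf("Log-linear agreement model: %s (n = %d)\n\n",
              x$spec$model, as.integer(x$n)))
  stats::printCoefmat(x$coefficients, digits = 3, signif.stars = FALSE)
  cat(sprintf("\nGoodness of fit: G2 = %.2f on %d df, p = %.3g\n",
              x$gof$statistic, x$gof$df, x$gof$p.value))
  invisible(x)
}

#' Goodness-of-fit test of a fitted agreement model
#'
#' Chi-square approximation to the deviance G2 on the residual df (the
#' model-vs-saturated likelihood-ratio test).  A warning is issued when
#' more than 20% of fitted counts fall below 5, where the chi-square
#' reference is doubtful.
#'
#' @param fit an [agree_loglin()] fit.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
goodness_of_fit <- function(fit) {
  if (mean(fit$fitted < 5) > 0.2)
    warning(sprintf(
      "%.0f%% of fitted counts are below 5; chi-square approximation to G2 may be poor",
      100 * mean(fit$fitted < 5)), call. = FALSE)
  list(statistic = fit$deviance, df = fit$df.residual,
       p.value = stats::pchisq(fit$deviance, fit$df.residual,
                               lower.tail = FALSE))
}

#' @export
coef.agree_loglin <- function(object, ...) object$coefficients

#' @export
vcov.agree_loglin <- function(object, ...) object$vcov

#' @export
fitted.agree_loglin <- function(object, ...) object$fitted

#' @export
logLik.agree_loglin <- function(object, ...) {
  y <- cell_counts(object$table)
  mu <- object$fitted
  structure(sum(stats::dpois(y, mu, log = TRUE)),
            df = length(object$coefficients), class = "logLik")
}

#' @export
residuals.agree_loglin <- function(object,
                                   type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  y <- cell_counts(object$table)
  mu <- object$fitted
  r <- switch(type,
    pearson = (y - mu) / sqrt(mu),
    deviance = sign(y - mu) *
      sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))))
  stats::setNames(r, names(object$fitted))
}

#' Parametric simulation from a fitted agreement model
#'
#' Draws tables of the same total n by multinomial sampling from the
#' fitted cell probabilities (the parametric-bootstrap generator).
#'
#' @param object an [agree_loglin()] fit.
#' @param nsim number of tables.
#' @param seed optional integer; RNG state is restored on exit.
#' @param ... unused.
#' @return list of [rating_table()] objects.
#' @export
simulate.agree_loglin <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$fitted / sum(object$fitted)
  with_seed(seed, {
    draws <- stats::rmultinom(nsim, size = as.integer(object$n), prob = p)
    lapply(seq_len(nsim), function(j)
      rating_table(draws[, j], raters(object$table),
                   categories(object$table)))
  })
}

# evaluate expr under an optional seed, restoring the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Serialize a fit as JSON
#'
#' Coefficients with labels and standard errors, the covariance matrix,
#' fitted counts in canonical cell order, G2, residual df and convergence
#' metadata.
#'
#' @param fit an [agree_loglin()] fit.
#' @param path optional file; when omitted the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  doc <- list(
    model = fit$spec$model,
    raters = fit$spec$raters,
    categories = fit$spec$categories,
    coefficients = as.list(fit$coefficients),
    se = as.list(stats::setNames(sqrt(diag(fit$vcov)),
                                 names(fit$coefficients))),
    covariance = unname(apply(fit$vcov, 1L, as.list)),
    fitted_counts = unname(fit$fitted),
    G2 = fit$deviance,
    df = fit$df.residual,
    converged = fit$converged,
    iterations = fit$iter
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
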