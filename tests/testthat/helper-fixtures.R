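# shared fixtures: the published 3x3 CAD-vs-consensus table and small
# random-table generators used by the property tests

renog_categories <- function() c("non-obstructed", "equivocal", "obstructed")

table1 <- function() {
  rating_table(c(101, 7, 1, 14, 13, 2, 5, 9, 33),
               raters = c("RENEX", "consensus"),
               categories = renog_categories())
}

# random dense table with all cells positive (keeps ML finite)
random_table <- function(K = 2, C = 3, n = 500) {
  raters <- paste0("R", seq_len(K))
  cats <- paste0("c", seq_len(C))
  p <- stats::rgamma(C^K, shape = 2)
  counts <- drop(stats::rmultinom(1, n, p / sum(p))) + 1
  rating_table(counts, raters, cats)
}

# independent two-rater glm oracle: Poisson fit on factors built straight
# from the cell grid, bypassing the package's design-matrix code
glm_oracle_2x <- function(tab, agreement = c("none", "shared", "by_category")) {
  agreement <- match.arg(agreement)
  cells <- cell_grid(raters(tab), categories(tab))
  y <- cell_counts(tab)
  f1 <- cells[[1L]]
  f2 <- cells[[2L]]
  dat <- data.frame(y = y, f1 = f1, f2 = f2)
  form <- y ~ f1 + f2
  if (agreement == "shared") {
    dat$I <- as.numeric(f1 == f2)
    form <- y ~ f1 + f2 + I
  } else if (agreement == "by_category") {
    for (m in levels(f1)) dat[[paste0("I_", m)]] <- as.numeric(f1 == m & f2 == m)
    form <- stats::reformulate(c("f1", "f2",
                                 paste0("I_", make.names(levels(f1)))),
                               response = "y")
    names(dat) <- make.names(names(dat))
  }
  stats::glm(form, family = stats::poisson(), data = dat)
}
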