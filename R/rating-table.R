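#' K-way contingency tables of rater category assignments
#'
#' A `rating_table` is a dense K-dimensional array of subject counts, one
#' dimension per rater, each dimension indexed by the declared (ordered)
#' category labels.  Zero cells are stored explicitly because the log-linear
#' fitter needs every one of the C^K cells.
#'
#' @param counts either a K-dimensional array with `dim = rep(C, K)`, or a
#'   numeric vector of length `C^K` in canonical cell order (see
#'   [cell_grid()]: the *last* rater's category varies fastest).
#' @param raters character vector of rater identifiers (length K >= 2).
#' @param categories character vector of ordered category labels
#'   (length C >= 2).  Order matters: weighted kappa and reported
#'   category-specific parameters follow it.
#' @return an object of class `rating_table`.
#' @examples
#' tab <- rating_table(c(101, 7, 1, 14, 13, 2, 5, 9, 33),
#'                     raters = c("RENEX", "consensus"),
#'                     categories = c("non-obstructed", "equivocal", "obstructed"))
#' tab
#' @seealso [build_table()] to tabulate long-format records,
#'   [marginalize()] for lower-order views.
#' @export
rating_table <- function(counts, raters, categories) {
  if (missing(raters) || missing(categories)) {
    if (!is.array(counts) || is.null(dimnames(counts)))
      stop("supply `raters` and `categories`, or a named dimnames array")
    categories <- dimnames(counts)[[1L]]
    raters <- names(dimnames(counts))
  }
  raters <- as.character(raters)
  categories <- as.character(categories)
  K <- length(raters); C <- length(categories)
  if (K < 2L) stop("need at least 2 raters")
  if (C < 2L) stop("need at least 2 categories")
  if (anyDuplicated(raters)) stop("duplicated rater identifiers")
  if (anyDuplicated(categories)) stop("duplicated category labels")
  if (is.array(counts)) {
    if (!identical(dim(counts), rep(C, K) + 0L) &&
        !identical(dim(counts), rep(C, K)))
      stop("array dimensions do not match rep(C, K)")
    a <- counts
  } else {
    if (length(counts) != C^K)
      stop(sprintf("expected %d cell counts, got %d", C^K, length(counts)))
    # canonical order has the last rater fastest; R arrays store the first
    # index fastest, so fill reversed and permute back
    a <- aperm(array(counts, dim = rep(C, K)), K:1)
  }
  storage.mode(a) <- "double"
  if (anyNA(a) || any(a < 0)) stop("cell counts must be non-negative and non-missing")
  if (any(a != round(a))) stop("cell counts must be whole numbers")
  dimnames(a) <- stats::setNames(rep(list(categories), K), raters)
  structure(a, class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  K <- length(dim(x))
  cat(sprintf("rating_table: %d raters x %d categories, n = %d\n",
              K, dim(x)[1L], as.integer(sum(x))))
  cat("raters:", paste(raters(x), collapse = ", "), "\n")
  if (K == 2L) {
    print(unclass(x))
  } else {
    cat("(use as.data.frame() or marginalize() to inspect cells)\n")
  }
  invisible(x)
}

#' @rdname rating_table
#' @param x a `rating_table`.
#' @export
raters <- function(x) names(dimnames(x))

#' @rdname rating_table
#' @export
categories <- function(x) dimnames(x)[[1L]]

#' Canonical cell enumeration
#'
#' Cells of a C^K table are enumerated in odometer order over category
#' indices with the last rater varying fastest, so that for two raters the
#' order reads row by row of the printed table.  All cell-count vectors,
#' design-matrix rows and fitted-count vectors in this package use this
#' order.
#'
#' @param raters,categories character vectors as in [rating_table()].
#' @return data.frame with one factor column per rater giving the category
#'   read in each cell.
#' @export
cell_grid <- function(raters, categories) {
  g <- expand.grid(rep(list(factor(categories, levels = categories)),
                       length(raters)))[, length(raters):1, drop = FALSE]
  names(g) <- raters
  rownames(g) <- NULL
  g
}

#' @rdname cell_grid
#' @param x a `rating_table`.
#' @return `cell_counts()`: numeric vector of counts in canonical order.
#' @export
cell_counts <- function(x) {
  K <- length(dim(x))
  as.vector(aperm(unclass(x), K:1))
}

#' @export
as.data.frame.rating_table <- function(x, ...) {
  out <- cell_grid(raters(x), categories(x))
  out$count <- cell_counts(x)
  out
}

#' Tabulate long-format rating records into a contingency table
#'
#' Only subjects rated by *all* requested raters contribute (complete-case);
#' incompletely rated subjects are dropped with a message reporting how many.
#'
#' @param records data.frame with columns `subject`, `rater`, `category`
#'   (extra columns ignored).
#' @param raters ordered rater identifiers to tabulate.
#' @param categories ordered category labels; a record with a category
#'   outside this set is an error.
#' @return a [rating_table()].
#' @examples
#' recs <- data.frame(subject = c(1, 1, 2, 2),
#'                    rater = c("A", "B", "A", "B"),
#'                    category = c("pos", "pos", "neg", "pos"))
#' build_table(recs, c("A", "B"), c("neg", "pos"))
#' @export
build_table <- function(records, raters, categories) {
  records <- as.data.frame(records)
  need <- c("subject", "rater", "category")
  if (!all(need %in% names(records)))
    stop("records must have columns subject, rater, category")
  records <- records[records$rater %in% raters, need, drop = FALSE]
  bad <- setdiff(unique(as.character(records$category)), categories)
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = ", "))
  key <- paste(records$subject, records$rater, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(records$subject[duplicated(key)])
    stop("conflicting duplicate reading(s) for subject(s): ",
         paste(dups, collapse = ", "))
  }
  K <- length(raters)
  tab_empty <- rating_table(rep(0, length(categories)^K), raters, categories)
  if (nrow(records) == 0L) return(tab_empty)
  wide <- split(records, records$subject)
  complete <- vapply(wide, function(d) all(raters %in% d$rater), logical(1))
  if (any(!complete))
    message(sum(!complete), " subject(s) dropped: not rated by all raters")
  wide <- wide[complete]
  if (length(wide) == 0L) return(tab_empty)
  a <- unclass(tab_empty)
  for (d in wide) {
    idx <- match(d$category[match(raters, d$rater)], categories)
    a[matrix(idx, nrow = 1L)] <- a[matrix(idx, nrow = 1L)] + 1
  }
  structure(a, class = "rating_table")
}

#' Expand a contingency table back into long-format records
#'
#' Inverse of [build_table()] up to subject identity: subjects get
#' sequential ids `s1, s2, ...` in canonical cell order.
#'
#' @param x a `rating_table`.
#' @return data.frame with columns `subject`, `rater`, `category`.
#' @export
table_to_records <- function(x) {
  cells <- as.data.frame(x)
  K <- length(raters(x))
  rows <- rep(seq_len(nrow(cells)), cells$count)
  if (!length(rows))
    return(data.frame(subject = character(), rater = character(),
                      category = character()))
  subj <- paste0("s", seq_along(rows))
  data.frame(
    subject = rep(subj, each = K),
    rater = rep(raters(x), times = length(rows)),
    category = as.vector(t(as.matrix(cells[rows, seq_len(K)]))),
    stringsAsFactors = FALSE
  )
}

#' Collapse a table over raters
#'
#' Sums counts over the raters not kept, producing the lower-order
#' cross-classification (e.g. a pairwise 3x3 view of a 4-rater table).
#' The total count n is conserved.
#'
#' @param x a `rating_table`.
#' @param keep character vector: ordered subset of `raters(x)` to retain
#'   (length >= 1; length 1 gives a margin, >= 2 a valid `rating_table`).
#' @return a `rating_table` (or a named numeric margin when
#'   `length(keep) == 1`).
#' @export
marginalize <- function(x, keep) {
  keep <- as.character(keep)
  if (!length(keep) || !all(keep %in% raters(x)))
    stop("`keep` must be a non-empty subset of the table's raters")
  idx <- match(keep, raters(x))
  m <- apply(unclass(x), idx, sum)
  if (length(keep) == 1L) return(m)
  dimnames(m) <- stats::setNames(rep(list(categories(x)), length(keep)), keep)
  structure(m, class = "rating_table")
}

#' Read / write rating data as CSV
#'
#' `read_ratings()` expects long format with header `subject,rater,category`.
#' `read_cell_counts()`/`write_cell_counts()` use one row per cell with the
#' rater names as category columns plus a final `count` column; the pair
#' round-trips exactly.  Quoted fields and UTF-8 are handled by the base
#' CSV machinery; category matching is exact-string.
#'
#' @param path file path.
#' @param raters,categories as in [rating_table()].
#' @return `read_ratings()`: a data.frame of records; `read_cell_counts()`:
#'   a [rating_table()].
#' @export
read_ratings <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", encoding = "UTF-8")
  need <- c("subject", "rater", "category")
  if (!all(need %in% names(d)))
    stop("ratings CSV must have header subject,rater,category")
  d[, need]
}

#' @rdname read_ratings
#' @export
read_cell_counts <- function(path, raters = NULL, categories = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!"count" %in% names(d)) stop("cell-count CSV must have a `count` column")
  if (is.null(raters)) raters <- setdiff(names(d), "count")
  if (any(d$count < 0)) {
    bad <- which(d$count < 0)[1L]
    stop(sprintf("negative count in row %d of %s", bad, path))
  }
  if (is.null(categories)) categories <- sort(unique(unlist(d[raters])))
  C <- length(categories); K <- length(raters)
  tab <- rating_table(rep(0, C^K), raters, categories)
  a <- unclass(tab)
  for (i in seq_len(nrow(d))) {
    idx <- match(as.character(unlist(d[i, raters])), categories)
    if (anyNA(idx))
      stop("unknown category label(s) in row ", i, ": ",
           paste(setdiff(unlist(d[i, raters]), categories), collapse = ", "))
    a[matrix(idx, nrow = 1L)] <- a[matrix(idx, nrow = 1L)] + d$count[i]
  }
  structure(a, class = "rating_table")
}

#' @rdname read_ratings
#' @param x a `rating_table`.
#' @export
write_cell_counts <- function(x, path) {
  d <- as.data.frame(x)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
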