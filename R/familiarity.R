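#' Parse a census partner field
#'
#' Partners are stored as a `;`-separated string in the census table; an
#' empty string (state `alone`) is an empty set.
#' @keywords internal
parse_partners <- function(partners) {
  lapply(partners, function(p) {
    if (is.na(p) || !nzchar(p)) character(0) else strsplit(p, ";", fixed = TRUE)[[1]]
  })
}

validate_census <- function(census) {
  needed <- c("census_id", "date", "female", "state", "partners")
  missing <- setdiff(needed, names(census))
  if (length(missing))
    stop("census table missing column(s): ", paste(missing, collapse = ", "))
  census$date <- as.Date(census$date)
  census$partners[is.na(census$partners)] <- ""
  has_part <- nzchar(census$partners)
  if (any(census$state == "social" & !has_part) ||
      any(census$state == "alone" & has_part))
    stop("census invariant violated: partners nonempty iff state == 'social'")
  census
}

#' Directional dyadic familiarity index
#'
#' Fraction of line-census sessions in which A was in contact with or within
#' 3 m of B, out of the sessions in which A was recorded. Directional:
#' `index(A, B)` need not equal `index(B, A)`. If A was never recorded in
#' the period, the index is undefined (`NA`), not zero.
#'
#' @param census census data frame (`census_id`, `date`, `female`, `state`,
#'   `partners` as `;`-separated ids)
#' @param A,B individual ids
#' @param period optional `c(from, to)` dates restricting the census
#' @return fraction in \[0, 1\], or `NA_real_` when undefined
#' @export
familiarity_index <- function(census, A, B, period = NULL) {
  census <- validate_census(census)
  if (!is.null(period)) {
    period <- as.Date(period)
    census <- census[census$date >= period[1] & census$date <= period[2], ,
                     drop = FALSE]
  }
  rows <- census[census$female == A, , drop = FALSE]
  if (!nrow(rows)) return(NA_real_)
  with_b <- vapply(parse_partners(rows$partners), function(p) B %in% p,
                   logical(1))
  sum(with_b) / nrow(rows)
}

#' Full directional familiarity matrix for one period
#'
#' @param census census data frame
#' @param individuals ids to index (default: all females recorded)
#' @param period optional date range, as in [familiarity_index()]
#' @param label period identifier stored on the result
#' @return an object of class `familiarity_matrix`: list with `index`
#'   (matrix, rows = A, cols = B, `NA` row when A never recorded),
#'   `denominator` (sessions A recorded) and `period`
#' @export
familiarity_matrix <- function(census, individuals = NULL, period = NULL,
                               label = "all") {
  census <- validate_census(census)
  if (!is.null(period)) {
    period <- as.Date(period)
    census <- census[census$date >= period[1] & census$date <= period[2], ,
                     drop = FALSE]
  }
  ids <- individuals %||% sort(unique(census$female))
  idx <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  denom <- stats::setNames(integer(length(ids)), ids)
  plist <- parse_partners(census$partners)
  for (a in ids) {
    sel <- census$female == a
    denom[a] <- sum(sel)
    if (!denom[a]) next
    tab <- table(unlist(plist[sel]))
    idx[a, ] <- 0
    hit <- intersect(names(tab), ids)
    idx[a, hit] <- as.numeric(tab[hit]) / denom[a]
  }
  diag(idx) <- NA_real_
  structure(list(index = idx, denominator = denom, period = label),
            class = "familiarity_matrix")
}

#' Split census records into two observation periods
#'
#' Records strictly before `boundary` form period 1; the rest period 2. The
#' default boundary (1 April 2014) evenly divides a March 2013 - March 2015
#' study span.
#'
#' @param census census data frame
#' @param boundary a `Date`
#' @return list with `period1` and `period2` census subsets
#' @export
split_periods <- function(census, boundary = as.Date("2014-04-01")) {
  census <- validate_census(census)
  boundary <- as.Date(boundary)
  if (nrow(census) &&
      (boundary <= min(census$date) || boundary > max(census$date)))
    warning("period boundary falls outside the observation span")
  list(period1 = census[census$date < boundary, , drop = FALSE],
       period2 = census[census$date >= boundary, , drop = FALSE])
}

#' Between-period correlation of familiarity indices
#'
#' Pearson correlation over directed dyads whose index is defined in both
#' periods, optionally restricted to a supplied dyad universe (e.g. the
#' dyads appearing in analyzed PC-MC pairs).
#'
#' @param m1,m2 [familiarity_matrix()] objects on the same id set
#' @param dyads optional data frame (`A`, `B`) restricting the dyads
#' @return list: `r`, `n`, `p` (from [stats::cor.test()])
#' @export
period_correlation <- function(m1, m2, dyads = NULL) {
  stopifnot(inherits(m1, "familiarity_matrix"),
            inherits(m2, "familiarity_matrix"),
            identical(dimnames(m1$index), dimnames(m2$index)))
  if (is.null(dyads)) {
    keep <- !is.na(m1$index) & !is.na(m2$index)
    x <- m1$index[keep]; y <- m2$index[keep]
  } else {
    x <- m1$index[cbind(dyads$A, dyads$B)]
    y <- m2$index[cbind(dyads$A, dyads$B)]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
  }
  if (length(x) < 3) stop("need at least 3 dyads defined in both periods")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = length(x), p = NA_real_,
                note = "zero variance in one period"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}
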