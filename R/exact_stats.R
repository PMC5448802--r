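#' Signed-rank statistic with midranks
#'
#' Zero differences are dropped (their count is reported); the absolute
#' values of the remaining differences are ranked with midranks for ties,
#' and V is the sum of the ranks attached to positive differences. Midranks
#' make V half-integral when ties straddle the sign boundary.
#'
#' @param diffs numeric vector of paired differences (nonempty)
#' @return list with `V`, `ranks` (of the nonzero |diffs|), `signs`,
#'   `n_effective`, `n_zero` and a `degenerate` flag (all differences zero)
#' @export
signed_rank_statistic <- function(diffs) {
  stopifnot(is.numeric(diffs), length(diffs) >= 1)
  if (anyNA(diffs)) stop("NA differences are not allowed")
  nz <- diffs[diffs != 0]
  n_zero <- length(diffs) - length(nz)
  if (!length(nz))
    return(list(V = 0, ranks = numeric(0), signs = integer(0),
                n_effective = 0L, n_zero = n_zero, degenerate = TRUE))
  r <- rank(abs(nz))
  list(V = sum(r[nz > 0]), ranks = r, signs = sign(nz),
       n_effective = length(nz), n_zero = n_zero, degenerate = FALSE)
}

#' Exact null distribution of the signed-rank statistic
#'
#' Distribution of V under equiprobable, independent sign assignments to the
#' observed rank magnitudes (the exact permutation null, conditional on the
#' midrank pattern; no normal approximation). The default engine is the
#' shift (convolution) recursion, exact for any n; `"enumerate"` walks all
#' 2^n sign vectors and is retained as the independent cross-check for small
#' n.
#'
#' Midranks can be half-integers, so the recursion runs on doubled ranks;
#' the support is returned on the original scale.
#'
#' @param rank_magnitudes positive ranks (integers or half-integers)
#' @param method `"shift"` (default) or `"enumerate"`
#' @param cap maximum n for full enumeration (default 25)
#' @return data frame with columns `v` and `prob` (probabilities sum to 1)
#' @export
exact_null_distribution <- function(rank_magnitudes,
                                    method = c("shift", "enumerate"),
                                    cap = 25) {
  method <- match.arg(method)
  r <- rank_magnitudes
  if (!length(r)) stop("empty rank vector")
  m <- round(2 * r)
  if (max(abs(2 * r - m)) > 1e-8)
    stop("ranks must be integers or half-integers")
  n <- length(m)
  if (method == "enumerate") {
    if (n > cap) stop("enumeration capped at n = ", cap,
                      "; use method = 'shift'")
    total <- sum(m)
    counts <- numeric(total + 1)
    for (k in 0:(2^n - 1)) {
      signs <- bitwAnd(k, bitwShiftL(1L, 0:(n - 1))) > 0
      counts[sum(m[signs]) + 1] <- counts[sum(m[signs]) + 1] + 1
    }
    prob <- counts / 2^n
  } else {
    # f[v+1] = number of sign assignments with doubled statistic v
    f <- c(1, numeric(sum(m)))
    for (mi in m) {
      shifted <- c(numeric(mi), f[seq_len(length(f) - mi)])
      f <- f + shifted
    }
    prob <- f / 2^n
  }
  keep <- prob > 0
  data.frame(v = (which(keep) - 1) / 2, prob = prob[keep])
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired exact test: differences `x - y` are ranked with midranks (zeros
#' dropped), and the p-value comes from the exact sign-assignment null of
#' [exact_null_distribution()]. The default two-sided convention doubles the
#' smaller tail (capped at 1); `p_method = "minlike"` instead sums the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @param x numeric vector (or, with `y = NULL`, the differences themselves)
#' @param y optional paired sample of the same length as `x`
#' @param alternative `"two.sided"`, `"greater"` or `"less"`
#' @param p_method two-sided convention, `"doubling"` (default) or
#'   `"minlike"`
#' @return an object of class `signed_rank_result`: `V`, `n_effective`,
#'   `n_zero`, `p_two_sided` (or one-sided `p`), `method`
#' @export
#' @examples
#' exact_wilcoxon_test(c(1, 2, 3), c(0, 0, 0))$p # 0.25
exact_wilcoxon_test <- function(x, y = NULL,
                                alternative = c("two.sided", "greater", "less"),
                                p_method = c("doubling", "minlike")) {
  alternative <- match.arg(alternative)
  p_method <- match.arg(p_method)
  if (!is.null(y)) {
    if (length(x) != length(y)) stop("x and y must have the same length")
    diffs <- x - y
  } else diffs <- x
  st <- signed_rank_statistic(diffs)
  if (st$degenerate) {
    out <- list(V = 0, n_effective = 0L, n_zero = st$n_zero, p = 1,
                alternative = alternative, method = "degenerate (all zeros)")
    class(out) <- "signed_rank_result"
    return(out)
  }
  dist <- exact_null_distribution(st$ranks)
  eps <- 1e-9
  p_le <- sum(dist$prob[dist$v <= st$V + eps])
  p_ge <- sum(dist$prob[dist$v >= st$V - eps])
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = if (p_method == "doubling")
                min(1, 2 * min(p_le, p_ge))
              else {
                p_obs <- dist$prob[abs(dist$v - st$V) < eps]
                sum(dist$prob[dist$prob <= p_obs + eps])
              })
  out <- list(V = st$V, n_effective = st$n_effective, n_zero = st$n_zero,
              p = p, alternative = alternative,
              method = paste0("exact (shift recursion, ", p_method, ")"))
  class(out) <- "signed_rank_result"
  out
}

#' @export
print.signed_rank_result <- function(x, ...) {
  cat("Exact Wilcoxon signed-rank test\n")
  cat(sprintf("V = %g, n (nonzero) = %d, zeros dropped = %d\n",
              x$V, x$n_effective, x$n_zero))
  cat(sprintf("p (%s) = %.4g   [%s]\n", x$alternative, x$p, x$method))
  invisible(x)
}
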