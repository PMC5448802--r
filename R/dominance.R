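#' Construct or validate a dyadic win matrix
#'
#' `wins[i, j]` counts outcomes (aggression or supplants) in which `i` beat
#' `j`. Accepts a square matrix or a long data frame with columns `winner`,
#' `loser` and optionally `n`.
#'
#' @param x square numeric matrix (dimnames = individual ids) or data frame
#' @param individuals optional id vector fixing the matrix order
#' @return matrix of class `win_matrix`
#' @export
win_matrix <- function(x, individuals = NULL) {
  if (is.data.frame(x)) {
    ids <- individuals %||% sort(unique(c(x$winner, x$loser)))
    w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    n <- if ("n" %in% names(x)) x$n else rep(1, nrow(x))
    for (k in seq_len(nrow(x)))
      w[x$winner[k], x$loser[k]] <- w[x$winner[k], x$loser[k]] + n[k]
    x <- w
  }
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  if (is.null(rownames(x)))
    dimnames(x) <- list(paste0("id", seq_len(nrow(x))),
                        paste0("id", seq_len(nrow(x))))
  if (any(x < 0) || any(x != round(x))) stop("win counts must be nonnegative integers")
  if (any(diag(x) != 0)) stop("win matrix must have a zero diagonal")
  class(x) <- c("win_matrix", class(x))
  x
}

# Dominance direction: d[i,j] is 1 if i beats j by strict majority of wins.
# Equal nonzero counts are tied dyads; zero-zero dyads are unknown.
direction_matrix <- function(w) {
  d <- (w > t(w)) * 1
  diag(d) <- 0
  d
}

unknown_or_tied <- function(w) {
  u <- (w == t(w))
  diag(u) <- FALSE
  u
}

order_objective <- function(d, ord) {
  # Inconsistencies: pairs where the lower-ranked beats the higher-ranked.
  # Strength: total rank distance of the inconsistent pairs (I&SI).
  p <- d[ord, ord]
  lower <- lower.tri(p)
  inc <- p == 1 & lower
  c(count = sum(inc), strength = sum((row(p) - col(p))[inc]))
}

better <- function(a, b) {
  a["count"] < b["count"] ||
    (a["count"] == b["count"] && a["strength"] < b["strength"])
}

#' Dominance rank order minimizing inconsistencies
#'
#' Orders individuals to minimize first the number, then the total rank
#' distance (strength), of dyads in which a lower-ranked individual beats a
#' higher-ranked one (I&SI-style). Exhaustive search for N <= 8 (which also
#' serves as the test oracle); above that, a deterministic seeded
#' simulated-annealing pass over adjacent transpositions followed by greedy
#' sweeps. Individuals with no interactions at all are placed last, in id
#' order, and flagged.
#'
#' @param w a [win_matrix()]
#' @param seed seed for the annealing path (ignored for N <= 8)
#' @param n_anneal annealing iterations (default 20000)
#' @return list with `ranks` (named integer vector, 1 = most dominant),
#'   `inconsistencies`, `strength`, `isolated` (flagged ids), `method`
#' @export
rank_order <- function(w, seed = 1L, n_anneal = 20000L) {
  w <- win_matrix(unclass(w))
  ids <- rownames(w)
  if (length(ids) < 2) stop("need at least two individuals")
  interacted <- rowSums(w) + colSums(w) > 0
  isolated <- ids[!interacted]
  active <- ids[interacted]
  if (length(active) < 2) {
    ranks <- stats::setNames(seq_along(ids), sort(ids))
    return(list(ranks = ranks[ids][order(ranks[ids])],
                inconsistencies = 0, strength = 0,
                isolated = ids, method = "degenerate"))
  }
  d <- direction_matrix(w[active, active, drop = FALSE])
  n <- length(active)
  if (n <= 8) {
    perms <- permutations_lex(n)
    best <- NULL
    best_obj <- c(count = Inf, strength = Inf)
    for (i in seq_len(nrow(perms))) {
      obj <- order_objective(d, perms[i, ])
      if (better(obj, best_obj)) { best <- perms[i, ]; best_obj <- obj }
    }
    ord <- best
    method <- "exhaustive"
  } else {
    set.seed(seed)
    ord <- order(-(rowSums(d) - colSums(d)), active) # David's-score-ish init
    obj <- order_objective(d, ord)
    cur <- ord; cur_obj <- obj
    temp <- 2
    for (it in seq_len(n_anneal)) {
      k <- sample.int(n - 1, 1)
      cand <- cur; cand[c(k, k + 1)] <- cur[c(k + 1, k)]
      cand_obj <- order_objective(d, cand)
      delta <- (cand_obj["count"] - cur_obj["count"]) * n +
        (cand_obj["strength"] - cur_obj["strength"]) / n
      if (delta <= 0 || runif(1) < exp(-delta / temp)) {
        cur <- cand; cur_obj <- cand_obj
        if (better(cur_obj, obj)) { ord <- cur; obj <- cur_obj }
      }
      temp <- temp * 0.9997
    }
    # greedy adjacent-swap sweeps until no improvement
    repeat {
      improved <- FALSE
      for (k in seq_len(n - 1)) {
        cand <- ord; cand[c(k, k + 1)] <- ord[c(k + 1, k)]
        cand_obj <- order_objective(d, cand)
        if (better(cand_obj, obj)) { ord <- cand; obj <- cand_obj; improved <- TRUE }
      }
      if (!improved) break
    }
    method <- "annealing"
  }
  final_obj <- order_objective(d, ord)
  ordered_ids <- c(active[ord], sort(isolated))
  ranks <- stats::setNames(seq_along(ordered_ids), ordered_ids)
  list(ranks = ranks, inconsistencies = unname(final_obj["count"]),
       strength = unname(final_obj["strength"]),
       isolated = sort(isolated), method = method)
}

permutations_lex <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_lex(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

landau_h_from_scores <- function(v) {
  n <- length(v)
  12 / (n^3 - n) * sum((v - (n - 1) / 2)^2)
}

#' Landau's linearity index h
#'
#' `h = 12/(N^3 - N) * sum_i (V_i - (N-1)/2)^2`, where `V_i` is the number
#' of individuals i dominates (strict majority of wins). 1 for a perfectly
#' linear hierarchy, 0 for maximal circularity.
#'
#' @param w a [win_matrix()] with N >= 3 individuals
#' @return h in \[0, 1\]
#' @export
landau_h <- function(w) {
  w <- win_matrix(unclass(w))
  if (nrow(w) < 3) stop("Landau's h is undefined for N < 3")
  landau_h_from_scores(rowSums(direction_matrix(w)))
}

#' de Vries' improved linearity index h' with randomization test
#'
#' Unknown (no interactions) and tied (equal nonzero wins) dyads are
#' resolved by a fair coin in each of `n_randomizations` replicates; h' is
#' the mean of Landau's h over those resolutions. The linearity p-value is
#' the fraction of fully randomized matrices (every dyad a coin flip) whose
#' h is at least h' (the two-step randomization of the method this index
#' comes from). With no unknown or tied dyads, h' equals h exactly.
#'
#' @param w a [win_matrix()], N >= 3
#' @param n_randomizations replicates (>= 1000 recommended; default 10000)
#' @param seed mandatory seed for reproducibility
#' @return list: `h_prime`, `p_linearity`, `h` (ties unresolved),
#'   `n_unknown_dyads`, `n_randomizations`, `seed`
#' @export
devries_h_prime <- function(w, n_randomizations = 10000L, seed) {
  if (missing(seed)) stop("seed is mandatory for devries_h_prime")
  w <- win_matrix(unclass(w))
  n <- nrow(w)
  if (n < 3) stop("h' is undefined for N < 3")
  d <- direction_matrix(w)
  unk <- unknown_or_tied(w)
  up <- upper.tri(d)
  unk_i <- row(d)[unk & up]
  unk_j <- col(d)[unk & up]
  base_v <- rowSums(d)
  set.seed(seed)
  # step 1: h' = mean h over coin-flip resolutions of the unknown/tied dyads
  if (length(unk_i)) {
    h_vals <- vapply(seq_len(n_randomizations), function(r) {
      heads <- stats::runif(length(unk_i)) < 0.5
      v <- base_v +
        tabulate(c(unk_i[heads], unk_j[!heads]), nbins = n)
      landau_h_from_scores(v)
    }, numeric(1))
    h_prime <- mean(h_vals)
  } else {
    h_prime <- landau_h_from_scores(base_v)
  }
  # step 2: reference distribution from fully random tournaments
  all_i <- row(d)[up]
  all_j <- col(d)[up]
  h_rand <- vapply(seq_len(n_randomizations), function(r) {
    heads <- stats::runif(length(all_i)) < 0.5
    v <- tabulate(c(all_i[heads], all_j[!heads]), nbins = n)
    landau_h_from_scores(v)
  }, numeric(1))
  list(h_prime = h_prime, p_linearity = mean(h_rand >= h_prime),
       h = landau_h_from_scores(rowSums(d)),
       n_unknown_dyads = length(unk_i),
       n_randomizations = n_randomizations, seed = seed)
}

#' Signed rank difference between subject and former opponent
#'
#' `subject_rank - opponent_rank`; positive values mean the subject is
#' subordinate to the former opponent (rank 1 = most dominant).
#'
#' @param subject_rank,opponent_rank integer ranks in 1..N
#' @return signed integer
#' @export
rank_difference <- function(subject_rank, opponent_rank) {
  if (anyNA(subject_rank) || anyNA(opponent_rank))
    stop("unranked individual: rank difference undefined")
  subject_rank - opponent_rank
}
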