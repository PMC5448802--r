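#' Simulation configuration
#'
#' The stated world of the generator: a free-ranging group of adult females
#' with a strictly linear dominance hierarchy, dyadic conflicts followed by
#' 5-min PC focal sessions and matched controls, census-derived familiarity
#' structure, and logistic models for post-conflict affiliation, vocal use
#' and renewed aggression. Defaults are sized to the study the design comes
#' from (about 90 females, about 600 PC-MC pairs, 172 census sessions over
#' two years); scale `n_females` / `n_conflicts` / `census_sessions` down
#' for fast tests.
#'
#' @param n_females group size (>= 3)
#' @param seed mandatory integer seed; every stage derives its substream
#'   from it deterministically
#' @param n_conflicts number of dyadic conflicts (= PC-MC pairs)
#' @param hierarchy_completeness probability a dyad has any dominance
#'   interactions recorded
#' @param p_win_dominant probability the dominant wins a recorded
#'   interaction (1 = strictly linear outcomes)
#' @param p_physical,p_counter probability a conflict includes physical
#'   aggression / counter-aggression
#' @param p_victim_subordinate probability the victim is the subordinate of
#'   the dyad
#' @param familiarity_zero_mass,familiarity_beta,familiarity_max familiarity
#'   mixture: point mass at 0, else `familiarity_max * Beta(a, b)`
#' @param pc_affiliation_model logistic coefficients (intercept,
#'   familiarity, rank_diff, physical, counter) for affiliation with the
#'   former opponent in PC
#' @param pc_minute_weights distribution of the PC affiliation minute (1..5)
#' @param mc_affiliation_hazard per-minute probability of affiliation with
#'   any partner in MC
#' @param vocal_model logistic coefficients (intercept, familiarity) for
#'   vocal use given PC affiliation; the familiarity slope defaults to -7.8
#' @param p_vocal_only_given_vocal probability a vocal affiliation is
#'   vocalization only (no contact/approach)
#' @param mc_vocal_prob probability of vocal use given MC affiliation
#' @param renewed_aggression_model probabilities the focal victim receives
#'   aggression from the opponent in the exposure window, by state
#'   (`none`, `affiliation_vocal`, `affiliation_novocal`, `aggressor_focal`)
#' @param background_aggression probability of receiving aggression from a
#'   third party, by session kind
#' @param census_sessions number of line-census sessions
#' @param census_detectability probability a female is recorded in a census
#'   session (scalar or per-female vector)
#' @param study_start,period_boundary,study_end study span dates
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(
    n_females = 90,
    seed = 1L,
    n_conflicts = 605,
    hierarchy_completeness = 1,
    p_win_dominant = 1,
    p_physical = 0.35,
    p_counter = 0.15,
    p_victim_subordinate = 0.9,
    familiarity_zero_mass = 0.6,
    familiarity_beta = c(1.2, 3),
    familiarity_max = 0.73,
    pc_affiliation_model = c(intercept = -1.2, familiarity = 5.4,
                             rank_diff = 0.01, physical = -0.4,
                             counter = -1.35),
    pc_minute_weights = c(0.75, 0.11, 0.06, 0.05, 0.03),
    mc_affiliation_hazard = 0.088,
    vocal_model = c(intercept = 0.3, familiarity = -7.8),
    p_vocal_only_given_vocal = 0.4,
    mc_vocal_prob = 0.12,
    renewed_aggression_model = c(none = 0.073, affiliation_vocal = 0.146,
                                 affiliation_novocal = 0.208,
                                 aggressor_focal = 0.013),
    background_aggression = c(pc = 0.10, mc = 0.08),
    census_sessions = 172,
    census_detectability = 0.3,
    study_start = as.Date("2013-03-01"),
    period_boundary = as.Date("2014-04-01"),
    study_end = as.Date("2015-03-31")) {
  cfg <- as.list(environment())
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("seed is mandatory")
  if (cfg$n_females < 3) stop("n_females must be >= 3")
  probs <- c(cfg$hierarchy_completeness, cfg$p_win_dominant, cfg$p_physical,
             cfg$p_counter, cfg$p_victim_subordinate,
             cfg$familiarity_zero_mass, cfg$mc_affiliation_hazard,
             cfg$p_vocal_only_given_vocal, cfg$mc_vocal_prob,
             cfg$renewed_aggression_model, cfg$background_aggression,
             cfg$census_detectability)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$pc_minute_weights) - 1) > 1e-8)
    stop("pc_minute_weights must sum to 1")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate the population: hierarchy, win matrix, familiarity ground truth
#'
#' Individual ids are `F001..F<N>`, ranked 1..N in id order (a strictly
#' linear hierarchy). The win matrix records dominance interactions for each
#' observed dyad; the symmetric familiarity ground truth is drawn from the
#' configured zero-inflated Beta mixture.
#'
#' @param config a [simulation_config()]
#' @return list of class `pcmc_population`: `ids`, `ranks`, `familiarity`
#'   (matrix), `win_matrix`, `config`
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_females
  ids <- sprintf("F%03d", seq_len(n))
  ranks <- stats::setNames(seq_len(n), ids)
  fam <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    f <- if (stats::runif(1) < config$familiarity_zero_mass) 0 else
      config$familiarity_max * stats::rbeta(1, config$familiarity_beta[1],
                                            config$familiarity_beta[2])
    fam[i, j] <- fam[j, i] <- f
  }
  w <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) > config$hierarchy_completeness) next
    k <- 1L + stats::rpois(1, 1.5)
    dom_wins <- stats::rbinom(1, k, config$p_win_dominant)
    w[i, j] <- dom_wins
    w[j, i] <- k - dom_wins
  }
  structure(list(ids = ids, ranks = ranks, familiarity = fam,
                 win_matrix = win_matrix(w), config = config),
            class = "pcmc_population")
}

rdate <- function(n, from, to) {
  from + floor(stats::runif(n) * (as.numeric(to - from) + 1))
}

logistic_draw <- function(eta) stats::runif(length(eta)) < stats::plogis(eta)

#' Simulate PC-MC session pairs with event streams
#'
#' One PC-MC pair per conflict: roles assigned (the victim is the
#' subordinate with high probability), the focal alternating between
#' aggressor and victim; PC affiliation with the former opponent drawn from
#' the configured logistic model, with the affiliation minute from
#' `pc_minute_weights` and event times uniform within their minute; vocal
#' use given affiliation from `vocal_model` (distance <= 5 m, oriented);
#' renewed and background aggression per the configured hazards; MC
#' affiliation with any partner from the per-minute hazard, 1-13 days later
#' at a time of day within 2 h.
#'
#' @param population a [simulate_population()] result
#' @param config a [simulation_config()] (defaults to the population's)
#' @return a [pcmc_data()] with `pairs` and `truth` attached
#' @export
simulate_sessions <- function(population, config = population$config) {
  stopifnot(inherits(population, "pcmc_population"))
  set.seed(config$seed + 1L)
  n <- config$n_conflicts
  ids <- population$ids
  ranks <- population$ranks
  fam <- population$familiarity
  pairs <- data.frame(pair_id = sprintf("P%04d", seq_len(n)),
                      pc = sprintf("S%04d_PC", seq_len(n)),
                      mc = sprintf("S%04d_MC", seq_len(n)),
                      stringsAsFactors = FALSE)
  am <- config$pc_affiliation_model
  vm <- config$vocal_model
  ram <- config$renewed_aggression_model
  # flat accumulators (one data.frame build at the end, not one per row)
  s_id <- s_kind <- s_focal <- s_opp <- s_role <- character(2 * n)
  s_when <- numeric(2 * n)
  s_phys <- s_count <- logical(2 * n)
  e_sid <- list(); e_t <- list(); e_actor <- list(); e_recip <- list()
  e_beh <- list(); e_orient <- list(); e_dist <- list()
  for (k in seq_len(n)) {
    dyad <- sample(ids, 2)
    dominant <- dyad[which.min(ranks[dyad])]
    subordinate <- setdiff(dyad, dominant)
    victim <- if (stats::runif(1) < config$p_victim_subordinate)
      subordinate else dominant
    aggressor <- setdiff(dyad, victim)
    focal_role <- if (k %% 2 == 1) "aggressor" else "victim"
    focal <- if (focal_role == "aggressor") aggressor else victim
    opponent <- setdiff(dyad, focal)
    physical <- stats::runif(1) < config$p_physical
    counter <- stats::runif(1) < config$p_counter
    pc_date <- rdate(1, config$study_start, config$study_end - 20)
    pc_time <- as.POSIXct(paste0(format(pc_date), " 09:00:00"), tz = "UTC") +
      round(stats::runif(1, 0, 8 * 3600))
    mc_time <- pc_time + sample(1:13, 1) * 86400 +
      round(stats::runif(1, -1.5, 1.5) * 3600)
    f <- fam[focal, opponent]
    rd <- unname(ranks[focal] - ranks[opponent])
    eta <- am["intercept"] + am["familiarity"] * f + am["rank_diff"] * rd +
      am["physical"] * physical + am["counter"] * counter
    pc_affil <- logistic_draw(eta)
    pc_id <- pairs$pc[k]; mc_id <- pairs$mc[k]
    add <- function(session_id, t, actor, recipient, behavior,
                    oriented = NA, dist = NA_real_) {
      i <- length(e_sid) + 1L
      e_sid[[i]] <<- session_id; e_t[[i]] <<- t; e_actor[[i]] <<- actor
      e_recip[[i]] <<- recipient; e_beh[[i]] <<- behavior
      e_orient[[i]] <<- oriented; e_dist[[i]] <<- dist
    }
    aff_t <- NA_real_
    vocal <- FALSE
    if (pc_affil) {
      minute <- sample(1:5, 1, prob = config$pc_minute_weights)
      aff_t <- (minute - 1) * 60 + stats::runif(1, 0, 60)
      vocal <- logistic_draw(vm["intercept"] + vm["familiarity"] * f)
      vocal_only <- vocal &&
        stats::runif(1) < config$p_vocal_only_given_vocal
      if (!vocal_only)
        add(pc_id, aff_t, focal, opponent,
            sample(c("contact", "groom_give", "approach"), 1))
      if (vocal)
        add(pc_id, min(aff_t + stats::runif(1, 0, 5), 299.9), focal, opponent,
            "vocalization", oriented = TRUE, dist = stats::runif(1, 0.5, 5))
    }
    # renewed aggression from the former opponent, in the exposure window
    p_renew <- if (focal_role == "aggressor") ram["aggressor_focal"]
    else if (!pc_affil) ram["none"]
    else if (vocal) ram["affiliation_vocal"] else ram["affiliation_novocal"]
    if (stats::runif(1) < p_renew) {
      lo <- if (pc_affil) aff_t else 60
      add(pc_id, stats::runif(1, lo, SESSION_SECONDS - 0.1), opponent, focal,
          sample(AGGRESSIVE_BEHAVIORS, 1))
    }
    if (stats::runif(1) < config$background_aggression["pc"]) {
      third <- sample(setdiff(ids, dyad), 1)
      add(pc_id, stats::runif(1, 0, SESSION_SECONDS), third, focal,
          sample(AGGRESSIVE_BEHAVIORS, 1))
    }
    # matched control: affiliation with any partner, per-minute hazard
    mc_minute <- which(stats::runif(5) < config$mc_affiliation_hazard)
    if (length(mc_minute)) {
      m <- mc_minute[1]
      t_mc <- (m - 1) * 60 + stats::runif(1, 0, 60)
      wts <- fam[focal, setdiff(ids, focal)] + 0.01
      partner <- sample(setdiff(ids, focal), 1, prob = wts)
      if (stats::runif(1) < config$mc_vocal_prob)
        add(mc_id, t_mc, focal, partner, "vocalization",
            oriented = TRUE, dist = stats::runif(1, 0.5, 5))
      else
        add(mc_id, t_mc, focal, partner,
            sample(c("contact", "groom_give", "approach"), 1))
    }
    if (stats::runif(1) < config$background_aggression["mc"]) {
      third <- sample(setdiff(ids, focal), 1)
      add(mc_id, stats::runif(1, 0, SESSION_SECONDS), third, focal,
          sample(AGGRESSIVE_BEHAVIORS, 1))
    }
    for (side in 1:2) {
      i <- 2 * (k - 1) + side
      s_id[i] <- if (side == 1) pc_id else mc_id
      s_kind[i] <- if (side == 1) "PC" else "MC"
      s_focal[i] <- focal; s_opp[i] <- opponent; s_role[i] <- focal_role
      s_when[i] <- round(as.numeric(if (side == 1) pc_time else mc_time))
      s_phys[i] <- physical; s_count[i] <- counter
    }
  }
  sessions <- data.frame(
    session_id = s_id, kind = s_kind, focal = s_focal, opponent = s_opp,
    focal_role = s_role,
    date_time = as.POSIXct(s_when, origin = "1970-01-01", tz = "UTC"),
    conflict_physical = s_phys, conflict_counter = s_count,
    stringsAsFactors = FALSE)
  events <- data.frame(
    session_id = unlist(e_sid) %||% character(0),
    t = unlist(e_t) %||% numeric(0),
    actor = unlist(e_actor) %||% character(0),
    recipient = unlist(e_recip) %||% character(0),
    behavior = unlist(e_beh) %||% character(0),
    oriented_at_recipient = as.logical(unlist(e_orient)) %||% logical(0),
    distance_m = unlist(e_dist) %||% numeric(0),
    stringsAsFactors = FALSE)
  pcmc_data(sessions, events, pairs = pairs,
            truth = list(ranks = population$ranks,
                         familiarity = population$familiarity,
                         win_matrix = population$win_matrix,
                         config = config))
}

#' Simulate line-census records
#'
#' Census dates are split between the two observation periods in the same
#' 87:85 proportion as the emulated study. Each female is recorded with the
#' configured detectability; for each dyad a per-session proximity event is
#' drawn with probability equal to the ground-truth familiarity, so the
#' familiarity index applied to the output is a consistent estimator of the
#' truth (bias vanishing as sessions grow).
#'
#' @param population a [simulate_population()] result
#' @param config a [simulation_config()] (defaults to the population's)
#' @return a census data frame
#' @export
simulate_census <- function(population, config = population$config) {
  stopifnot(inherits(population, "pcmc_population"))
  set.seed(config$seed + 2L)
  n_sess <- config$census_sessions
  n1 <- round(n_sess * 87 / 172)
  ids <- population$ids
  n <- length(ids)
  det <- rep_len(config$census_detectability, n)
  fam <- population$familiarity
  dates <- c(rdate(n1, config$study_start, config$period_boundary - 1),
             rdate(n_sess - n1, config$period_boundary, config$study_end))
  dates <- sort(dates)
  out <- vector("list", n_sess)
  iu <- which(upper.tri(fam), arr.ind = TRUE)
  for (s in seq_len(n_sess)) {
    recorded <- stats::runif(n) < det
    prox <- stats::runif(nrow(iu)) < fam[iu]
    adj <- matrix(FALSE, n, n)
    adj[iu[prox, , drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    rec_idx <- which(recorded)
    if (!length(rec_idx)) next
    partners <- vapply(rec_idx, function(i)
      paste(ids[adj[i, ]], collapse = ";"), character(1))
    out[[s]] <- data.frame(
      census_id = sprintf("C%05d", s), date = dates[s],
      female = ids[rec_idx],
      state = ifelse(nzchar(partners), "social", "alone"),
      partners = partners, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Simulate a complete dataset (population, sessions, census)
#'
#' @param config a [simulation_config()]
#' @return a [pcmc_data()] with pairs, census and ground truth attached
#' @export
simulate_dataset <- function(config = simulation_config()) {
  pop <- simulate_population(config)
  data <- simulate_sessions(pop, config)
  data$census <- simulate_census(pop, config)
  data
}
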