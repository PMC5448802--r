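# Fixture builders shared across the suite. Everything is generated in code;
# no files ship with the package.

make_event <- function(session_id, t, actor, recipient, behavior,
                       oriented = NA, dist = NA_real_) {
  data.frame(session_id = session_id, t = t, actor = actor,
             recipient = recipient, behavior = behavior,
             oriented_at_recipient = oriented, distance_m = dist,
             stringsAsFactors = FALSE)
}

make_session_row <- function(session_id, kind = "PC", focal = "A",
                             opponent = "B", focal_role = "victim",
                             date_time = "2013-06-01T10:00:00",
                             physical = FALSE, counter = FALSE) {
  data.frame(session_id = session_id, kind = kind, focal = focal,
             opponent = opponent, focal_role = focal_role,
             date_time = date_time, conflict_physical = physical,
             conflict_counter = counter, stringsAsFactors = FALSE)
}

# A session "object" as get_session() returns, for the scalar operations.
fake_session <- function(events, focal = "A", opponent = "B", kind = "PC",
                         session_id = "S1") {
  list(session_id = session_id, kind = kind, focal = focal,
       opponent = opponent, events = events)
}

no_events <- function() data.frame(
  session_id = character(0), t = numeric(0), actor = character(0),
  recipient = character(0), behavior = character(0),
  oriented_at_recipient = logical(0), distance_m = numeric(0))

small_sim_config <- function(seed = 7, ...) {
  simulation_config(n_females = 12, n_conflicts = 60, census_sessions = 40,
                    seed = seed, ...)
}

# Null world for the simulator: the PC affiliation process (marginal
# probability and first-minute distribution) is made identical to the MC
# per-minute hazard process, with all covariate slopes at zero.
null_sim_config <- function(seed, hazard = 0.088, ...) {
  p_any <- 1 - (1 - hazard)^5
  w <- hazard * (1 - hazard)^(0:4) / p_any
  simulation_config(
    pc_affiliation_model = c(intercept = stats::qlogis(p_any),
                             familiarity = 0, rank_diff = 0, physical = 0,
                             counter = 0),
    pc_minute_weights = w,
    mc_affiliation_hazard = hazard,
    seed = seed, ...)
}

# A bare logistic mixed-model table with known coefficients, for the
# parameter-recovery and zero-variance contracts.
simulate_glmm_table <- function(n = 400, beta = c(0, 1.5), re_sd = 0.5,
                                n_subjects = 40, n_opponents = 40, seed = 1) {
  set.seed(seed)
  subject <- sample(sprintf("S%02d", seq_len(n_subjects)), n, replace = TRUE)
  opponent <- sample(sprintf("O%02d", seq_len(n_opponents)), n, replace = TRUE)
  u_s <- stats::setNames(rnorm(n_subjects, 0, re_sd),
                         sprintf("S%02d", seq_len(n_subjects)))
  u_o <- stats::setNames(rnorm(n_opponents, 0, re_sd),
                         sprintf("O%02d", seq_len(n_opponents)))
  x <- rnorm(n)
  eta <- beta[1] + beta[2] * x + u_s[subject] + u_o[opponent]
  data.frame(response = runif(n) < plogis(eta), x = x,
             subject = subject, opponent = opponent,
             stringsAsFactors = FALSE)
}

glmm_sim_spec <- function() {
  structure(list(model_id = "SIM", role_subset = "victim",
                 sessions = "PC", response = "response", fixed = "x",
                 label = "simulation check"),
            class = "pcmc_model_spec")
}

# Independent brute-force pair classifier, straight from the verbal rule:
# attracted iff affiliation only in / earlier in PC; dispersed mirrored;
# neutral on ties and double absence. Used as the enumeration oracle.
oracle_classify <- function(pc, mc, t) {
  p <- if (is.na(pc)) 6L else pc
  m <- if (is.na(mc)) 6L else mc
  overall <- if (p < m) "attracted" else if (m < p) "dispersed" else "neutral"
  if (overall == "attracted" && p == t) "attracted"
  else if (overall == "dispersed" && m == t) "dispersed"
  else "neutral"
}
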