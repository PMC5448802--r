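#' Qualifying affiliative events of a session
#'
#' Affiliative behaviours are contact, grooming (either direction), approach
#' and vocalization; a vocalization qualifies only when the caller's face is
#' oriented at the recipient within 5 m. The event must involve the focal
#' (as actor or recipient). Under `opponent_only` scope the other party must
#' be the former opponent; under `any_partner` any partner counts.
#'
#' @keywords internal
affiliative_events <- function(session,
                               scope = c("opponent_only", "any_partner")) {
  scope <- match.arg(scope)
  ev <- session$events
  if (!nrow(ev)) return(ev)
  aff <- ev$behavior %in% AFFILIATIVE_BEHAVIORS
  vocal <- ev$behavior == "vocalization"
  if (any(vocal & (is.na(ev$oriented_at_recipient) | is.na(ev$distance_m))))
    stop("vocalization event missing orientation or distance in session ",
         session$session_id)
  qual <- !vocal | (ev$oriented_at_recipient & !is.na(ev$distance_m) &
                      ev$distance_m <= VOCAL_MAX_DISTANCE_M)
  involves <- ev$actor == session$focal |
    (!is.na(ev$recipient) & ev$recipient == session$focal)
  other <- ifelse(ev$actor == session$focal, ev$recipient, ev$actor)
  in_scope <- if (scope == "opponent_only")
    !is.na(other) & other == session$opponent else TRUE
  ev[aff & qual & involves & in_scope, , drop = FALSE]
}

#' First affiliation minute of a session
#'
#' Minute (1..5) of the earliest qualifying affiliative event by or toward
#' the focal, or `NA` if none occurred. Minute m covers `[60(m-1), 60m)`:
#' an event at exactly 60 s falls in minute 2.
#'
#' @param session a session as returned by [get_session()]
#' @param scope `"opponent_only"` (the PC rule) or `"any_partner"` (the MC
#'   rule)
#' @return integer minute in 1..5, or `NA_integer_`
#' @export
first_affiliation_minute <- function(session,
                                     scope = c("opponent_only", "any_partner")) {
  t <- first_affiliation_time(session, scope)
  if (is.na(t)) NA_integer_ else as.integer(t %/% 60) + 1L
}

#' Time (seconds) of the first qualifying affiliation, or NA
#' @inheritParams first_affiliation_minute
#' @export
first_affiliation_time <- function(session,
                                   scope = c("opponent_only", "any_partner")) {
  ev <- affiliative_events(session, scope)
  if (!nrow(ev)) NA_real_ else min(ev$t)
}

#' Classify a PC-MC pair at one timeframe
#'
#' A pair is *attracted* at timeframe t iff the PC first-affiliation minute
#' equals t and the MC affiliation is absent or later; *dispersed* at t iff
#' the MC minute equals t and the PC affiliation is absent or later;
#' *neutral* otherwise (ties at the same minute, and double absence, are
#' neutral). A pair is therefore attracted (dispersed) at exactly the minute
#' of its earlier first affiliation, or at none, so the per-timeframe labels
#' partition the pair-level categories.
#'
#' @param pc_minute PC first-affiliation minute (1..5 or `NA`); vectorized
#' @param mc_minute MC first-affiliation minute (1..5 or `NA`); vectorized
#' @param t timeframe 1..5
#' @return character vector: `"attracted"`, `"dispersed"` or `"neutral"`
#' @export
classify_pair_at_timeframe <- function(pc_minute, mc_minute, t) {
  stopifnot(all(t %in% 1:5),
            all(is.na(pc_minute) | pc_minute %in% 1:5),
            all(is.na(mc_minute) | mc_minute %in% 1:5))
  attracted <- !is.na(pc_minute) & pc_minute == t &
    (is.na(mc_minute) | mc_minute > t)
  dispersed <- !is.na(mc_minute) & mc_minute == t &
    (is.na(pc_minute) | pc_minute > t)
  ifelse(attracted, "attracted", ifelse(dispersed, "dispersed", "neutral"))
}

#' Pair-level attracted/dispersed/neutral label
#'
#' Attracted iff affiliation occurred only in, or earlier in, the PC than in
#' the MC; dispersed for the mirror case; neutral on ties and double absence.
#'
#' @inheritParams classify_pair_at_timeframe
#' @return character vector of labels
#' @export
classify_pair_overall <- function(pc_minute, mc_minute) {
  p <- ifelse(is.na(pc_minute), Inf, pc_minute)
  m <- ifelse(is.na(mc_minute), Inf, mc_minute)
  ifelse(p < m, "attracted", ifelse(m < p, "dispersed", "neutral"))
}

# Materialize session objects for many ids at once (one split of the event
# table instead of a scan per session).
session_list <- function(x, ids) {
  ev_idx <- split(seq_len(nrow(x$events)), x$events$session_id)
  srows <- x$sessions[match(ids, x$sessions$session_id), , drop = FALSE]
  if (anyNA(srows$session_id)) stop("unknown session id in pair table")
  lapply(seq_along(ids), function(i) {
    out <- as.list(srows[i, ])
    idx <- ev_idx[[ids[i]]]
    out$events <- x$events[if (is.null(idx)) integer(0) else idx, ,
                           drop = FALSE]
    out
  })
}

#' Classify every PC-MC pair of a dataset
#'
#' Applies the scope asymmetry of the design: in PC sessions only
#' affiliation with the former opponent counts; in MC sessions affiliation
#' with any partner (including the former opponent) counts.
#'
#' @param x a `pcmc_data` object
#' @param pairs pair table (defaults to `x$pairs`)
#' @param pc_scope,mc_scope scope overrides (defaults per the design)
#' @return data frame with one row per pair: subject, role, PC/MC minutes,
#'   overall label and the five per-timeframe labels `t1`..`t5`
#' @export
classify_pairs <- function(x, pairs = x$pairs,
                           pc_scope = "opponent_only",
                           mc_scope = "any_partner") {
  stopifnot(inherits(x, "pcmc_data"), !is.null(pairs), nrow(pairs) > 0)
  pcm <- vapply(session_list(x, pairs$pc), first_affiliation_minute,
                integer(1), scope = pc_scope)
  mcm <- vapply(session_list(x, pairs$mc), first_affiliation_minute,
                integer(1), scope = mc_scope)
  srow <- x$sessions[match(pairs$pc, x$sessions$session_id), ]
  out <- data.frame(pair_id = pairs$pair_id, subject = srow$focal,
                    opponent = srow$opponent, role = srow$focal_role,
                    pc_minute = pcm, mc_minute = mcm,
                    overall = classify_pair_overall(pcm, mcm),
                    stringsAsFactors = FALSE)
  for (t in 1:5)
    out[[paste0("t", t)]] <- classify_pair_at_timeframe(pcm, mcm, t)
  rownames(out) <- NULL
  out
}

#' Long-format (pair, timeframe, label) view of a classification
#' @param classified output of [classify_pairs()]
#' @return data frame: pair_id, subject, role, timeframe, label
#' @export
classification_long <- function(classified) {
  do.call(rbind, lapply(1:5, function(t)
    data.frame(pair_id = classified$pair_id, subject = classified$subject,
               role = classified$role, timeframe = t,
               label = classified[[paste0("t", t)]],
               stringsAsFactors = FALSE)))
}

#' Per-subject attracted/dispersed proportions and conciliatory tendency
#'
#' Subjects observed in fewer than `min_pairs` PC-MC pairs are excluded.
#' Proportions are per-subject means over that subject's pairs; the
#' conciliatory tendency of a subject is
#' (attracted pairs - dispersed pairs) / n pairs, using the pair-level
#' classification.
#'
#' @param classified output of [classify_pairs()]
#' @param min_pairs minimum pairs per retained subject (default 3)
#' @return data frame, one row per retained subject, with columns
#'   `subject`, `n_pairs`, `att_t1`..`att_t5`, `dis_t1`..`dis_t5`,
#'   `attracted`, `dispersed`, `ct`; the excluded subjects are attached as
#'   attribute `"excluded"`
#' @export
subject_proportions <- function(classified, min_pairs = 3) {
  if (!nrow(classified)) {
    warning("no classified pairs; returning empty proportions table")
    return(data.frame(subject = character(), n_pairs = integer()))
  }
  split_idx <- split(seq_len(nrow(classified)), classified$subject)
  rows <- lapply(names(split_idx), function(s) {
    d <- classified[split_idx[[s]], , drop = FALSE]
    n <- nrow(d)
    r <- data.frame(subject = s, n_pairs = n, stringsAsFactors = FALSE)
    for (t in 1:5) {
      r[[paste0("att_t", t)]] <- mean(d[[paste0("t", t)]] == "attracted")
      r[[paste0("dis_t", t)]] <- mean(d[[paste0("t", t)]] == "dispersed")
    }
    r$attracted <- mean(d$overall == "attracted")
    r$dispersed <- mean(d$overall == "dispersed")
    r$ct <- (sum(d$overall == "attracted") - sum(d$overall == "dispersed")) / n
    r
  })
  out <- do.call(rbind, rows)
  excluded <- out$subject[out$n_pairs < min_pairs]
  out <- out[out$n_pairs >= min_pairs, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Group conciliatory tendency
#'
#' Unweighted mean over subjects of the per-subject conciliatory tendency.
#'
#' @param props output of [subject_proportions()]
#' @return a fraction in \[-1, 1\]
#' @export
conciliatory_tendency <- function(props) {
  stopifnot(nrow(props) > 0)
  mean(props$ct)
}

#' Did the focal give a qualifying vocalization?
#'
#' TRUE iff some vocalization *by the focal* was oriented at its recipient
#' within 5 m, with the recipient in scope.
#'
#' @inheritParams first_affiliation_minute
#' @return logical
#' @export
vocal_given <- function(session, scope = c("opponent_only", "any_partner")) {
  scope <- match.arg(scope)
  ev <- session$events
  if (!nrow(ev)) return(FALSE)
  vocal <- ev$behavior == "vocalization" & ev$actor == session$focal
  if (any(vocal & is.na(ev$distance_m)))
    stop("vocalization event missing distance_m in session ",
         session$session_id)
  ok <- vocal & !is.na(ev$oriented_at_recipient) & ev$oriented_at_recipient &
    ev$distance_m <= VOCAL_MAX_DISTANCE_M
  if (scope == "opponent_only")
    ok <- ok & !is.na(ev$recipient) & ev$recipient == session$opponent
  any(ok)
}

#' Aggression exposure in the risk window (Model 3 rule)
#'
#' If affiliation with the former opponent occurred, aggression counts from
#' the initiation of the affiliative behaviours to the session end
#' (`[t_affiliation, 300)`); if not, it counts over the whole session except
#' the first minute (`[60, 300)`).
#'
#' @param session a PC session as returned by [get_session()]
#' @param affiliation_t time (s) of the first affiliation with the opponent,
#'   or `NA`/`NULL` when none occurred; defaults to computing it
#' @return logical: did the focal receive aggression from the opponent in
#'   the window?
#' @export
aggression_exposure <- function(session, affiliation_t = NULL) {
  if (is.null(affiliation_t))
    affiliation_t <- first_affiliation_time(session, "opponent_only")
  lo <- if (is.na(affiliation_t)) 60 else affiliation_t
  ev <- session$events
  if (!nrow(ev)) return(FALSE)
  agg <- ev$behavior %in% AGGRESSIVE_BEHAVIORS &
    ev$actor == session$opponent &
    !is.na(ev$recipient) & ev$recipient == session$focal &
    ev$t >= lo & ev$t < SESSION_SECONDS
  any(agg)
}

#' Did the focal receive aggression from anyone, anywhere in the session?
#' @param session a session as returned by [get_session()]
#' @return logical
#' @export
received_aggression_any <- function(session) {
  ev <- session$events
  if (!nrow(ev)) return(FALSE)
  any(ev$behavior %in% AGGRESSIVE_BEHAVIORS &
        !is.na(ev$recipient) & ev$recipient == session$focal)
}
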