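#' Column mapping for event and session tables
#'
#' Declares how columns of an input CSV/TSV map onto the internal field
#' names. Values are the column names as they appear in the file; names are
#' the internal fields. Defaults are the identity mapping.
#'
#' @param events named character vector for the event table
#' @param sessions named character vector for the session table
#' @param census named character vector for the census table
#' @return an object of class `pcmc_mapping`
#' @export
pcmc_mapping <- function(events = NULL, sessions = NULL, census = NULL) {
  ev <- c(session_id = "session_id", t = "t", actor = "actor",
          recipient = "recipient", behavior = "behavior",
          oriented_at_recipient = "oriented_at_recipient",
          distance_m = "distance_m")
  se <- c(session_id = "session_id", kind = "kind", focal = "focal",
          opponent = "opponent", focal_role = "focal_role",
          date_time = "date_time", conflict_physical = "conflict_physical",
          conflict_counter = "conflict_counter")
  ce <- c(census_id = "census_id", date = "date", female = "female",
          state = "state", partners = "partners")
  if (!is.null(events))   ev[names(events)] <- events
  if (!is.null(sessions)) se[names(sessions)] <- sessions
  if (!is.null(census))   ce[names(census)] <- census
  structure(list(events = ev, sessions = se, census = ce),
            class = "pcmc_mapping")
}

read_table_mapped <- function(path, mapping, what, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing <- setdiff(unname(mapping), names(raw))
  if (length(missing)) {
    stop(sprintf("schema error in %s table '%s': missing column(s) %s",
                 what, basename(path), paste(sQuote(missing), collapse = ", ")))
  }
  out <- raw[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  out
}

coerce_events <- function(events) {
  events$session_id <- as.character(events$session_id)
  events$t <- as.numeric(events$t)
  events$actor <- as.character(events$actor)
  events$recipient <- as.character(events$recipient)
  events$recipient[!is.na(events$recipient) & events$recipient == ""] <- NA_character_
  events$behavior <- as.character(events$behavior)
  events$oriented_at_recipient <- as.logical(events$oriented_at_recipient)
  events$distance_m <- as.numeric(events$distance_m)
  events
}

coerce_sessions <- function(sessions) {
  sessions$session_id <- as.character(sessions$session_id)
  sessions$kind <- as.character(sessions$kind)
  sessions$focal <- as.character(sessions$focal)
  sessions$opponent <- as.character(sessions$opponent)
  sessions$focal_role <- as.character(sessions$focal_role)
  if (!inherits(sessions$date_time, "POSIXct")) {
    sessions$date_time <- as.POSIXct(sessions$date_time,
                                     format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  sessions$conflict_physical <- as.logical(sessions$conflict_physical)
  sessions$conflict_counter <- as.logical(sessions$conflict_counter)
  sessions
}

#' Validate an event table
#'
#' Enforces the event-record invariants: known behaviour labels, event times
#' inside the 5-min session `[0, 300)`, and orientation/distance present on
#' vocalization rows (legal to leave unset elsewhere).
#'
#' @param events event data frame (internal column names)
#' @return invisibly, a data frame of problems (empty when valid); errors
#'   by default
#' @param action `"error"` to stop on the first collected batch of
#'   problems, `"report"` to return them
#' @export
validate_events <- function(events, action = c("error", "report")) {
  action <- match.arg(action)
  problems <- list()
  bad <- function(rows, msg) {
    if (length(rows)) {
      problems[[length(problems) + 1L]] <<-
        data.frame(row = rows, problem = msg, stringsAsFactors = FALSE)
    }
  }
  bad(which(is.na(events$t) | events$t < 0 | events$t >= SESSION_SECONDS),
      sprintf("t outside [0, %d)", SESSION_SECONDS))
  bad(which(!events$behavior %in% ALL_BEHAVIORS), "unknown behavior label")
  vocal <- events$behavior == "vocalization"
  bad(which(vocal & is.na(events$oriented_at_recipient)),
      "vocalization row missing oriented_at_recipient")
  bad(which(vocal & is.na(events$distance_m)),
      "vocalization row missing distance_m")
  bad(which(!is.na(events$distance_m) & events$distance_m < 0),
      "negative distance_m")
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(), problem = character())
  if (action == "error" && nrow(problems)) {
    stop("event validation failed:\n",
         paste(sprintf("  row %d: %s", problems$row, problems$problem),
               collapse = "\n"))
  }
  invisible(problems)
}

validate_sessions <- function(sessions) {
  if (anyDuplicated(sessions$session_id))
    stop("duplicate session_id in session table")
  if (!all(sessions$kind %in% c("PC", "MC")))
    stop("session kind must be PC or MC")
  if (!all(sessions$focal_role %in% c("aggressor", "victim")))
    stop("focal_role must be aggressor or victim")
  if (any(is.na(sessions$date_time)))
    stop("unparseable date_time (expected ISO-8601, e.g. 2013-06-01T10:00:00)")
  invisible(sessions)
}

#' Construct a PC-MC dataset container
#'
#' Bundles the session table, the event table and (optionally) census and
#' pairing tables, after validation. Events are sorted by session and time.
#'
#' @param sessions session data frame
#' @param events event data frame
#' @param census optional census data frame
#' @param pairs optional pair table (`pair_id`, `pc`, `mc`)
#' @param truth optional simulation ground truth
#' @return an object of class `pcmc_data`
#' @export
pcmc_data <- function(sessions, events, census = NULL, pairs = NULL,
                      truth = NULL) {
  sessions <- validate_sessions(coerce_sessions(sessions))
  events <- coerce_events(events)
  validate_events(events)
  orphan <- setdiff(events$session_id, sessions$session_id)
  if (length(orphan))
    stop("events reference unknown session(s): ",
         paste(utils::head(orphan, 5), collapse = ", "))
  events <- events[order(events$session_id, events$t), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(sessions = sessions, events = events, census = census,
                 pairs = pairs, truth = truth),
            class = "pcmc_data")
}

#' @export
print.pcmc_data <- function(x, ...) {
  cat(sprintf("<pcmc_data> %d sessions (%d PC / %d MC), %d events\n",
              nrow(x$sessions), sum(x$sessions$kind == "PC"),
              sum(x$sessions$kind == "MC"), nrow(x$events)))
  if (!is.null(x$pairs)) cat(sprintf("  %d PC-MC pairs\n", nrow(x$pairs)))
  if (!is.null(x$census))
    cat(sprintf("  %d census rows over %d sessions\n",
                nrow(x$census), length(unique(x$census$census_id))))
  invisible(x)
}

#' Read behavioural event and session tables
#'
#' @param events_path path to the event CSV/TSV
#' @param sessions_path path to the session CSV/TSV
#' @param mapping column mapping from [pcmc_mapping()]
#' @param dialect `"csv"` or `"tsv"`
#' @return a [pcmc_data()] object with events time-sorted
#' @export
read_events <- function(events_path, sessions_path,
                        mapping = pcmc_mapping(), dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  events <- read_table_mapped(events_path, mapping$events, "event", dialect)
  sessions <- read_table_mapped(sessions_path, mapping$sessions, "session",
                                dialect)
  if (!nrow(events)) warning("event table is empty (header only)")
  pcmc_data(sessions, events)
}

#' Write a dataset back to normalized CSV tables
#'
#' Writes `events.csv` and `sessions.csv` (plus `pairs.csv` / `census.csv`
#' when present) such that [read_events()] round-trips field for field.
#'
#' @param x a `pcmc_data` object
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_events <- function(x, dir) {
  stopifnot(inherits(x, "pcmc_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  se <- x$sessions
  se$date_time <- format(se$date_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  paths <- c(events = file.path(dir, "events.csv"),
             sessions = file.path(dir, "sessions.csv"))
  utils::write.csv(x$events, paths["events"], row.names = FALSE, na = "")
  utils::write.csv(se, paths["sessions"], row.names = FALSE, na = "")
  if (!is.null(x$pairs)) {
    paths["pairs"] <- file.path(dir, "pairs.csv")
    utils::write.csv(x$pairs, paths["pairs"], row.names = FALSE, na = "")
  }
  if (!is.null(x$census)) {
    paths["census"] <- file.path(dir, "census.csv")
    utils::write.csv(x$census, paths["census"], row.names = FALSE, na = "")
  }
  invisible(paths)
}

seconds_of_day <- function(dt) {
  as.numeric(dt) - as.numeric(as.POSIXct(format(dt, "%Y-%m-%d"), tz = "UTC"))
}

#' Pair PC sessions with their matched controls
#'
#' Each post-conflict (PC) session is matched to at most one matched-control
#' (MC) session of the same focal animal, same former opponent and same
#' focal role, observed at least one day and at most 14 days later at
#' approximately the same time of day (within 2 h). When several MCs are
#' eligible the earliest is taken (with a warning). Sessions are sorted
#' before matching, so the pairing is stable under permutation of the input.
#'
#' @param x a `pcmc_data` object or a session data frame
#' @return a list with `pairs` (data frame: `pair_id`, `pc`, `mc`),
#'   `unmatched` (session ids), and `issues` (violations found, reported
#'   rather than silently dropped)
#' @export
pair_pc_mc <- function(x) {
  sessions <- if (inherits(x, "pcmc_data")) x$sessions else
    validate_sessions(coerce_sessions(x))
  sessions <- sessions[order(sessions$date_time, sessions$session_id), ,
                       drop = FALSE]
  pc <- sessions[sessions$kind == "PC", , drop = FALSE]
  mc <- sessions[sessions$kind == "MC", , drop = FALSE]
  used <- character(0)
  issues <- list()
  pairs <- list()
  for (i in seq_len(nrow(pc))) {
    p <- pc[i, ]
    same <- mc$focal == p$focal & mc$opponent == p$opponent &
      mc$focal_role == p$focal_role & !(mc$session_id %in% used)
    ident <- mc[same, , drop = FALSE]
    if (!nrow(ident)) next
    day_diff <- as.numeric(as.Date(ident$date_time) - as.Date(p$date_time))
    tod_diff <- abs(seconds_of_day(ident$date_time) -
                      seconds_of_day(p$date_time))
    early <- day_diff < 1
    if (any(early)) {
      issues[[length(issues) + 1L]] <- data.frame(
        pc = p$session_id, mc = ident$session_id[early],
        problem = "candidate MC not later than PC", stringsAsFactors = FALSE)
    }
    flags_ok <- ident$conflict_physical == p$conflict_physical &
      ident$conflict_counter == p$conflict_counter
    if (any(!flags_ok)) {
      issues[[length(issues) + 1L]] <- data.frame(
        pc = p$session_id, mc = ident$session_id[!flags_ok],
        problem = "conflict attributes differ within candidate pair",
        stringsAsFactors = FALSE)
    }
    ok <- day_diff >= 1 & day_diff <= 14 & tod_diff <= 2 * 3600 & flags_ok
    cand <- ident[ok, , drop = FALSE]
    if (!nrow(cand)) next
    if (nrow(cand) > 1)
      warning(sprintf("PC %s: %d eligible MCs, taking the earliest",
                      p$session_id, nrow(cand)))
    chosen <- cand$session_id[order(cand$date_time, cand$session_id)][1]
    used <- c(used, chosen)
    pairs[[length(pairs) + 1L]] <- data.frame(
      pc = p$session_id, mc = chosen, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pc = character(), mc = character())
  if (nrow(pairs)) pairs <- cbind(pair_id = sprintf("P%04d", seq_len(nrow(pairs))),
                                  pairs, stringsAsFactors = FALSE)
  else pairs <- cbind(pair_id = character(), pairs)
  unmatched <- setdiff(sessions$session_id, c(pairs$pc, pairs$mc))
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(pc = character(), mc = character(), problem = character())
  list(pairs = pairs, unmatched = unmatched, issues = issues)
}

#' Postponement rule for PC sessions
#'
#' A PC session must be postponed (restarted) if aggression between the
#' former opponents resumes within 30 s of the end of the original conflict.
#'
#' @param conflict_end_t end of the conflict, seconds (nonnegative)
#' @param renewed_aggression_ts times of renewed aggression, seconds
#' @return `TRUE` if the session is usable, `FALSE` if it must be postponed
#' @export
validate_postponement <- function(conflict_end_t, renewed_aggression_ts) {
  stopifnot(conflict_end_t >= 0, all(renewed_aggression_ts >= 0))
  since <- renewed_aggression_ts - conflict_end_t
  !any(since >= 0 & since < POSTPONE_WINDOW_S)
}

#' Retrieve one session with its events
#'
#' @param x a `pcmc_data` object
#' @param session_id the session to extract
#' @return a list with the session fields plus `events`
#' @export
get_session <- function(x, session_id) {
  stopifnot(inherits(x, "pcmc_data"))
  row <- x$sessions[x$sessions$session_id == session_id, , drop = FALSE]
  if (!nrow(row)) stop("unknown session: ", session_id)
  out <- as.list(row)
  out$events <- x$events[x$events$session_id == session_id, , drop = FALSE]
  out
}

deposited_sheets <- c("sessions", "events", "census")

#' Read a deposited-style dataset (XLSX or CSV directory)
#'
#' Adapter for a deposited workbook holding `sessions`, `events` and
#' optionally `census` sheets in the same layout the simulator writes
#' ([write_deposited_dataset()]). The published supplementary workbook this
#' layout stands in for was not available when the adapter was written, so
#' the schema is the package's own (synthetic) deposited-style layout; an
#' unmappable schema raises an explicit adapter error rather than a silent
#' partial load. XLSX needs the readxl package; a directory of CSV sheets is
#' read with base R.
#'
#' @param path an `.xlsx` file or a directory containing `sessions.csv`,
#'   `events.csv` (and optionally `census.csv`)
#' @param mapping column mapping, as in [read_events()]
#' @return a list with `data` (a [pcmc_data()] with pairs attached),
#'   `pairs`, `unmatched`, `issues`, and `covariates` (one row per pair)
#' @export
read_deposited_dataset <- function(path, mapping = pcmc_mapping()) {
  read_sheet <- function(sheet) {
    if (dir.exists(path)) {
      f <- file.path(path, paste0(sheet, ".csv"))
      if (!file.exists(f)) {
        if (sheet == "census") return(NULL)
        stop("deposited-dataset adapter error: missing sheet '", sheet, "'")
      }
      utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading .xlsx needs the readxl package")
      sheets <- readxl::excel_sheets(path)
      if (!sheet %in% sheets) {
        if (sheet == "census") return(NULL)
        stop("deposited-dataset adapter error: missing sheet '", sheet, "'")
      }
      as.data.frame(readxl::read_excel(path, sheet = sheet))
    }
  }
  check <- function(df, map, sheet) {
    missing <- setdiff(unname(map), names(df))
    if (length(missing))
      stop(sprintf(
        "deposited-dataset adapter error: sheet '%s' is missing column(s) %s",
        sheet, paste(sQuote(missing), collapse = ", ")))
    out <- df[, unname(map), drop = FALSE]
    names(out) <- names(map)
    out
  }
  sessions <- check(read_sheet("sessions"), mapping$sessions, "sessions")
  events <- check(read_sheet("events"), mapping$events, "events")
  census <- read_sheet("census")
  if (!is.null(census)) census <- check(census, mapping$census, "census")
  data <- pcmc_data(sessions, events, census = census)
  pairing <- pair_pc_mc(data)
  data$pairs <- pairing$pairs
  pcrows <- data$sessions[match(pairing$pairs$pc, data$sessions$session_id), ]
  covariates <- data.frame(
    pair_id = pairing$pairs$pair_id,
    focal = pcrows$focal, opponent = pcrows$opponent,
    focal_role = pcrows$focal_role,
    conflict_physical = pcrows$conflict_physical,
    conflict_counter = pcrows$conflict_counter,
    stringsAsFactors = FALSE)
  list(data = data, pairs = pairing$pairs, unmatched = pairing$unmatched,
       issues = pairing$issues, covariates = covariates)
}

#' Write a dataset in the deposited-style layout
#'
#' Writes the directory-of-CSV-sheets form accepted by
#' [read_deposited_dataset()]; the round trip is lossless at field level.
#'
#' @param x a `pcmc_data` object
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_deposited_dataset <- function(x, dir) {
  write_events(x, dir)
  invisible(dir)
}
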