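#' Pipeline configuration
#'
#' One declarative config governs every stage; it is echoed into the report
#' so each number is traceable to the settings that produced it.
#'
#' @param min_pairs minimum PC-MC pairs per retained subject (default 3)
#' @param models model ids to fit (default all seven)
#' @param slopes random-slope policy passed to [fit_model()]; the pipeline
#'   default is `"none"` for run-time predictability (see the methods
#'   vignette), `"auto"` gives the attempt-then-reduce behaviour
#' @param fit_models fit the GLMM suite at all?
#' @param period_boundary date splitting the two familiarity periods
#' @param h_prime_randomizations,h_prime_seed linearity randomization budget
#' @param restrict_correlation_to_pairs restrict the between-period
#'   familiarity correlation to dyads appearing in analyzed PC-MC pairs?
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(min_pairs = 3,
                            models = MODEL_IDS,
                            slopes = "none",
                            fit_models = TRUE,
                            period_boundary = as.Date("2014-04-01"),
                            h_prime_randomizations = 1000L,
                            h_prime_seed = 1L,
                            restrict_correlation_to_pairs = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full PC-MC analysis pipeline
#'
#' Executes the analysis chain: validation and pairing, minute-by-minute
#' attracted/dispersed classification, per-subject proportions and exact
#' signed-rank tests, conciliatory tendency, dominance ranks and linearity,
#' familiarity matrices and their between-period correlation, occurrence /
#' risk / vocal-use summaries, and the model suite. Regeneration from the
#' same inputs and config is bit-identical (all randomization is seeded).
#'
#' @param data a `pcmc_data` object (pairs attached or derivable)
#' @param config a [pipeline_config()]
#' @return an object of class `pcmc_report`
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  stopifnot(inherits(data, "pcmc_data"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  pairing <- stage("pairing", {
    if (is.null(data$pairs)) pair_pc_mc(data) else
      list(pairs = data$pairs, unmatched = character(0),
           issues = data.frame())
  })
  pairs <- pairing$pairs
  classified <- stage("classification", classify_pairs(data, pairs))
  props <- stage("proportions",
                 subject_proportions(classified, config$min_pairs))
  timeframe_tests <- stage("exact tests", lapply(1:5, function(t) {
    x <- props[[paste0("att_t", t)]]
    y <- props[[paste0("dis_t", t)]]
    tst <- exact_wilcoxon_test(x, y)
    list(timeframe = t,
         attracted_mean_pct = round(100 * mean(x), 1),
         attracted_sd_pct = round(100 * stats::sd(x), 1),
         dispersed_mean_pct = round(100 * mean(y), 1),
         dispersed_sd_pct = round(100 * stats::sd(y), 1),
         V = tst$V, p = tst$p, n_subjects = nrow(props))
  }))
  ct <- stage("conciliatory tendency", conciliatory_tendency(props))

  dominance <- NULL
  ranks <- data$truth$ranks
  if (!is.null(data$truth$win_matrix)) {
    dominance <- stage("dominance", {
      ro <- rank_order(data$truth$win_matrix)
      hp <- devries_h_prime(data$truth$win_matrix,
                            n_randomizations = config$h_prime_randomizations,
                            seed = config$h_prime_seed)
      list(ranks = ro$ranks, inconsistencies = ro$inconsistencies,
           h_prime = hp$h_prime, p_linearity = hp$p_linearity)
    })
    ranks <- dominance$ranks
  }

  familiarity <- NULL
  fam_cov <- if (!is.null(data$truth$familiarity)) data$truth$familiarity
  if (!is.null(data$census)) {
    familiarity <- stage("familiarity", {
      sp <- split_periods(data$census, config$period_boundary)
      ids <- sort(unique(c(data$sessions$focal, data$sessions$opponent,
                           data$census$female)))
      m1 <- familiarity_matrix(sp$period1, ids, label = "period1")
      m2 <- familiarity_matrix(sp$period2, ids, label = "period2")
      dyads <- if (config$restrict_correlation_to_pairs) {
        pcrows <- data$sessions[match(pairs$pc, data$sessions$session_id), ]
        unique(data.frame(A = pcrows$focal, B = pcrows$opponent,
                          stringsAsFactors = FALSE))
      }
      corr <- tryCatch(period_correlation(m1, m2, dyads),
                       error = function(e) list(note = conditionMessage(e)))
      list(period1 = m1, period2 = m2, correlation = corr,
           n_sessions = c(period1 = length(unique(sp$period1$census_id)),
                          period2 = length(unique(sp$period2$census_id))))
    })
    fam_cov <- list(period1 = familiarity$period1,
                    period2 = familiarity$period2,
                    boundary = config$period_boundary)
  }

  flags <- stage("session summaries", session_flags(data, pairs))
  summarize_role <- function(r) {
    f <- flags[flags$role == r, ]
    pc <- f[f$kind == "PC", ]; mc <- f[f$kind == "MC", ]
    va_pc <- sum(pc$vocal); na_pc <- sum(pc$affiliation)
    va_mc <- sum(mc$vocal); na_mc <- sum(mc$affiliation)
    list(n_pairs = nrow(pc),
         pc_affiliation = na_pc, mc_affiliation = na_mc,
         pc_received_from_opponent = sum(pc$received_opp_windowed),
         pc_vocal = va_pc,
         pc_vocal_pct = if (na_pc) pct(va_pc, na_pc) else NA_real_,
         mc_vocal = va_mc,
         mc_vocal_pct = if (na_mc) pct(va_mc, na_mc) else NA_real_)
  }
  role_summaries <- list(aggressor = summarize_role("aggressor"),
                         victim = summarize_role("victim"))
  vf <- flags[flags$role == "victim" & flags$kind == "PC" & flags$affiliation, ]
  consequence <- list(
    n_affiliation = nrow(vf),
    by_type = lapply(split(vf, vf$behavior_type), function(d)
      list(n = nrow(d), aggression = sum(d$received_after_affiliation),
           pct = if (nrow(d)) pct(sum(d$received_after_affiliation), nrow(d))
           else NA_real_)))

  fits <- NULL
  if (config$fit_models) {
    fits <- stage("models", {
      out <- list()
      for (id in config$models) {
        spec <- model_spec(id)
        tab <- assemble_model_table(data, spec, familiarity = fam_cov,
                                    ranks = ranks, pairs = pairs)
        roles <- if (spec$role_subset == "each")
          c("aggressor", "victim") else spec$role_subset
        for (r in roles) {
          sub <- tab[tab$role == r, , drop = FALSE]
          key <- if (length(roles) > 1) paste(id, r, sep = "_") else id
          out[[key]] <- tryCatch(
            fit_model(sub, spec, slopes = config$slopes),
            error = function(e) list(model_id = id, role = r,
                                     error = conditionMessage(e)))
        }
      }
      out
    })
  }

  report <- list(
    pairing = list(n_pairs = nrow(pairs),
                   n_unmatched = length(pairing$unmatched),
                   unmatched = pairing$unmatched),
    classification = classified,
    proportions = props,
    excluded_subjects = attr(props, "excluded"),
    timeframes = timeframe_tests,
    conciliatory_tendency_pct = round(100 * ct, 1),
    dominance = dominance,
    familiarity = familiarity,
    role_summaries = role_summaries,
    consequence = consequence,
    fits = fits,
    provenance = list(
      seed = data$truth$config$seed %||% NA,
      generated = !is.null(data$truth),
      config = config[setdiff(names(config), "models")],
      models = config$models,
      n_sessions = nrow(data$sessions), n_events = nrow(data$events)))
  class(report) <- "pcmc_report"
  report
}

#' @export
print.pcmc_report <- function(x, ...) {
  cat("<pcmc_report>\n")
  cat(sprintf("  pairs: %d (unmatched sessions: %d)\n",
              x$pairing$n_pairs, x$pairing$n_unmatched))
  cat(sprintf("  subjects retained: %d (excluded: %d)\n",
              nrow(x$proportions), length(x$excluded_subjects)))
  t1 <- x$timeframes[[1]]
  cat(sprintf("  minute 1: attracted %.1f%% vs dispersed %.1f%% (V = %g, p = %.3g)\n",
              t1$attracted_mean_pct, t1$dispersed_mean_pct, t1$V, t1$p))
  cat(sprintf("  conciliatory tendency: %.1f%%\n", x$conciliatory_tendency_pct))
  if (!is.null(x$fits))
    cat("  models fitted:", paste(names(x$fits), collapse = ", "), "\n")
  invisible(x)
}

strip_fit <- function(f) {
  if (!inherits(f, "pcmc_fit")) return(f)
  f$fit <- NULL
  unclass(f)
}

#' Write a pipeline report to disk (JSON summary + CSV tables)
#'
#' @param report a `pcmc_report`
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(classification = file.path(dir, "classifications.csv"),
             proportions = file.path(dir, "subject_proportions.csv"),
             summary = file.path(dir, "report.json"))
  utils::write.csv(classification_long(report$classification),
                   paths["classification"], row.names = FALSE)
  utils::write.csv(report$proportions, paths["proportions"],
                   row.names = FALSE)
  slim <- report
  slim$classification <- NULL
  slim$proportions <- NULL
  slim$fits <- lapply(report$fits, strip_fit)
  slim$familiarity$period1 <- NULL
  slim$familiarity$period2 <- NULL
  slim$dominance$ranks <- NULL
  jsonlite::write_json(unclass(slim), paths["summary"], auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  invisible(paths)
}
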