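MODEL_IDS <- c("M1", "M2", "M3", "M4", "M5", "M6", "M6prime")

# Fixed effects listed in the reduction order used when random slopes fail
# to converge (slopes are dropped from the end of this list first).
MODEL_REGISTRY <- list(
  M1 = list(
    role_subset = "each", sessions = "PC",
    response = "affiliation_opponent",
    fixed = c("physical", "counter", "rank_diff", "familiarity"),
    label = "occurrence of affiliative interaction with the former opponent in PC"),
  M2 = list(
    role_subset = "each", sessions = "PC_MC",
    response = "received_aggression_any",
    fixed = c("kind"),
    label = "risk of receiving aggression in PC and MC"),
  M3 = list(
    role_subset = "victim", sessions = "PC",
    response = "received_aggression_opponent_windowed",
    fixed = c("affiliation", "physical", "counter", "rank_diff", "familiarity"),
    label = "risk of receiving aggression from the former opponent in PC"),
  M4 = list(
    role_subset = "each", sessions = "affiliation_only",
    response = "vocal_use",
    fixed = c("kind"),
    label = "vocal use during affiliative interactions in PC and MC"),
  M5 = list(
    role_subset = "victim", sessions = "PC_affiliation",
    response = "vocal_use",
    fixed = c("physical", "counter", "rank_diff", "familiarity"),
    label = "vocal use toward the former opponent in PC"),
  M6 = list(
    role_subset = "victim", sessions = "PC_affiliation",
    response = "received_aggression_after_affiliation",
    # counter-aggression deliberately excluded: a model including it is not
    # estimable on data of this shape
    fixed = c("physical", "rank_diff", "familiarity", "vocal"),
    label = "aggression after post-conflict affiliation, by vocal use"),
  M6prime = list(
    role_subset = "victim", sessions = "PC_affiliation",
    response = "received_aggression_after_affiliation",
    fixed = c("physical", "rank_diff", "familiarity", "behavior_type"),
    label = "aggression after post-conflict affiliation, by behaviour type")
)

BEHAVIOR_TYPE_LEVELS <- c("contact_or_approach_only", "vocal_only",
                          "vocal_with_contact_or_approach")

#' Model registry: declarative specification of models 1-6'
#'
#' Returns the registry entry for one of the seven binomial mixed models:
#' response, fixed effects (in slope-reduction order), session subset and
#' role subset. Models are fitted separately by focal role where
#' `role_subset` is `"each"`.
#'
#' @param model_id one of `"M1"`, `"M2"`, `"M3"`, `"M4"`, `"M5"`, `"M6"`,
#'   `"M6prime"`
#' @return an object of class `pcmc_model_spec`
#' @export
model_spec <- function(model_id) {
  if (!model_id %in% MODEL_IDS)
    stop("unknown model id: ", model_id, " (expected one of ",
         paste(MODEL_IDS, collapse = ", "), ")")
  spec <- MODEL_REGISTRY[[model_id]]
  spec$model_id <- model_id
  spec$random_effects <- c("subject", "opponent")
  class(spec) <- "pcmc_model_spec"
  spec
}

#' @export
print.pcmc_model_spec <- function(x, ...) {
  cat(sprintf("<model %s> %s\n", x$model_id, x$label))
  cat("  response:", x$response, "\n")
  cat("  fixed:   ", paste(x$fixed, collapse = ", "), "\n")
  cat("  subset:  ", x$sessions, "sessions,", x$role_subset, "role(s)\n")
  invisible(x)
}

session_flags <- function(x, pairs) {
  # per-session derived quantities reused by several models
  ids <- c(pairs$pc, pairs$mc)
  sess <- session_list(x, ids)
  per <- lapply(sess, function(s) {
    scope <- if (s$kind == "PC") "opponent_only" else "any_partner"
    aff_t <- first_affiliation_time(s, scope)
    has_aff <- !is.na(aff_t)
    vocal <- if (has_aff) vocal_given(s, scope) else FALSE
    btype <- NA_character_
    if (s$kind == "PC" && has_aff) {
      ev <- affiliative_events(s, "opponent_only")
      any_contact <- any(ev$behavior %in%
                           c("contact", "groom_give", "groom_receive", "approach"))
      btype <- if (vocal && any_contact) "vocal_with_contact_or_approach"
      else if (vocal) "vocal_only"
      else "contact_or_approach_only"
    }
    list(aff_t = if (has_aff) aff_t else NA_real_, vocal = vocal,
         btype = btype,
         received_any = received_aggression_any(s),
         received_opp = if (s$kind == "PC")
           aggression_exposure(s, if (has_aff) aff_t else NA_real_) else NA,
         received_after = if (s$kind == "PC" && has_aff)
           aggression_exposure(s, aff_t) else NA)
  })
  srows <- x$sessions[match(ids, x$sessions$session_id), ]
  pick <- function(f, mode) vapply(per, `[[`, vector(mode, 1), f)
  data.frame(
    session_id = ids, kind = srows$kind, subject = srows$focal,
    opponent = srows$opponent, role = srows$focal_role,
    date = as.Date(srows$date_time),
    physical = srows$conflict_physical, counter = srows$conflict_counter,
    affiliation_t = pick("aff_t", "numeric"),
    affiliation = !is.na(pick("aff_t", "numeric")),
    vocal = pick("vocal", "logical"),
    behavior_type = pick("btype", "character"),
    received_any = pick("received_any", "logical"),
    received_opp_windowed = pick("received_opp", "logical"),
    received_after_affiliation = pick("received_after", "logical"),
    row.names = NULL, stringsAsFactors = FALSE)
}

lookup_familiarity <- function(familiarity, subject, opponent, date) {
  if (inherits(familiarity, "familiarity_matrix"))
    return(familiarity$index[cbind(subject, opponent)])
  if (is.matrix(familiarity))
    return(familiarity[cbind(subject, opponent)])
  if (is.list(familiarity)) {
    # list(period1 =, period2 =, boundary =): select by session date
    b <- as.Date(familiarity$boundary)
    m1 <- familiarity$period1; m2 <- familiarity$period2
    get <- function(m) if (inherits(m, "familiarity_matrix")) m$index else m
    ifelse(date < b, get(m1)[cbind(subject, opponent)],
           get(m2)[cbind(subject, opponent)])
  } else stop("unsupported familiarity covariate")
}

#' Assemble the analysis table for one model
#'
#' Builds one row per session in the model's subset, with the response and
#' covariates; rows with missing covariates are dropped with a logged
#' reason (attribute `"dropped"`).
#'
#' @param x a `pcmc_data` object with pairs
#' @param spec a [model_spec()] (or model id)
#' @param familiarity familiarity covariate: a [familiarity_matrix()], a
#'   plain matrix, or `list(period1=, period2=, boundary=)` for
#'   period-matched lookup
#' @param ranks named integer vector of dominance ranks
#' @param pairs pair table (defaults to `x$pairs`)
#' @return data frame ready for [fit_model()]
#' @export
assemble_model_table <- function(x, spec, familiarity = NULL, ranks = NULL,
                                 pairs = x$pairs) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(x, "pcmc_data"))
  if (is.null(pairs) || !nrow(pairs)) {
    return(data.frame(session_id = character(), response = logical()))
  }
  flags <- session_flags(x, pairs)
  rows <- switch(spec$sessions,
    PC = flags[flags$kind == "PC", ],
    PC_MC = flags,
    affiliation_only = flags[flags$affiliation, ],
    PC_affiliation = flags[flags$kind == "PC" & flags$affiliation, ],
    stop("unknown session subset: ", spec$sessions))
  if (spec$role_subset != "each")
    rows <- rows[rows$role == spec$role_subset, ]
  rows$response <- switch(spec$response,
    affiliation_opponent = rows$affiliation,
    received_aggression_any = rows$received_any,
    received_aggression_opponent_windowed = rows$received_opp_windowed,
    vocal_use = rows$vocal,
    received_aggression_after_affiliation = rows$received_after_affiliation,
    stop("unknown response: ", spec$response))
  rows$kind <- factor(rows$kind, levels = c("MC", "PC"))
  rows$behavior_type <- factor(rows$behavior_type,
                               levels = BEHAVIOR_TYPE_LEVELS)
  if (any(c("rank_diff") %in% spec$fixed) || !is.null(ranks)) {
    if (is.null(ranks)) stop("model needs ranks but none supplied")
    rows$rank_diff <- rank_difference(ranks[rows$subject],
                                      ranks[rows$opponent])
  }
  if ("familiarity" %in% spec$fixed) {
    if (is.null(familiarity)) stop("model needs familiarity but none supplied")
    rows$familiarity <- lookup_familiarity(familiarity, rows$subject,
                                           rows$opponent, rows$date)
  }
  needed <- c("response", spec$fixed)
  keep <- stats::complete.cases(rows[, needed, drop = FALSE])
  dropped <- rows$session_id[!keep]
  if (length(dropped))
    message(sprintf("model %s: dropped %d row(s) with missing covariates",
                    spec$model_id, length(dropped)))
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "model_id") <- spec$model_id
  out
}

glmer_quiet <- function(formula, data) {
  warn <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(formula, data = data, family = stats::binomial("logit"),
                  nAGQ = 1L,
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")),
      error = function(e) e),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  list(fit = fit, warnings = warn)
}

fit_failed <- function(res) {
  inherits(res$fit, "error") ||
    any(grepl("failed to converge|convergence", res$warnings, ignore.case = TRUE))
}

re_terms <- function(slope_vars) {
  inner <- if (length(slope_vars))
    paste(c("1", slope_vars), collapse = " + ") else "1"
  sprintf("(%s | subject) + (%s | opponent)", inner, inner)
}

#' Fit one binomial mixed model
#'
#' Logit-link binomial GLMM (Laplace approximation, via lme4) with random
#' intercepts for subject and former opponent. With `slopes = "auto"` the
#' full random-slope structure over the fixed effects is attempted first;
#' on non-convergence, slopes are dropped one at a time from the end of the
#' registry's fixed-effect list, ending at intercepts only, and the final
#' structure is recorded. Also refits the null model (random effects only,
#' same random structure) and reports the full-vs-null likelihood ratio
#' test.
#'
#' @param table output of [assemble_model_table()] (possibly filtered to one
#'   role)
#' @param spec a [model_spec()] or model id
#' @param slopes `"auto"`, `"none"` or `"full"`
#' @param null_fit also fit the random-effects-only null and report the
#'   full-vs-null likelihood ratio test? (default `TRUE`)
#' @return an object of class `pcmc_fit`
#' @export
fit_model <- function(table, spec, slopes = c("auto", "none", "full"),
                      null_fit = TRUE) {
  slopes <- match.arg(slopes)
  if (is.character(spec)) spec <- model_spec(spec)
  if (!nrow(table)) stop("empty analysis table")
  y <- table$response
  if (length(unique(y)) < 2)
    stop("separation/degenerate response: all outcomes identical (",
         unique(y), ")")
  fixed <- spec$fixed
  notes <- character(0)
  slope_try <- switch(slopes, none = list(character(0)),
                      full = list(fixed),
                      auto = c(lapply(rev(seq_along(fixed)), function(k)
                        fixed[seq_len(k)]), list(character(0))))
  fit <- NULL; used_slopes <- NULL
  for (i in seq_along(slope_try)) {
    sl <- slope_try[[i]]
    fml <- stats::as.formula(paste("response ~",
                                   paste(fixed, collapse = " + "), "+",
                                   re_terms(sl)))
    res <- glmer_quiet(fml, table)
    if (!fit_failed(res)) { fit <- res$fit; used_slopes <- sl; break }
    last <- i == length(slope_try)
    if (last && !inherits(res$fit, "error")) {
      # accept the simplest structure even if convergence warnings remain
      fit <- res$fit; used_slopes <- sl
      notes <- c(notes, paste("non-convergence warnings on final fit:",
                              paste(res$warnings, collapse = "; ")))
      break
    }
    notes <- c(notes, sprintf("random-slope structure {%s} dropped: %s",
                              paste(sl, collapse = ", "),
                              if (inherits(res$fit, "error"))
                                conditionMessage(res$fit)
                              else paste(res$warnings, collapse = "; ")))
  }
  if (is.null(fit))
    stop("model could not be fitted: ", notes[length(notes)])
  co <- summary(fit)$coefficients
  coefficients <- data.frame(term = rownames(co), beta = co[, "Estimate"],
                             se = co[, "Std. Error"], z = co[, "z value"],
                             p = co[, "Pr(>|z|)"], row.names = NULL,
                             stringsAsFactors = FALSE)
  if (any(abs(coefficients$beta) > 15))
    notes <- c(notes, "extreme coefficient magnitude: possible separation")
  lrt <- NULL
  if (null_fit) {
  nullfml <- stats::as.formula(paste("response ~ 1 +", re_terms(used_slopes)))
  nullres <- glmer_quiet(nullfml, table)
  if (!inherits(nullres$fit, "error")) {
    chi2 <- 2 * (as.numeric(stats::logLik(fit)) -
                   as.numeric(stats::logLik(nullres$fit)))
    df <- length(lme4::fixef(fit)) - length(lme4::fixef(nullres$fit))
    lrt <- list(chi2 = chi2, df = df,
                p = stats::pchisq(chi2, df, lower.tail = FALSE))
  }
  }
  out <- list(model_id = spec$model_id, coefficients = coefficients,
              loglik = as.numeric(stats::logLik(fit)), n = nrow(table),
              lrt_vs_null = lrt, random_slopes = used_slopes,
              convergence = length(notes) == 0, notes = notes,
              n_fixed_terms = length(lme4::fixef(fit)) - 1L,
              fit = fit)
  class(out) <- "pcmc_fit"
  out
}

#' @export
print.pcmc_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<pcmc_fit %s> binomial GLMM (logit), N = %d, logLik = %.3f\n",
              x$model_id, x$n, x$loglik))
  print(cbind(x$coefficients[1],
              round(x$coefficients[-1], digits)), row.names = FALSE)
  if (!is.null(x$lrt_vs_null))
    cat(sprintf("full vs null: chi2_%d = %.3f, P = %.4g\n",
                x$lrt_vs_null$df, x$lrt_vs_null$chi2, x$lrt_vs_null$p))
  if (length(x$random_slopes))
    cat("random slopes:", paste(x$random_slopes, collapse = ", "), "\n")
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = " | "), "\n")
  invisible(x)
}

#' Likelihood ratio test between nested fits
#'
#' @param full,reduced `pcmc_fit` objects on the same rows, reduced nested
#'   in full
#' @return list: `chi2`, `df`, `p`
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "pcmc_fit"), inherits(reduced, "pcmc_fit"))
  if (full$n != reduced$n)
    stop("models were fitted on different row sets (n = ", full$n, " vs ",
         reduced$n, ")")
  df <- full$n_fixed_terms - reduced$n_fixed_terms
  if (df < 0) stop("'reduced' has more fixed-effect terms than 'full'")
  chi2 <- 2 * (full$loglik - reduced$loglik)
  list(chi2 = chi2, df = df,
       p = if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE))
}
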