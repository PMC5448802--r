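test_that("the model registry matches the published variable definitions", {
  m5 <- model_spec("M5")
  expect_setequal(m5$fixed, c("rank_diff", "familiarity", "physical", "counter"))
  expect_equal(m5$response, "vocal_use")
  expect_equal(m5$role_subset, "victim")

  # counter-aggression deliberately absent from the consequences model
  expect_false("counter" %in% model_spec("M6")$fixed)
  expect_true("vocal" %in% model_spec("M6")$fixed)

  m6p <- model_spec("M6prime")
  expect_true("behavior_type" %in% m6p$fixed)
  expect_length(pcmcr:::BEHAVIOR_TYPE_LEVELS, 3)

  expect_setequal(model_spec("M1")$fixed,
                  c("rank_diff", "familiarity", "physical", "counter"))
  expect_equal(model_spec("M2")$fixed, "kind")
  expect_true("affiliation" %in% model_spec("M3")$fixed)
  expect_error(model_spec("M7"), "unknown model id")
})

test_that("assembled tables reproduce the subset bookkeeping", {
  d <- simulate_dataset(small_sim_config(seed = 13))
  flags <- pcmcr:::session_flags(d, d$pairs)
  ranks <- d$truth$ranks
  fam <- d$truth$familiarity

  t1 <- assemble_model_table(d, "M1", familiarity = fam, ranks = ranks)
  expect_equal(nrow(t1), nrow(d$pairs)) # one row per PC session
  expect_setequal(unique(t1$kind), "PC")

  t2 <- assemble_model_table(d, "M2", familiarity = fam, ranks = ranks)
  expect_equal(nrow(t2), 2 * nrow(d$pairs))

  t4 <- assemble_model_table(d, "M4", familiarity = fam, ranks = ranks)
  expect_equal(nrow(t4), sum(flags$affiliation))
  # internal consistency: N is the sum of the PC- and MC-affiliation counts
  for (r in c("aggressor", "victim")) {
    f <- flags[flags$role == r, ]
    expect_equal(sum(t4$role == r),
                 sum(f$affiliation & f$kind == "PC") +
                   sum(f$affiliation & f$kind == "MC"))
  }

  t5 <- assemble_model_table(d, "M5", familiarity = fam, ranks = ranks)
  expect_equal(nrow(t5),
               sum(flags$role == "victim" & flags$kind == "PC" &
                     flags$affiliation))
  expect_true(all(t5$response %in% c(TRUE, FALSE)))

  empty <- assemble_model_table(
    pcmc_data(d$sessions, d$events), "M1",
    familiarity = fam, ranks = ranks,
    pairs = d$pairs[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("boundary-zero random-effect variances reproduce plain logistic regression", {
  tab <- simulate_glmm_table(n = 300, beta = c(-0.3, 1.2), re_sd = 0,
                             n_subjects = 6, n_opponents = 6, seed = 5)
  fit <- fit_model(tab, glmm_sim_spec(), slopes = "none")
  vc <- lme4::VarCorr(fit$fit)
  expect_true(all(vapply(vc, function(v) v[1], numeric(1)) < 1e-8))
  ref <- stats::glm(response ~ x, binomial(), tab)
  expect_equal(fit$coefficients$beta, unname(coef(ref)), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("degenerate responses and mismatched LRT inputs raise errors", {
  tab <- simulate_glmm_table(n = 50, seed = 2)
  tab$response <- FALSE
  expect_error(fit_model(tab, glmm_sim_spec()), "separation|identical")

  tab2 <- simulate_glmm_table(n = 120, seed = 3)
  f <- fit_model(tab2, glmm_sim_spec(), slopes = "none")
  self <- likelihood_ratio_test(f, f)
  expect_equal(self$chi2, 0)
  expect_equal(self$df, 0)
  expect_equal(self$p, 1)

  g <- fit_model(tab2[1:100, ], glmm_sim_spec(), slopes = "none")
  expect_error(likelihood_ratio_test(f, g), "different row sets")
})

test_that("full-vs-null LRT has the right df and the multilevel effect test uses df = 2", {
  d <- simulate_dataset(simulation_config(n_females = 20, n_conflicts = 300,
                                          census_sessions = 60, seed = 17))
  fam <- d$truth$familiarity
  ranks <- d$truth$ranks

  t5 <- assemble_model_table(d, "M5", familiarity = fam, ranks = ranks)
  f5 <- fit_model(t5, "M5", slopes = "none")
  expect_equal(f5$lrt_vs_null$df, 4)
  expect_gte(f5$lrt_vs_null$chi2, 0)

  spec6p <- model_spec("M6prime")
  t6 <- assemble_model_table(d, spec6p, familiarity = fam, ranks = ranks)
  # some seeds produce a type level with no variation; require all 3 present
  expect_setequal(levels(t6$behavior_type), pcmcr:::BEHAVIOR_TYPE_LEVELS)
  full <- fit_model(t6, spec6p, slopes = "none")
  reduced_spec <- spec6p
  reduced_spec$fixed <- setdiff(spec6p$fixed, "behavior_type")
  reduced <- fit_model(t6, reduced_spec, slopes = "none")
  lrt <- likelihood_ratio_test(full, reduced)
  expect_equal(lrt$df, 2) # three-level factor contributes two coefficients
  expect_gte(lrt$chi2, -1e-8)
})

test_that("slopes = 'auto' falls back deterministically and records the structure", {
  tab <- simulate_glmm_table(n = 150, beta = c(0, 1), re_sd = 0.3,
                             n_subjects = 8, n_opponents = 8, seed = 6)
  fit <- fit_model(tab, glmm_sim_spec(), slopes = "auto")
  expect_true(is.character(fit$random_slopes))
  expect_true(length(fit$random_slopes) <= 1)
  fit2 <- fit_model(tab, glmm_sim_spec(), slopes = "auto")
  expect_identical(fit$random_slopes, fit2$random_slopes)
  expect_identical(fit$coefficients, fit2$coefficients)
})
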