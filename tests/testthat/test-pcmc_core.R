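test_that("first affiliation minute bins and scopes correctly", {
  s <- fake_session(make_event("S1", 75, "A", "B", "contact"))
  expect_identical(first_affiliation_minute(s, "opponent_only"), 2L)
  # half-open bins: exactly 60 s is minute 2
  s60 <- fake_session(make_event("S1", 60, "A", "B", "approach"))
  expect_identical(first_affiliation_minute(s60, "opponent_only"), 2L)
  expect_identical(first_affiliation_minute(
    fake_session(make_event("S1", 0, "B", "A", "groom_give"))), 1L)

  agg <- fake_session(make_event("S1", 10, "B", "A", "aggression_physical"))
  expect_identical(first_affiliation_minute(agg, "opponent_only"), NA_integer_)

  # PC scope: affiliation with a third party does not count...
  third <- fake_session(make_event("S1", 30, "A", "C", "contact"))
  expect_identical(first_affiliation_minute(third, "opponent_only"), NA_integer_)
  # ...but under the MC rule any partner counts
  expect_identical(first_affiliation_minute(third, "any_partner"), 1L)

  # vocalizations qualify only when oriented within 5 m
  far <- fake_session(make_event("S1", 30, "A", "B", "vocalization",
                                 oriented = TRUE, dist = 6))
  expect_identical(first_affiliation_minute(far, "opponent_only"), NA_integer_)
  near <- fake_session(make_event("S1", 30, "A", "B", "vocalization",
                                  oriented = TRUE, dist = 4))
  expect_identical(first_affiliation_minute(near, "opponent_only"), 1L)
})

test_that("timeframe classification follows the attracted/dispersed rule", {
  expect_identical(classify_pair_at_timeframe(1L, NA, 1), "attracted")
  expect_identical(classify_pair_at_timeframe(3L, 1L, 1), "dispersed")
  # same minute in PC and MC is neutral, per the design's tie rule
  expect_identical(classify_pair_at_timeframe(2L, 2L, 2), "neutral")
  expect_identical(classify_pair_at_timeframe(NA, NA, 4), "neutral")
  expect_identical(classify_pair_at_timeframe(c(1L, 2L), c(2L, 1L), 1),
                   c("attracted", "dispersed"))
})

test_that("timeframe labels match the 36-case brute-force oracle and partition the pair-level label", {
  vals <- c(1:5, NA)
  for (pc in vals) for (mc in vals) {
    labels <- vapply(1:5, function(t) classify_pair_at_timeframe(pc, mc, t),
                     character(1))
    oracle <- vapply(1:5, function(t) oracle_classify(pc, mc, t), character(1))
    expect_identical(labels, oracle,
                     info = sprintf("pc=%s mc=%s", pc, mc))
    overall <- classify_pair_overall(pc, mc)
    # attracted overall iff attracted at exactly one timeframe (its PC minute)
    expect_identical(sum(labels == "attracted"),
                     as.integer(overall == "attracted"))
    expect_identical(sum(labels == "dispersed"),
                     as.integer(overall == "dispersed"))
    if (overall == "attracted")
      expect_identical(which(labels == "attracted"), as.integer(pc))
  }
})

test_that("subject proportions apply the minimum-pairs filter and average per subject", {
  mk <- function(subject, pc, mc) {
    d <- data.frame(pair_id = "x", subject = subject, opponent = "Z",
                    role = "victim", pc_minute = pc, mc_minute = mc,
                    overall = classify_pair_overall(pc, mc),
                    stringsAsFactors = FALSE)
    for (t in 1:5) d[[paste0("t", t)]] <- classify_pair_at_timeframe(pc, mc, t)
    d
  }
  cl <- rbind(mk("A", 1L, NA), mk("A", NA, NA), mk("A", NA, NA), # 3 pairs
              mk("B", 1L, NA), mk("B", 2L, 1L))                  # only 2
  props <- subject_proportions(cl, min_pairs = 3)
  expect_identical(props$subject, "A")
  expect_identical(attr(props, "excluded"), "B")
  expect_equal(props$att_t1, 1 / 3)
  expect_equal(props$attracted, 1 / 3)
  expect_equal(props$ct, 1 / 3)

  expect_warning(empty <- subject_proportions(cl[0, ]), "no classified pairs")
  expect_identical(nrow(empty), 0L)
})

test_that("per-timeframe proportions sum to the overall proportions on simulated data", {
  d <- simulate_dataset(small_sim_config(seed = 21))
  cl <- classify_pairs(d)
  props <- subject_proportions(cl, min_pairs = 1)
  att_sum <- rowSums(props[, paste0("att_t", 1:5)])
  dis_sum <- rowSums(props[, paste0("dis_t", 1:5)])
  expect_equal(att_sum, props$attracted, ignore_attr = TRUE)
  expect_equal(dis_sum, props$dispersed, ignore_attr = TRUE)
  expect_true(all(att_sum <= 1) && all(dis_sum <= 1))
  expect_equal(props$ct, props$attracted - props$dispersed,
               ignore_attr = TRUE)
})

test_that("conciliatory tendency hits its closed-form extremes", {
  all_att <- data.frame(ct = c(1, 1, 1))
  expect_equal(conciliatory_tendency(all_att), 1)
  balanced <- data.frame(ct = c(0, 0))
  expect_equal(conciliatory_tendency(balanced), 0)
})

test_that("vocal_given applies the orientation and 5 m rules to the focal's calls", {
  voc <- function(dist, oriented, actor = "A", recipient = "B")
    fake_session(make_event("S1", 30, actor, recipient, "vocalization",
                            oriented = oriented, dist = dist))
  expect_true(vocal_given(voc(4, TRUE), "opponent_only"))
  expect_false(vocal_given(voc(6, TRUE), "opponent_only"))
  expect_false(vocal_given(voc(3, FALSE), "opponent_only"))
  # calls received from the opponent do not make the focal a vocalizer
  expect_false(vocal_given(voc(3, TRUE, actor = "B", recipient = "A"),
                           "opponent_only"))
  expect_error(vocal_given(fake_session(
    data.frame(session_id = "S1", t = 30, actor = "A", recipient = "B",
               behavior = "vocalization", oriented_at_recipient = TRUE,
               distance_m = NA_real_))), "missing distance_m")
})

test_that("aggression exposure uses the affiliation-onset window, else minutes 2-5", {
  agg_at <- function(t) make_event("S1", t, "B", "A", "aggression_nonphysical")
  s <- fake_session(rbind(make_event("S1", 90, "A", "B", "contact"),
                          agg_at(100)))
  expect_true(aggression_exposure(s, affiliation_t = 90))
  expect_true(aggression_exposure(s)) # window computed from events

  expect_false(aggression_exposure(fake_session(agg_at(30)), NA_real_))
  expect_true(aggression_exposure(fake_session(agg_at(200)), NA_real_))
  # aggression before the affiliation onset does not count
  s2 <- fake_session(rbind(make_event("S1", 150, "A", "B", "contact"),
                           agg_at(100)))
  expect_false(aggression_exposure(s2))
  # third-party aggression never counts toward the opponent-risk response
  s3 <- fake_session(make_event("S1", 200, "C", "A", "aggression_physical"))
  expect_false(aggression_exposure(s3, NA_real_))
  expect_true(received_aggression_any(s3))
})
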