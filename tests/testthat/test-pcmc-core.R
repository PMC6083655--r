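test_that("first-affiliation minute uses half-open one-based bins", {
  expect_equal(first_affiliation_minute(30), 1L)
  expect_equal(first_affiliation_minute(c(130, 20)), 1L)
  expect_equal(first_affiliation_minute(60), 2L)
  expect_equal(first_affiliation_minute(599.9), 10L)
  expect_true(is.na(first_affiliation_minute(numeric(0))))
})

test_that("pair labelling follows the attracted/dispersed/neutral rule", {
  expect_equal(as.character(label_pair(2, NA)), "attracted")
  expect_equal(as.character(label_pair(4, 2)), "dispersed")
  expect_equal(as.character(label_pair(NA, 3)), "dispersed")
  expect_equal(as.character(label_pair(3, 3)), "neutral")
  expect_equal(as.character(label_pair(NA, NA)), "neutral")
})

test_that("labelling is total and exclusive over all minute combinations", {
  vals <- c(1:10, NA)
  grid <- expand.grid(pc = vals, mc = vals)
  lab <- label_pair(grid$pc, grid$mc)
  expect_false(anyNA(lab))
  expect_equal(sum(table(lab)), nrow(grid))
  # earlier-in-PC always attracted, symmetry of the rule
  expect_true(all(lab[!is.na(grid$pc) & (is.na(grid$mc) | grid$pc < grid$mc)] == "attracted"))
  expect_true(all(lab[!is.na(grid$mc) & (is.na(grid$pc) | grid$mc < grid$pc)] == "dispersed"))
})

test_that("CCT arithmetic, bounds and monotonicity", {
  expect_equal(cct(12, 4, 8), 1 / 3, tolerance = 1e-12)
  expect_equal(cct(0, 1, 3), -0.25)
  for (k in c(1, 4)) for (m in 0:2) expect_equal(cct(k, k, m), 0)
  expect_equal(cct(5, 0, 0), 1)
  expect_equal(cct(0, 5, 0), -1)
  set.seed(2)
  for (i in 1:20) {
    a <- rpois(1, 3); d <- rpois(1, 3); nn <- rpois(1, 3)
    if (a + d + nn == 0) next
    v <- cct(a, d, nn)
    expect_true(v >= -1 && v <= 1)
    expect_gte(cct(a + 1, d, nn), v)   # one more attracted never decreases
    expect_lte(cct(a, d + 1, nn), v)   # one more dispersed never increases
  }
})

test_that("group CCT is the unweighted mean with sample-based SE", {
  expect_equal(group_cct(c(0.5, -0.5))$mean, 0)
  expect_equal(group_cct(0.4)$mean, 0.4)
  g <- group_cct(c(0.2, 0.4, 0.6))
  expect_equal(g$se, sd(c(0.2, 0.4, 0.6)) / sqrt(3))
})

test_that("attracted vs dispersed test concords with the proportions", {
  concil <- data.frame(victim = letters[1:6], attracted = c(5, 6, 4, 7, 3, 5),
                       dispersed = c(1, 2, 0, 3, 1, 2), neutral = 2)
  concil$total <- concil$attracted + concil$dispersed + concil$neutral
  r <- attracted_vs_dispersed_test(concil)
  expect_gt(r$z_adjusted, 0)
  expect_error(attracted_vs_dispersed_test(concil[1, ]), "at least 2")
  same <- data.frame(victim = c("a", "b"), attracted = c(2, 3), dispersed = c(2, 3),
                     neutral = 0, total = c(4, 6))
  expect_error(attracted_vs_dispersed_test(same), "degenerate")
})

test_that("time rule: identical and extreme separations", {
  same <- data.frame(victim = rep(letters[1:4], 3),
                     pc_minute = rep(c(1, 3, 5), each = 4),
                     mc_minute = rep(c(1, 3, 5), each = 4))
  tr <- time_rule(same)
  expect_equal(tr$ks$statistic, 0)
  sep <- data.frame(victim = rep(letters[1:5], 2),
                    pc_minute = 1, mc_minute = 10)
  tr2 <- time_rule(sep)
  expect_equal(tr2$ks$statistic, 1)
  expect_equal(tr2$window, 1L)
  none <- data.frame(victim = "a", pc_minute = NA_integer_, mc_minute = NA_integer_)
  expect_true(time_rule(none)$degenerate)
})

test_that("time rule D matches the ECDF oracle on generated minutes", {
  set.seed(33)
  pcm <- pmin(floor(rexp(60, 1 / 99) / 60) + 1, 10)
  mcm <- sample(1:10, 40, replace = TRUE)
  pairs <- data.frame(victim = "x",
                      pc_minute = c(pcm, rep(NA, 40)),
                      mc_minute = c(rep(NA, 60), mcm))
  tr <- time_rule(pairs)
  expect_equal(tr$ks$statistic, oracle_ks_d(pcm, mcm))
})

test_that("reconciliation characterization: intensity and run duration", {
  one_nc <- data.frame(initiator = "victim", latency_s = 12, event_duration_s = 3,
                       patterns = "approach_friendly", any_contact = FALSE)
  r <- characterize_reconciliation(one_nc)
  expect_equal(r$intensity, "low")
  expect_false(r$gap_flag)
  expect_equal(r$duration_s, 3)

  contact <- rbind(one_nc,
                   data.frame(initiator = "victim", latency_s = 16, event_duration_s = 2,
                              patterns = "nose_touch", any_contact = TRUE))
  r2 <- characterize_reconciliation(contact)
  expect_equal(r2$intensity, "high")
  expect_equal(r2$latency_s, 12)
  expect_equal(r2$initiator, "victim")
  expect_equal(r2$duration_s, 6)     # run ends at 16 + 2

  two_nc <- contact; two_nc$any_contact <- FALSE; two_nc$patterns[2] <- "stand_friendly"
  r3 <- characterize_reconciliation(two_nc)
  expect_equal(r3$intensity, "low")
  expect_true(r3$gap_flag)           # outside the low/high dichotomy, audited

  # a gap beyond the threshold or a different initiator ends the run
  gap <- contact; gap$latency_s[2] <- 40
  expect_equal(characterize_reconciliation(gap, gap_s = 5)$duration_s, 3)
  other <- contact; other$initiator[2] <- "aggressor"
  expect_equal(characterize_reconciliation(other)$duration_s, 3)
  expect_null(characterize_reconciliation(one_nc[0, ]))
})

test_that("proximity summary: identity, regimes and disjoint groups", {
  pairs <- data.frame(aggressor = rep(c("a", "c"), each = 4),
                      victim = rep(c("b", "d"), each = 4),
                      pc_proximity_s = c(100, 110, 90, 105, 10, 20, 15, 12),
                      mc_proximity_s = c(100, 110, 90, 105, 100, 95, 110, 99),
                      label = "neutral",
                      group = rep(c("g1", "g2"), each = 4),
                      stringsAsFactors = FALSE)
  ps <- proximity_summary(pairs)
  d1 <- ps$dyads[ps$dyads$group == "g1", ]
  expect_equal(d1$pc, d1$mc)                      # identical PC and MC
  d2 <- ps$dyads[ps$dyads$group == "g2", ]
  expect_lt(d2$pc, d2$mc)                         # avoider-like dyad
})

test_that("cross-tabs count strata and reconciled fractions", {
  pairs <- make_strata_pairs(n_high = 10, rec_high = 4, n_low = 10, rec_low = 2,
                             n_feed = 5, rec_feed = 1)
  xt <- conflict_cross_tabs(pairs)
  expect_equal(xt$intensity$n, c(10L, 10L))
  expect_equal(xt$intensity$reconciled_pct[xt$intensity$level == "high"], 40)
  expect_equal(xt$context$reconciled[xt$context$level == "feeding"], 1L)
  expect_equal(sum(xt$context$n), nrow(pairs))
  empty <- conflict_cross_tabs(pairs[pairs$intensity == "high", ])
  expect_equal(empty$intensity$n[empty$intensity$level == "low"], 0L)
  expect_true(is.na(empty$intensity$reconciled_pct[empty$intensity$level == "low"]))
})

test_that("labelled pairs from a dataset keep label totality", {
  ds <- generate_dataset(scenario_config(n_conflicts = 60), seed = 4)
  pairs <- build_pcmc_pairs(ds, min_conflicts = 1)
  expect_equal(nrow(pairs), 60)
  expect_equal(sum(table(pairs$label)), nrow(pairs))
  concil <- conciliatory_table(pairs)
  expect_equal(sum(concil$total), nrow(pairs))
})
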