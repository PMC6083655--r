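fake_fit <- function(terms, logLik, k = 4L, n = 100L, coef = NULL, se = NULL) {
  cf <- c(`(Intercept)` = 0.1)
  sf <- c(`(Intercept)` = 0.2)
  for (tm in terms) { cf[tm] <- coef %||% 1; sf[tm] <- se %||% 0.5 }
  list(terms = terms, logLik = logLik, k = k, n = n, coef = cf, se = sf,
       converged = TRUE, message = "")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("candidate set enumerates all subsets including the null", {
  expect_length(build_candidate_set(letters[1:5]), 32)
  expect_equal(build_candidate_set(character(0)), list(character(0)))
  s2 <- build_candidate_set(c("A", "B"))
  expect_setequal(vapply(s2, paste, character(1), collapse = "+"),
                  c("", "A", "B", "A+B"))
})

test_that("AICc arithmetic: definition, limit and guard", {
  expect_equal(aicc(-10, 3, 20), 20 + 6 + 24 / 16)
  # large-n limit is plain AIC
  expect_equal(aicc(-10, 3, 1e9), 2 * 10 + 2 * 3, tolerance = 1e-6)
  expect_error(aicc(-10, 3, 4), "n > k \\+ 1")
})

test_that("ranking produces normalized weights and nonnegative deltas", {
  fits <- list(fake_fit("a", -50), fake_fit("b", -50))
  ms <- rank_and_weight(fits, 100)
  expect_equal(ms$table$weight, c(0.5, 0.5))
  # delta 0 vs 2 -> exp(-1)/(1+exp(-1)) split
  fits2 <- list(fake_fit("a", -50), fake_fit("b", -51))
  ms2 <- rank_and_weight(fits2, 100)
  expect_equal(ms2$table$delta, c(0, 2))
  expect_equal(ms2$table$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(rank_and_weight(list(fake_fit("a", -50)), 100)$table$weight, 1)
  # properties: weights sum to 1, weights invariant to a logLik shift
  set.seed(6)
  lls <- -50 - runif(8, 0, 5)
  fits3 <- lapply(seq_along(lls), function(i) fake_fit(letters[i], lls[i]))
  w <- rank_and_weight(fits3, 100)$table$weight
  expect_lt(abs(sum(w) - 1), 1e-9)
  fits4 <- lapply(seq_along(lls), function(i) fake_fit(letters[i], lls[i] + 7))
  expect_equal(sort(rank_and_weight(fits4, 100)$table$weight), sort(w), tolerance = 1e-12)
  expect_true(all(rank_and_weight(fits3, 100)$table$delta >= 0))
})

test_that("non-converged fits are excluded with a message, never silently", {
  bad <- fake_fit("a", -50); bad$converged <- FALSE; bad$message <- "boom"
  expect_message(ms <- rank_and_weight(list(bad, fake_fit("b", -51)), 100),
                 "excluded")
  expect_equal(nrow(ms$table), 1)
  expect_error(suppressMessages(rank_and_weight(list(bad), 100)), "no successfully fitted")
})

test_that("conditional averaging reproduces hand arithmetic and RVI", {
  # two models containing the term, weights 0.6/0.2 (renormalized 0.75/0.25)
  fits <- list(fake_fit(c("x"), -50, coef = 2, se = 0.4),
               fake_fit(c("x", "y"), -50.5),
               fake_fit(character(0), -51))
  fits[[2]]$coef["x"] <- 1; fits[[2]]$se["x"] <- 0.8
  ms <- rank_and_weight(fits, 100)
  av <- model_average(ms)
  w <- ms$table$weight[match(c("x", "x + y"), ms$table$model)]
  wt <- w / sum(w)
  bbar <- wt[1] * 2 + wt[2] * 1
  se_star <- wt[1] * sqrt(0.4^2 + (2 - bbar)^2) + wt[2] * sqrt(0.8^2 + (1 - bbar)^2)
  row <- av$terms[av$terms$term == "x", ]
  expect_equal(row$estimate, bbar, tolerance = 1e-12)
  expect_equal(row$adjusted_se, se_star, tolerance = 1e-12)
  expect_equal(row$z, abs(bbar) / se_star, tolerance = 1e-12)
  expect_equal(row$rvi, sum(w), tolerance = 1e-12)
  # a term only in one model has rvi equal to that model's weight
  rvy <- av$terms$rvi[av$terms$term == "y"]
  expect_equal(rvy, ms$table$weight[ms$table$model == "x + y"], tolerance = 1e-12)
  expect_true(all(av$terms$rvi >= 0 & av$terms$rvi <= 1))
})

test_that("degenerate averaging: identical coefficients pass through", {
  fits <- list(fake_fit("x", -50, coef = 1.5, se = 0.3),
               fake_fit(c("x", "y"), -50.7, coef = 1.5, se = 0.3))
  av <- model_average(rank_and_weight(fits, 100))
  row <- av$terms[av$terms$term == "x", ]
  expect_equal(row$estimate, 1.5)
  expect_equal(row$adjusted_se, 0.3)
})

test_that("a term in every model has RVI 1", {
  fits <- list(fake_fit("x", -50), fake_fit(c("x", "y"), -50.5))
  av <- model_average(rank_and_weight(fits, 100))
  expect_equal(av$terms$rvi[av$terms$term == "x"], 1, tolerance = 1e-12)
})

test_that("gaussian null logLik matches the closed-form normal MLE", {
  set.seed(14)
  # grouping labels carry no signal: the variance components sit at the
  # boundary and the ML log-likelihood equals the iid normal one
  df <- data.frame(y = rnorm(40, 2, 1.5),
                   dyad = rep(c("d1", "d2"), 20), victim = rep(c("v1", "v2"), 20))
  f <- fit_model("y", character(0), df, "gaussian")
  sig2 <- mean((df$y - mean(df$y))^2)
  ll_closed <- -40 / 2 * (log(2 * pi * sig2) + 1)
  expect_equal(f$logLik, ll_closed, tolerance = 1e-6)
  expect_equal(f$k, 4L)   # intercept + 2 variance components + residual
  # a single grouping level collapses to the fixed-effects fit
  df1 <- data.frame(y = rnorm(30, 1), dyad = "d1", victim = "v1")
  f1 <- fit_model("y", character(0), df1, "gaussian")
  expect_match(f1$message, "collapsed")
  sig2b <- mean((df1$y - mean(df1$y))^2)
  expect_equal(f1$logLik, -30 / 2 * (log(2 * pi * sig2b) + 1), tolerance = 1e-6)
})

test_that("a perfectly separating predictor is surfaced, not hidden", {
  set.seed(15)
  df <- data.frame(y = rep(c(0, 1), each = 20),
                   x = rep(c(0, 1), each = 20) + rnorm(40, 0, 0.01),
                   dyad = rep(c("d1", "d2"), 20), victim = rep(c("v1", "v2"), 20))
  f <- suppressWarnings(fit_model("y", "x", df, "binomial"))
  expect_true(!isTRUE(f$converged) || nzchar(f$message) || abs(f$coef["x"]) > 4)
})

test_that("the full candidate machinery runs end to end on generated data", {
  ds <- generate_dataset(scenario_config(n_conflicts = 80), seed = 19)
  pairs <- build_pcmc_pairs(ds, 1)
  mf <- build_model_frame(ds, pairs)
  ms <- suppressMessages(
    ic_model_set("occurrence", c("context", "rank_distance"), mf, "binomial"))
  expect_equal(nrow(ms$table) + length(ms$dropped), 4)
  expect_lt(abs(sum(ms$table$weight) - 1), 1e-9)
  av <- model_average(ms)
  expect_true(all(c("context", "rank_distance") %in% av$terms$term))
})
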