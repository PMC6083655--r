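# Independent oracles and fixture builders shared across the test files.
# Every oracle is a naive, direct evaluation kept deliberately separate from
# the package's implementation path.

# --- David's scores: literal four-loop evaluation of the four sums
naive_davids <- function(mat) {
  k <- nrow(mat)
  P <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    nij <- mat[i, j] + mat[j, i]
    if (i != j && nij > 0) P[i, j] <- mat[i, j] / nij
  }
  w <- l <- w2 <- l2 <- numeric(k)
  for (i in seq_len(k)) for (j in seq_len(k)) w[i] <- w[i] + P[i, j]
  for (i in seq_len(k)) for (j in seq_len(k)) l[i] <- l[i] + P[j, i]
  for (i in seq_len(k)) for (j in seq_len(k)) w2[i] <- w2[i] + P[i, j] * w[j]
  for (i in seq_len(k)) for (j in seq_len(k)) l2[i] <- l2[i] + P[j, i] * l[j]
  w + w2 - l - l2
}

# --- tie-corrected Wilcoxon Z, direct textbook formula
oracle_wilcoxon_z <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  ties <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  (w_plus - n * (n + 1) / 4) / sqrt(v)
}

# --- tie-corrected Mann-Whitney Z, direct textbook formula
oracle_mwu_z <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(c(x, y))
  v <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  (u1 - n * m / 2) / sqrt(v)
}

# --- KS D by direct ECDF scan over a fine grid
oracle_ks_d <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# --- tiny handmade dataset touching every table, used by the IO tests
make_tiny_dataset <- function(registry = default_registry()) {
  individuals <- data.frame(
    id = c("alpha", "beta", "gamma"), pack_id = "p1",
    species = "wolf", sex = c("male", "female", "female"),
    stringsAsFactors = FALSE)
  t0 <- as.POSIXct("2013-02-01 09:00:00", tz = "UTC")
  focal_events <- data.frame(
    session_id = "s1", focal = "alpha", pack_id = "p1",
    session_start = t0, session_duration_s = 600,
    time_s = c(10, 30.5, 200), actor = c("beta", "alpha", "gamma"),
    receiver = c("alpha", "beta", "alpha"),
    behaviour = c("crouch", "nose_touch", "threat"), duration_s = 0,
    stringsAsFactors = FALSE)
  conflicts <- data.frame(
    conflict_id = "c1", pack_id = "p1", aggressor = "alpha", victim = "beta",
    start_datetime = t0 + 3600, end_time_s = 20, context = "non_feeding",
    intensity = "high", outcome = "decided", stringsAsFactors = FALSE)
  observations <- data.frame(
    obs_id = c("c1_PC", "c1_MC"), conflict_id = "c1", type = c("PC", "MC"),
    focal = "beta", start_datetime = c(t0 + 3620, t0 + 3620 + 86400),
    duration_s = 600, proximity_s = c(120.5, 80),
    event_index = c(1L, NA), initiator = c("victim", NA),
    latency_s = c(35.5, NA), event_duration_s = c(4.2, NA),
    patterns = c("nose_touch", NA), any_contact = c(TRUE, NA),
    stringsAsFactors = FALSE)
  list(individuals = individuals,
       focal_events = annotate_events(focal_events, registry, individuals),
       conflicts = conflicts, observations = observations)
}

# labelled-pairs frame with prescribed per-stratum reconciled counts
make_strata_pairs <- function(n_high, rec_high, n_low, rec_low,
                              n_feed, rec_feed) {
  n <- n_high + n_low
  stopifnot(n_feed <= n, rec_feed <= rec_high + rec_low)
  intensity <- c(rep("high", n_high), rep("low", n_low))
  label <- rep("neutral", n)
  label[seq_len(rec_high)] <- "attracted"
  label[n_high + seq_len(rec_low)] <- "attracted"
  att <- which(label == "attracted")
  non <- which(label != "attracted")
  context <- rep("non_feeding", n)
  context[att[seq_len(rec_feed)]] <- "feeding"
  context[non[seq_len(n_feed - rec_feed)]] <- "feeding"
  data.frame(conflict_id = sprintf("c%03d", seq_len(n)),
             aggressor = "a", victim = "v", context = context,
             intensity = intensity, outcome = "decided",
             label = factor(label, c("attracted", "dispersed", "neutral")),
             stringsAsFactors = FALSE)
}
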