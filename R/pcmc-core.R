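#' PC-MC labelling and conciliatory tendency
#'
#' The matched-control method compares, for each conflict, the minute of
#' the first opponent-directed affiliative contact in the post-conflict
#' (PC) observation with the same quantity in its matched control (MC).
#' A pair is *attracted* when opponents affiliated only in the PC or
#' earlier in the PC than in the MC, *dispersed* in the mirror cases, and
#' *neutral* when the first contacts fall in the same minute or neither
#' observation contains one. The corrected conciliatory tendency of an
#' individual is (attracted - dispersed) / total pairs.
#'
#' @name pcmc-core
NULL

#' Minute of first opponent-directed affiliation
#'
#' Minutes are half-open bins: minute k covers `[60(k-1), 60k)` seconds,
#' k = 1..duration/60.
#'
#' @param latencies numeric vector of affiliative-event latencies within
#'   one observation, seconds from its start (may be empty or all `NA`).
#' @return integer minute of the earliest event, or `NA_integer_` when no
#'   opponent-directed affiliation occurred.
#' @examples
#' first_affiliation_minute(c(130, 20))  # 1
#' @export
first_affiliation_minute <- function(latencies) {
  latencies <- latencies[!is.na(latencies)]
  if (length(latencies) == 0L) return(NA_integer_)
  as.integer(floor(min(latencies) / 60) + 1)
}

#' Label a PC-MC pair
#'
#' @param pc_minute,mc_minute first-affiliation minutes (`NA` = no
#'   affiliation in that observation). Vectorized.
#' @return factor with levels `attracted`, `dispersed`, `neutral`. The
#'   labelling is total and exclusive: every pair gets exactly one label.
#' @examples
#' label_pair(2, NA)  # attracted
#' label_pair(4, 2)   # dispersed
#' @export
label_pair <- function(pc_minute, mc_minute) {
  n <- max(length(pc_minute), length(mc_minute))
  pc <- rep_len(as.numeric(pc_minute), n)
  mc <- rep_len(as.numeric(mc_minute), n)
  lab <- ifelse(
    !is.na(pc) & (is.na(mc) | pc < mc), "attracted",
    ifelse(!is.na(mc) & (is.na(pc) | mc < pc), "dispersed", "neutral")
  )
  factor(lab, levels = c("attracted", "dispersed", "neutral"))
}

#' Corrected conciliatory tendency (CCT)
#'
#' \deqn{\mathrm{CCT} = \frac{\mathrm{attracted} - \mathrm{dispersed}}
#'       {\mathrm{attracted} + \mathrm{dispersed} + \mathrm{neutral}}}
#'
#' @param attracted,dispersed,neutral nonnegative pair counts
#'   (vectorized).
#' @return CCT in `[-1, 1]`; `NA` with a message for individuals with no
#'   pairs (they are excluded from group summaries).
#' @examples
#' cct(12, 4, 8)  # 1/3
#' @export
cct <- function(attracted, dispersed, neutral) {
  a <- as.numeric(attracted); d <- as.numeric(dispersed); nn <- as.numeric(neutral)
  if (any(c(a, d, nn) < 0, na.rm = TRUE)) stop("counts must be nonnegative", call. = FALSE)
  tot <- a + d + nn
  if (any(tot == 0, na.rm = TRUE)) {
    message(sum(tot == 0, na.rm = TRUE), " individual(s) with zero PC-MC pairs excluded from CCT")
  }
  ifelse(tot > 0, (a - d) / tot, NA_real_)
}

#' Per-individual conciliatory table from labelled pairs
#'
#' @param pairs data.frame with columns `victim` and `label` (from
#'   [label_pair()]).
#' @return data.frame `victim, attracted, dispersed, neutral, total, cct`.
#' @export
conciliatory_table <- function(pairs) {
  tab <- table(pairs$victim, factor(pairs$label, c("attracted", "dispersed", "neutral")))
  out <- data.frame(victim = rownames(tab),
                    attracted = as.integer(tab[, "attracted"]),
                    dispersed = as.integer(tab[, "dispersed"]),
                    neutral = as.integer(tab[, "neutral"]),
                    stringsAsFactors = FALSE)
  out$total <- out$attracted + out$dispersed + out$neutral
  out$cct <- cct(out$attracted, out$dispersed, out$neutral)
  rownames(out) <- NULL
  out
}

#' Group conciliatory tendency
#'
#' Unweighted mean of the individual CCTs with its standard error
#' (sample SD / sqrt(n)); individuals without pairs are dropped.
#'
#' @param ccts numeric vector of individual CCTs.
#' @return list `mean`, `se`, `n`.
#' @export
group_cct <- function(ccts) {
  ccts <- ccts[!is.na(ccts)]
  if (length(ccts) == 0L) stop("no usable individual CCTs", call. = FALSE)
  list(mean = mean(ccts),
       se = if (length(ccts) > 1) stats::sd(ccts) / sqrt(length(ccts)) else NA_real_,
       n = length(ccts))
}

#' Attracted versus dispersed proportions across individuals
#'
#' Per individual, the proportions attracted/total and dispersed/total
#' are compared with the tie-corrected Wilcoxon matched-pair signed-ranks
#' test: evidence that opponents affiliate earlier after conflicts than
#' at baseline.
#'
#' @param concil data.frame from [conciliatory_table()].
#' @return a `pcmc_test` (see [wilcoxon_signed_rank()]).
#' @export
attracted_vs_dispersed_test <- function(concil) {
  use <- concil[concil$total > 0, , drop = FALSE]
  if (nrow(use) < 2L) stop("need at least 2 individuals with PC-MC pairs", call. = FALSE)
  wilcoxon_signed_rank(use$attracted / use$total, use$dispersed / use$total)
}

#' Time-rule analysis of first-affiliation minutes
#'
#' Compares the distribution of the minute of first opponent affiliation
#' in PCs with that in MCs: per-minute histograms, a two-sample
#' Kolmogorov-Smirnov test on the minutes (observations without a first
#' contact are excluded from the distributions), the divergence window
#' (the earliest minute at which the absolute ECDF difference is
#' maximal), and a per-individual Wilcoxon test of PC versus MC
#' first-contact counts within that window.
#'
#' @param pairs data.frame with `victim`, `pc_minute`, `mc_minute`.
#' @param n_minutes observation length in minutes (default 10).
#' @return list of class `pcmc_timerule`: `histogram` (minute, pc, mc),
#'   `ks` (`pcmc_test`), `window` (integer minutes), `window_test`
#'   (`pcmc_test` or `NULL` when degenerate), `degenerate` flag.
#' @export
time_rule <- function(pairs, n_minutes = 10L) {
  pcm <- pairs$pc_minute[!is.na(pairs$pc_minute)]
  mcm <- pairs$mc_minute[!is.na(pairs$mc_minute)]
  minutes <- seq_len(n_minutes)
  hist <- data.frame(minute = minutes,
                     pc = vapply(minutes, function(k) sum(pcm == k), integer(1)),
                     mc = vapply(minutes, function(k) sum(mcm == k), integer(1)))
  degenerate <- length(pcm) == 0L || length(mcm) == 0L
  ks <- NULL; window <- integer(0); wt <- NULL
  if (!degenerate) {
    ks <- ks_two_sample(pcm, mcm)
    cdf_pc <- cumsum(hist$pc) / length(pcm)
    cdf_mc <- cumsum(hist$mc) / length(mcm)
    gap <- abs(cdf_pc - cdf_mc)
    # divergence window: the earliest minute at which the cumulative
    # difference peaks (ties resolved to the first attainment)
    window <- if (max(gap) > 0) minutes[which.max(gap)] else integer(0)
    if (length(window)) {
      per_id <- lapply(split(pairs, pairs$victim), function(df) {
        c(pc = sum(df$pc_minute %in% window, na.rm = TRUE),
          mc = sum(df$mc_minute %in% window, na.rm = TRUE))
      })
      m <- do.call(rbind, per_id)
      wt <- tryCatch(wilcoxon_signed_rank(m[, "pc"], m[, "mc"]),
                     error = function(e) NULL)
    }
  }
  out <- list(histogram = hist, ks = ks, window = window,
              window_test = wt, degenerate = degenerate)
  class(out) <- "pcmc_timerule"
  out
}

#' @export
print.pcmc_timerule <- function(x, ...) {
  if (x$degenerate) {
    cat("time rule: degenerate (no first contacts in PC or MC)\n")
    return(invisible(x))
  }
  cat(sprintf("time rule: KS D = %.3f, p = %.4g; divergence window: minute %s\n",
              x$ks$statistic, x$ks$p_two_tailed, paste(x$window, collapse = ",")))
  if (!is.null(x$window_test)) {
    cat(sprintf("  within-window Wilcoxon: Z adj = %.2f, p = %.4g (n = %d)\n",
                x$window_test$z_adjusted, x$window_test$p_two_tailed, x$window_test$n))
  }
  invisible(x)
}

#' Characterize the reconciliation event of a PC observation
#'
#' Takes the ordered opponent-directed affiliative sub-events of one PC
#' and summarizes the reconciliation: latency of the first event,
#' its initiator, duration from the start of the first affiliative
#' behaviour to the end of the last *consecutive* one displayed by the
#' initiator (consecutive = same initiator and inter-event gap at most
#' `gap_s`), and intensity — *high* when at least one pattern in the run
#' involves physical contact, *low* when a single non-contact pattern was
#' shown. More than one pattern with none involving contact falls outside
#' the low/high dichotomy; such events are classified low and flagged
#' (`gap_flag`) so they stay auditable.
#'
#' @param events data.frame of the PC's affiliative sub-events:
#'   `initiator, latency_s, event_duration_s, patterns, any_contact`
#'   (`patterns` space-separated codes). Zero rows return `NULL`.
#' @param gap_s maximum inter-event gap for the consecutive run, seconds.
#' @return list `latency_s, duration_s, intensity, initiator, n_patterns,
#'   gap_flag`, or `NULL` when no affiliation occurred.
#' @export
characterize_reconciliation <- function(events, gap_s = 5) {
  if (is.null(events) || nrow(events) == 0L) return(NULL)
  ev <- events[order(events$latency_s), , drop = FALSE]
  initiator <- ev$initiator[1]
  run_end <- ev$latency_s[1] + ev$event_duration_s[1]
  last <- 1L
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      if (ev$initiator[i] == initiator && ev$latency_s[i] <= run_end + gap_s) {
        run_end <- max(run_end, ev$latency_s[i] + ev$event_duration_s[i])
        last <- i
      } else break
    }
  }
  run <- ev[seq_len(last), , drop = FALSE]
  pats <- unlist(strsplit(run$patterns[!is.na(run$patterns)], " ", fixed = TRUE))
  n_patterns <- max(length(pats), nrow(run))
  contact <- any(run$any_contact, na.rm = TRUE)
  intensity <- if (contact) "high" else "low"
  gap_flag <- !contact && n_patterns > 1
  list(latency_s = ev$latency_s[1],
       duration_s = run_end - ev$latency_s[1],
       intensity = intensity,
       initiator = initiator,
       n_patterns = n_patterns,
       gap_flag = gap_flag)
}

#' Reconciliation-event table for all attracted PCs
#'
#' @param observations observations table (PC rows with sub-events).
#' @param pairs labelled pairs data.frame (needs `conflict_id`, `label`).
#' @param gap_s consecutive-run gap, see [characterize_reconciliation()].
#' @return data.frame, one row per attracted PC with an affiliative
#'   event: `conflict_id, latency_s, duration_s, intensity, initiator,
#'   n_patterns, gap_flag`.
#' @export
reconciliation_events <- function(observations, pairs, gap_s = 5) {
  att <- pairs$conflict_id[pairs$label == "attracted"]
  rows <- lapply(att, function(cid) {
    ev <- observations[observations$conflict_id == cid & observations$type == "PC" &
                         !is.na(observations$event_index), , drop = FALSE]
    r <- characterize_reconciliation(ev, gap_s)
    if (is.null(r)) return(NULL)
    data.frame(conflict_id = cid, latency_s = r$latency_s, duration_s = r$duration_s,
               intensity = r$intensity, initiator = r$initiator,
               n_patterns = r$n_patterns, gap_flag = r$gap_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(conflict_id = character(0), latency_s = numeric(0),
                      duration_s = numeric(0), intensity = character(0),
                      initiator = character(0), n_patterns = integer(0),
                      gap_flag = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Proximity summaries and comparisons
#'
#' Per-dyad mean seconds the victim spent in close proximity to its
#' aggressor during PCs and MCs, with Mann-Whitney comparisons at the
#' dyad level: PC proximity between two groups (e.g. species), MC
#' proximity between groups, and — within one group — PC proximity of
#' reconciled (attracted) versus unreconciled conflicts.
#'
#' @param pairs labelled pairs with `aggressor, victim, pc_proximity_s,
#'   mc_proximity_s, label` and a `group` column when comparing groups.
#' @return list of class `pcmc_proximity`: `dyads` (per-dyad means),
#'   `pc_group_test`, `mc_group_test`, `reconciled_test` (each a
#'   `pcmc_test` or `NULL` when not estimable).
#' @export
proximity_summary <- function(pairs) {
  pairs$dyad <- paste(pmin(pairs$aggressor, pairs$victim),
                      pmax(pairs$aggressor, pairs$victim), sep = "~")
  agg <- function(v) tapply(v, pairs$dyad, mean, na.rm = TRUE)
  dy <- data.frame(dyad = names(agg(pairs$pc_proximity_s)),
                   pc = as.numeric(agg(pairs$pc_proximity_s)),
                   mc = as.numeric(agg(pairs$mc_proximity_s)),
                   stringsAsFactors = FALSE)
  if (!is.null(pairs$group)) {
    grp <- tapply(as.character(pairs$group), pairs$dyad, function(g) g[1])
    dy$group <- as.character(grp[dy$dyad])
  }
  pc_test <- mc_test <- rec_test <- NULL
  if (!is.null(dy$group) && length(unique(dy$group)) == 2L) {
    gs <- sort(unique(dy$group))
    pc_test <- tryCatch(mann_whitney_u(dy$pc[dy$group == gs[1]], dy$pc[dy$group == gs[2]]),
                        error = function(e) NULL)
    mc_test <- tryCatch(mann_whitney_u(dy$mc[dy$group == gs[1]], dy$mc[dy$group == gs[2]]),
                        error = function(e) NULL)
  }
  rec <- pairs$pc_proximity_s[pairs$label == "attracted"]
  unrec <- pairs$pc_proximity_s[pairs$label != "attracted"]
  if (length(rec) && length(unrec)) {
    rec_test <- tryCatch(mann_whitney_u(rec, unrec), error = function(e) NULL)
  }
  out <- list(dyads = dy, pc_group_test = pc_test, mc_group_test = mc_test,
              reconciled_test = rec_test)
  class(out) <- "pcmc_proximity"
  out
}

#' Conflict cross-tabulations
#'
#' Counts and percentages of conflicts by context, intensity and outcome,
#' with the reconciled fraction (reconciled = attracted label) within
#' each stratum.
#'
#' @param pairs labelled pairs carrying the conflict attributes
#'   `context`, `intensity`, `outcome` and `label`.
#' @return list of class `pcmc_crosstab` of data.frames (`context`,
#'   `intensity`, `outcome`), each with `level, n, pct, reconciled,
#'   reconciled_pct` (percentages to full precision; `reconciled_pct` is
#'   `NA` for empty strata).
#' @export
conflict_cross_tabs <- function(pairs) {
  one <- function(var) {
    levs <- switch(var,
                   context = c("feeding", "non_feeding"),
                   intensity = c("low", "high"),
                   outcome = c("decided", "undecided"))
    x <- factor(pairs[[var]], levs)
    n <- as.integer(table(x))
    rec <- as.integer(table(x[pairs$label == "attracted"]))
    data.frame(level = levs, n = n,
               pct = ifelse(nrow(pairs) > 0, 100 * n / nrow(pairs), NA_real_),
               reconciled = rec,
               reconciled_pct = ifelse(n > 0, 100 * rec / n, NA_real_),
               stringsAsFactors = FALSE)
  }
  out <- list(context = one("context"), intensity = one("intensity"),
              outcome = one("outcome"))
  class(out) <- "pcmc_crosstab"
  out
}

#' @export
print.pcmc_crosstab <- function(x, ...) {
  for (nm in names(x)) {
    cat(nm, ":\n", sep = "")
    df <- x[[nm]]
    df$pct <- round(df$pct, 2); df$reconciled_pct <- round(df$reconciled_pct, 2)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' Assemble labelled PC-MC pairs from a dataset
#'
#' Joins PC and MC observations by conflict, computes first-affiliation
#' minutes, applies the minimum-conflicts dyad filter, labels every pair
#' and carries along the conflict attributes and proximity durations.
#'
#' @param dataset list with `conflicts` and `observations`.
#' @param min_conflicts dyad filter threshold (default 3; use 1 to keep
#'   everything).
#' @return data.frame, one row per PC-MC pair: `conflict_id, aggressor,
#'   victim, context, intensity, outcome, pc_minute, mc_minute, label,
#'   pc_proximity_s, mc_proximity_s`.
#' @export
build_pcmc_pairs <- function(dataset, min_conflicts = 3L) {
  obs <- dataset$observations
  conf <- dataset$conflicts
  cids <- intersect(unique(obs$conflict_id[obs$type == "PC"]),
                    unique(obs$conflict_id[obs$type == "MC"]))
  cids <- intersect(conf$conflict_id, cids)
  rows <- lapply(cids, function(cid) {
    crow <- conf[conf$conflict_id == cid, , drop = FALSE]
    pc <- obs[obs$conflict_id == cid & obs$type == "PC", , drop = FALSE]
    mc <- obs[obs$conflict_id == cid & obs$type == "MC", , drop = FALSE]
    data.frame(conflict_id = cid,
               aggressor = crow$aggressor, victim = crow$victim,
               context = crow$context, intensity = crow$intensity,
               outcome = crow$outcome,
               pc_minute = first_affiliation_minute(pc$latency_s[!is.na(pc$event_index)]),
               mc_minute = first_affiliation_minute(mc$latency_s[!is.na(mc$event_index)]),
               pc_proximity_s = pc$proximity_s[1],
               mc_proximity_s = mc$proximity_s[1],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) stop("no resolvable PC-MC pairs in dataset", call. = FALSE)
  pairs <- dyad_conflict_filter(pairs, min_conflicts)
  pairs$label <- label_pair(pairs$pc_minute, pairs$mc_minute)
  pairs
}
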