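#' End-to-end post-conflict analysis
#'
#' [run_full_analysis()] executes the whole pipeline on one dataset:
#' validation, relationship metrics, the minimum-conflicts dyad filter,
#' PC-MC labelling, conciliatory tendencies with the attracted-versus-
#' dispersed test, the time rule, reconciliation-event characterization,
#' proximity summaries, conflict cross-tabs and — optionally — the five
#' all-subsets AICc model sets (occurrence, initiator, intensity,
#' latency, duration of reconciliation). [run_species_comparison()]
#' contrasts two reports at the dyad level.
#'
#' @name pcmc-pipeline
NULL

#' Build the model frame for the reconciliation models
#'
#' One row per labelled PC-MC pair with the conflict attributes, dyadic
#' predictors oriented aggressor-to-victim (AFFav, AGGav, signed rank
#' distance) and the responses: `occurrence` (attracted yes/no) for the
#' full set, plus `initiator`, `recon_intensity`, `latency_s` and
#' `duration_s` on the attracted pairs that carry a reconciliation event.
#'
#' @param dataset dataset list.
#' @param pairs labelled pairs from [build_pcmc_pairs()].
#' @param rank_form `"signed"` (default) or `"absolute"` rank distance.
#' @param gap_s consecutive-run gap for the event characterization.
#' @return data.frame with grouping columns `pack`, `dyad`, `victim`.
#' @export
build_model_frame <- function(dataset, pairs, rank_form = c("signed", "absolute"),
                              gap_s = 5) {
  rank_form <- match.arg(rank_form)
  ev <- dataset$focal_events
  aff <- dyad_asymmetries(ev, "affiliative")
  agg <- dyad_asymmetries(ev, "aggressive")
  oriented <- function(tab, a, v) {
    key_a <- pmin(a, v); key_b <- pmax(a, v)
    i <- match(paste(key_a, key_b), paste(tab$id_a, tab$id_b))
    ifelse(a == key_a, tab$asymmetry[i], -tab$asymmetry[i])
  }
  packs <- dataset$individuals$pack_id[match(pairs$victim, dataset$individuals$id)]
  rd <- numeric(nrow(pairs))
  for (p in unique(packs)) {
    ids <- dataset$individuals$id[dataset$individuals$pack_id == p]
    ds <- davids_scores(submission_matrix(ev, ids))
    sel <- which(packs == p)
    rd[sel] <- vapply(sel, function(i) {
      r <- rank_distance(ds, pairs$aggressor[i], pairs$victim[i])
      if (rank_form == "signed") r$signed else r$absolute
    }, numeric(1))
  }
  mf <- data.frame(
    conflict_id = pairs$conflict_id,
    pack = packs,
    dyad = paste(pmin(pairs$aggressor, pairs$victim),
                 pmax(pairs$aggressor, pairs$victim), sep = "~"),
    victim = pairs$victim,
    occurrence = as.integer(pairs$label == "attracted"),
    context = factor(pairs$context, c("non_feeding", "feeding")),
    conflict_intensity = factor(pairs$intensity, c("low", "high")),
    rank_distance = rd,
    aggression_symmetry = oriented(agg, pairs$aggressor, pairs$victim),
    affiliation_symmetry = oriented(aff, pairs$aggressor, pairs$victim),
    stringsAsFactors = FALSE)
  rec <- reconciliation_events(dataset$observations, pairs, gap_s)
  i <- match(mf$conflict_id, rec$conflict_id)
  mf$initiator <- as.integer(rec$initiator[i] == "victim")
  mf$recon_intensity <- as.integer(rec$intensity[i] == "high")
  mf$latency_s <- rec$latency_s[i]
  mf$duration_s <- rec$duration_s[i]
  mf
}

MODEL_TERMS <- c("context", "conflict_intensity", "rank_distance",
                 "aggression_symmetry", "affiliation_symmetry")

#' @rdname pcmc-pipeline
#' @param dataset dataset list (from [read_dataset()] or
#'   [generate_dataset()]).
#' @param registry behaviour registry.
#' @param min_conflicts dyad filter threshold (default 3).
#' @param observation_hours total observation effort, for rates per hour
#'   (optional).
#' @param fit_models logical; fit the five all-subsets mixed-model sets
#'   (can be slow on large candidate sets).
#' @param rank_form signed or absolute rank distance in the models.
#' @return object of class `pcmc_report`.
#' @export
run_full_analysis <- function(dataset, registry = default_registry(),
                              min_conflicts = 3L, observation_hours = NULL,
                              fit_models = FALSE, rank_form = "signed") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  validation <- stage("validate", {
    if (nrow(dataset$conflicts) == 0L) stop("empty dataset: no conflicts")
    validate_dataset(dataset, registry)
  })
  if (is.null(dataset$focal_events$category)) {
    dataset$focal_events <- annotate_events(dataset$focal_events, registry,
                                            dataset$individuals)
  }
  metrics <- stage("metrics", {
    list(affiliation = dyad_asymmetries(dataset$focal_events, "affiliative"),
         aggression = dyad_asymmetries(dataset$focal_events, "aggressive"),
         davids = lapply(split(dataset$individuals$id, dataset$individuals$pack_id),
                         function(ids) davids_scores(submission_matrix(dataset$focal_events, ids))))
  })
  pairs <- stage("pcmc_label", build_pcmc_pairs(dataset, min_conflicts))
  concil <- stage("cct", conciliatory_table(pairs))
  grp <- stage("cct", group_cct(concil$cct))
  advd <- stage("cct", tryCatch(attracted_vs_dispersed_test(concil),
                                error = function(e) NULL))
  tr <- stage("time_rule", time_rule(pairs))
  recon <- stage("reconciliation", reconciliation_events(dataset$observations, pairs))
  prox <- stage("proximity", proximity_summary(pairs))
  xtab <- stage("cross_tabs", conflict_cross_tabs(pairs))
  n_conf <- nrow(dataset$conflicts)
  summary_tab <- list(
    n_conflicts = n_conf,
    n_pairs = nrow(pairs),
    rate_per_hour = if (!is.null(observation_hours)) aggression_rate(n_conf, observation_hours) else NA_real_)
  models <- NULL
  if (fit_models) {
    models <- stage("models", {
      mf <- build_model_frame(dataset, pairs, rank_form)
      att <- mf[mf$occurrence == 1L & !is.na(mf$latency_s), , drop = FALSE]
      fit1 <- function(resp, data, family) {
        tryCatch(ic_model_set(resp, MODEL_TERMS, data, family),
                 error = function(e) structure(list(message = conditionMessage(e)),
                                               class = "pcmc_modsel_failed"))
      }
      list(occurrence = fit1("occurrence", mf, "binomial"),
           initiator = fit1("initiator", att, "binomial"),
           intensity = fit1("recon_intensity", att, "binomial"),
           latency = fit1("latency_s", att, "gaussian"),
           duration = fit1("duration_s", att, "gaussian"),
           frame = mf)
    })
  }
  out <- list(validation = validation, metrics = metrics, pairs = pairs,
              conciliatory = concil, group_cct = grp,
              attracted_vs_dispersed = advd, time_rule = tr,
              reconciliation = recon, proximity = prox, cross_tabs = xtab,
              summary = summary_tab, models = models,
              species = unique(dataset$individuals$species))
  class(out) <- "pcmc_report"
  out
}

#' @export
print.pcmc_report <- function(x, ...) {
  cat(sprintf("PC-MC analysis: %d conflicts, %d labelled pairs (dyad filter applied)\n",
              x$summary$n_conflicts, x$summary$n_pairs))
  if (is.finite(x$summary$rate_per_hour)) {
    cat(sprintf("  aggression rate: %.2f per observation hour\n", x$summary$rate_per_hour))
  }
  cat(sprintf("  group CCT: %.2f%% (s.e. %.2f%%, n = %d individuals)\n",
              100 * x$group_cct$mean, 100 * x$group_cct$se, x$group_cct$n))
  if (!is.null(x$attracted_vs_dispersed)) {
    cat(sprintf("  attracted vs dispersed: Z adj = %.2f, p = %.4g\n",
                x$attracted_vs_dispersed$z_adjusted, x$attracted_vs_dispersed$p_two_tailed))
  }
  print(x$time_rule)
  if (nrow(x$validation)) cat(sprintf("  NOTE: %d validation violation(s)\n", nrow(x$validation)))
  invisible(x)
}

#' Write the report's tables as CSV files
#'
#' Emits the per-victim conciliatory table, the time-rule histogram, the
#' reconciliation-event table and (when fitted) the ranking and averaged-
#' term tables of each model set. Floats are written with fixed
#' formatting so re-running on the same inputs byte-reproduces the files.
#'
#' @param report a `pcmc_report`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 6, format = "g"))
    df
  }
  emit <- function(df, name) utils::write.csv(fmt(df), file.path(dir, name),
                                              row.names = FALSE, quote = FALSE)
  emit(report$conciliatory, "conciliatory_tendencies.csv")
  emit(report$time_rule$histogram, "time_rule_histogram.csv")
  emit(report$reconciliation, "reconciliation_events.csv")
  emit(do.call(rbind, lapply(names(report$cross_tabs), function(nm) {
    cbind(variable = nm, report$cross_tabs[[nm]])
  })), "conflict_cross_tabs.csv")
  if (!is.null(report$models)) {
    for (nm in setdiff(names(report$models), "frame")) {
      ms <- report$models[[nm]]
      if (inherits(ms, "pcmc_modsel")) {
        emit(ms$table, sprintf("model_%s_ranking.csv", nm))
        emit(model_average(ms)$terms, sprintf("model_%s_averaged.csv", nm))
      }
    }
  }
  invisible(dir)
}

#' @rdname pcmc-pipeline
#' @param report_a,report_b two `pcmc_report`s built against the same
#'   registry (e.g. one per species).
#' @return list of class `pcmc_comparison`: dyad-level Mann-Whitney
#'   comparisons of the high-intensity conflict fraction and of PC and
#'   MC proximity durations, each a `pcmc_test` or `NULL` when
#'   degenerate (flagged in `degenerate`).
#' @export
run_species_comparison <- function(report_a, report_b) {
  dyad_stats <- function(rep) {
    p <- rep$pairs
    p$dyad <- paste(pmin(p$aggressor, p$victim), pmax(p$aggressor, p$victim), sep = "~")
    do.call(rbind, lapply(split(p, p$dyad), function(df) {
      data.frame(high_frac = mean(df$intensity == "high"),
                 pc_prox = mean(df$pc_proximity_s, na.rm = TRUE),
                 mc_prox = mean(df$mc_proximity_s, na.rm = TRUE))
    }))
  }
  a <- dyad_stats(report_a); b <- dyad_stats(report_b)
  if (nrow(a) < 2L || nrow(b) < 2L) stop("need at least 2 dyads per group", call. = FALSE)
  safe <- function(x, y) tryCatch(mann_whitney_u(x, y), error = function(e) NULL)
  out <- list(
    high_intensity = safe(a$high_frac, b$high_frac),
    pc_proximity = safe(a$pc_prox, b$pc_prox),
    mc_proximity = safe(a$mc_prox, b$mc_prox),
    n_dyads = c(a = nrow(a), b = nrow(b)))
  out$degenerate <- vapply(out[1:3], is.null, logical(1))
  class(out) <- "pcmc_comparison"
  out
}

#' @export
print.pcmc_comparison <- function(x, ...) {
  cat(sprintf("dyad-level comparison (n = %d vs %d dyads):\n",
              x$n_dyads["a"], x$n_dyads["b"]))
  for (nm in c("high_intensity", "pc_proximity", "mc_proximity")) {
    t <- x[[nm]]
    if (is.null(t)) cat(sprintf("  %s: degenerate (zero variance)\n", nm))
    else cat(sprintf("  %s: U = %.1f, Z adj = %.2f, p = %.4g\n",
                     nm, t$statistic, t$z_adjusted, t$p_two_tailed))
  }
  invisible(x)
}
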