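#' Synthetic multi-pack study generator
#'
#' Generates complete datasets with the statistical structure the PC-MC
#' analysis assumes: packs of 2-5 individuals with a latent dominance
#' order; conflicts drawn at a configurable rate with the aggressor
#' biased toward the higher-ranked opponent and context/intensity/outcome
#' drawn per configured fractions; a 10-minute PC observation per
#' conflict in which opponent-directed affiliation occurs with
#' probability `p_reconcile` at a truncated-exponential latency; a valid
#' matched control on the following (conflict-free) day at the same time
#' of day, with a flat baseline affiliation hazard; proximity durations
#' that differ between "reconciler" and "avoider" regimes; and focal
#' sessions whose directed affiliative/aggressive/submissive counts
#' honour per-dyad asymmetry targets in expectation. The generator
#' returns its ground truth so every estimate the pipeline produces can
#' be checked for parameter recovery.
#'
#' @name pcmc-synthetic
NULL

#' Scenario configuration
#'
#' Defaults describe a wolf-like multi-pack study: four packs of 5, 3, 3
#' and 2 animals observed for 524 h in total, 0.80 conflicts per
#' observation hour, about a quarter of conflicts in a feeding context,
#' 59% of high intensity, the aggressor being the higher-ranked opponent
#' in 90% of conflicts, PC affiliation probability 0.42 with a mean
#' 99 s latency (exponential, rejection-truncated into the 600 s
#' observation), and a 0.198 baseline MC affiliation probability with a
#' flat latency. `preset = "dog"` switches to an avoider scenario
#' (packs 4, 4, 3, 2; 403 h at 0.14 conflicts/h; 87% high intensity;
#' suppressed PC proximity).
#'
#' @param preset `"wolf"` or `"dog"` baseline parameter set.
#' @param ... overrides for any configuration field (see the returned
#'   list's names).
#' @return list of class `pcmc_scenario`.
#' @export
scenario_config <- function(preset = c("wolf", "dog"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    species = preset,
    pack_sizes = if (preset == "wolf") c(5L, 3L, 3L, 2L) else c(4L, 4L, 3L, 2L),
    observation_hours = if (preset == "wolf") 523.87 else 403.26,
    conflict_rate = if (preset == "wolf") 0.80 else 0.14,
    n_conflicts = NULL,                 # overrides rate * hours when set
    feeding_fraction = 0.254,
    high_intensity_fraction = if (preset == "wolf") 0.593 else 0.87,
    decided_fraction = 0.876,
    aggressor_higher_rank_p = 0.9,
    p_reconcile = if (preset == "wolf") 0.42 else 0.23,
    pc_latency_mean_s = 99,
    mc_affiliation_p = if (preset == "wolf") 0.198 else 0.267,
    victim_initiates_p = 0.82,
    recon_high_intensity_p = 0.565,
    recon_duration_mean_s = 8,
    proximity_regime = if (preset == "wolf") "reconciler" else "avoider",
    pc_proximity_mean_s = if (preset == "wolf") 120 else 30,
    mc_proximity_mean_s = 110,
    proximity_sd_s = 40,
    obs_duration_s = 600,
    affiliative_events_per_dyad = 20,
    aggressive_events_per_dyad = 10,
    submissive_events_per_dyad = 15,
    aff_asymmetry_target = 0,           # higher-rank vs lower-rank orientation
    agg_asymmetry_target = 0.6,
    submission_noise = 0.05,            # prob the higher-ranked submits
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  cfg[names(dots)] <- dots
  bad <- vapply(cfg[c("feeding_fraction", "high_intensity_fraction", "decided_fraction",
                      "aggressor_higher_rank_p", "p_reconcile", "mc_affiliation_p",
                      "victim_initiates_p", "recon_high_intensity_p", "submission_noise")],
                function(p) !is.numeric(p) || any(p < 0 | p > 1), logical(1))
  if (any(bad)) stop("probabilities must lie in [0, 1]: ",
                     paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  if (any(cfg$pack_sizes < 2L | cfg$pack_sizes > 5L)) {
    stop("pack sizes must be 2-5 (a single animal cannot have conflicts)", call. = FALSE)
  }
  if (cfg$conflict_rate <= 0) stop("conflict_rate must be positive", call. = FALSE)
  class(cfg) <- c("pcmc_scenario", "list")
  cfg
}

#' @rdname scenario_config
#' @param config a `pcmc_scenario`.
#' @param path YAML file.
#' @export
write_scenario <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname scenario_config
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(scenario_config, c(list(preset = raw$species %||% "wolf"),
                             raw[setdiff(names(raw), "species")]))
}

# All generated times are kept at 0.1 s resolution (video-coding precision),
# which also makes the CSV round-trip exact.
rtrunc_exp <- function(n, mean_s, upper) {
  out <- numeric(0)
  while (length(out) < n) {                  # rejection sampling into [0, upper)
    draw <- stats::rexp(n, 1 / mean_s)
    out <- c(out, draw[draw < upper])
  }
  floor(out[seq_len(n)] * 10) / 10
}

rtrunc_norm <- function(n, mean_s, sd_s, lower, upper) {
  round(pmin(pmax(stats::rnorm(n, mean_s, sd_s), lower), upper), 1)
}

#' Generate a synthetic dataset
#'
#' @param config a [scenario_config()].
#' @param seed master seed for all randomness; defaults to the seed in
#'   the config. The same seed always yields the identical dataset.
#' @param registry behaviour registry supplying the pattern codes used in
#'   generated events.
#' @return list with `individuals`, `focal_events` (annotated),
#'   `conflicts`, `observations`, and `truth` (ground truth: per-dyad
#'   `p_reconcile`, latent ranks, asymmetry targets, regime).
#' @export
generate_dataset <- function(config = scenario_config(), seed = config$seed,
                             registry = default_registry()) {
  stopifnot(inherits(config, "pcmc_scenario"))
  set.seed(as.integer(seed))
  species <- if (config$species %in% c("wolf", "dog")) config$species else "unknown"

  packs <- paste0("pack", seq_along(config$pack_sizes))
  individuals <- do.call(rbind, lapply(seq_along(packs), function(p) {
    n <- config$pack_sizes[p]
    data.frame(id = sprintf("%s_i%d", packs[p], seq_len(n)),
               pack_id = packs[p], species = species,
               sex = sample(c("male", "female"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  ranks <- do.call(rbind, lapply(packs, function(p) {
    ids <- individuals$id[individuals$pack_id == p]
    data.frame(id = ids, pack_id = p, rank = seq_along(ids), stringsAsFactors = FALSE)
  }))  # rank 1 = top

  # ---- conflicts: one per (even) day so matched controls on the following
  # (odd) day are guaranteed a quiet pre-window
  n_conf <- config$n_conflicts %||%
    stats::rpois(1, config$conflict_rate * config$observation_hours)
  if (n_conf < 1L) n_conf <- 1L
  eligible <- packs[config$pack_sizes >= 2L]
  pack_w <- config$pack_sizes[config$pack_sizes >= 2L]
  pack_w <- pack_w * (pack_w - 1) / 2
  conf_pack <- sample(eligible, n_conf, replace = TRUE, prob = pack_w)
  base <- as.POSIXct("2013-01-01 00:00:00", tz = "UTC")
  conflicts <- do.call(rbind, lapply(seq_len(n_conf), function(i) {
    ids <- individuals$id[individuals$pack_id == conf_pack[i]]
    pair <- sample(ids, 2L)
    r <- ranks$rank[match(pair, ranks$id)]
    hi <- pair[which.min(r)]; lo <- pair[which.max(r)]
    agg_is_hi <- stats::runif(1) < config$aggressor_higher_rank_p
    start <- base + (2 * (i - 1)) * 86400 + round(stats::runif(1, 8, 16) * 3600)
    data.frame(conflict_id = sprintf("c%04d", i),
               pack_id = conf_pack[i],
               aggressor = if (agg_is_hi) hi else lo,
               victim = if (agg_is_hi) lo else hi,
               start_datetime = start,
               end_time_s = round(stats::runif(1, 5, 60)),
               context = if (stats::runif(1) < config$feeding_fraction) "feeding" else "non_feeding",
               intensity = if (stats::runif(1) < config$high_intensity_fraction) "high" else "low",
               outcome = if (stats::runif(1) < config$decided_fraction) "decided" else "undecided",
               stringsAsFactors = FALSE)
  }))

  # ---- PC and MC observations
  aff_nc <- registry$behaviour[registry$category == "affiliative" & !registry$contact]
  aff_c <- registry$behaviour[registry$category == "affiliative" & registry$contact]
  obs_rows <- list()
  for (i in seq_len(n_conf)) {
    cf <- conflicts[i, ]
    pc_start <- cf$start_datetime + cf$end_time_s
    mc_start <- pc_start + 86400
    pc_id <- paste0(cf$conflict_id, "_PC"); mc_id <- paste0(cf$conflict_id, "_MC")
    mk <- function(obs_id, type, start, has_ev, latency, initiator, pats, contact,
                   ev_dur, prox) {
      data.frame(obs_id = obs_id, conflict_id = cf$conflict_id, type = type,
                 focal = cf$victim, start_datetime = start,
                 duration_s = config$obs_duration_s, proximity_s = prox,
                 event_index = if (has_ev) 1L else NA_integer_,
                 initiator = if (has_ev) initiator else NA_character_,
                 latency_s = if (has_ev) latency else NA_real_,
                 event_duration_s = if (has_ev) ev_dur else NA_real_,
                 patterns = if (has_ev) pats else NA_character_,
                 any_contact = if (has_ev) contact else NA,
                 stringsAsFactors = FALSE)
    }
    pc_prox <- rtrunc_norm(1, config$pc_proximity_mean_s, config$proximity_sd_s,
                           0, config$obs_duration_s)
    mc_prox <- rtrunc_norm(1, config$mc_proximity_mean_s, config$proximity_sd_s,
                           0, config$obs_duration_s)
    pc_has <- stats::runif(1) < config$p_reconcile
    if (pc_has) {
      lat <- rtrunc_exp(1, config$pc_latency_mean_s, config$obs_duration_s)
      init <- if (stats::runif(1) < config$victim_initiates_p) "victim" else "aggressor"
      high <- stats::runif(1) < config$recon_high_intensity_p
      pats <- if (high) paste(c(sample(aff_nc, 1), sample(aff_c, 1)), collapse = " ")
              else sample(aff_nc, 1)
      dur <- round(min(max(stats::rexp(1, 1 / config$recon_duration_mean_s), 0.6),
                       max(config$obs_duration_s - lat - 0.05, 0.1)), 1)
      obs_rows[[length(obs_rows) + 1L]] <-
        mk(pc_id, "PC", pc_start, TRUE, lat, init, pats, high, dur, pc_prox)
    } else {
      obs_rows[[length(obs_rows) + 1L]] <-
        mk(pc_id, "PC", pc_start, FALSE, NA, NA, NA, NA, NA, pc_prox)
    }
    mc_has <- stats::runif(1) < config$mc_affiliation_p
    if (mc_has) {
      lat <- round(stats::runif(1, 0, config$obs_duration_s - 1), 1)
      obs_rows[[length(obs_rows) + 1L]] <-
        mk(mc_id, "MC", mc_start, TRUE, lat,
           if (stats::runif(1) < 0.5) "victim" else "aggressor",
           sample(aff_nc, 1), FALSE,
           round(min(max(stats::rexp(1, 1 / config$recon_duration_mean_s), 0.6),
                     max(config$obs_duration_s - lat - 0.05, 0.1)), 1), mc_prox)
    } else {
      obs_rows[[length(obs_rows) + 1L]] <-
        mk(mc_id, "MC", mc_start, FALSE, NA, NA, NA, NA, NA, mc_prox)
    }
  }
  observations <- do.call(rbind, obs_rows)

  # ---- focal sessions honouring asymmetry targets in expectation
  sub_codes <- registry$behaviour[registry$category == "submissive"]
  agg_nc <- registry$behaviour[registry$category == "aggressive" & !registry$contact]
  ev_rows <- list()
  session_of <- stats::setNames(sprintf("s_%s", individuals$id), individuals$id)
  sess_start <- stats::setNames(base + seq_len(nrow(individuals)) * 3600, individuals$id)
  emit <- function(actor, receiver, behaviour) {
    focal <- actor   # event logged in the actor's focal session
    data.frame(session_id = session_of[[focal]], focal = focal,
               pack_id = individuals$pack_id[match(focal, individuals$id)],
               session_start = sess_start[[focal]], session_duration_s = 600,
               time_s = round(stats::runif(1, 0, 599), 1),
               actor = actor, receiver = receiver, behaviour = behaviour,
               duration_s = 0, stringsAsFactors = FALSE)
  }
  for (p in packs) {
    ids <- individuals$id[individuals$pack_id == p]
    if (length(ids) < 2L) next
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a >= b) next
      hi <- ids[a]; lo <- ids[b]      # a precedes b => higher latent rank
      n_aff <- stats::rpois(1, config$affiliative_events_per_dyad)
      p_hi <- (1 + config$aff_asymmetry_target) / 2
      for (k in seq_len(n_aff)) {
        if (stats::runif(1) < p_hi) ev_rows[[length(ev_rows) + 1L]] <- emit(hi, lo, sample(aff_nc, 1))
        else ev_rows[[length(ev_rows) + 1L]] <- emit(lo, hi, sample(aff_nc, 1))
      }
      n_agg <- stats::rpois(1, config$aggressive_events_per_dyad)
      p_hi <- (1 + config$agg_asymmetry_target) / 2
      for (k in seq_len(n_agg)) {
        if (stats::runif(1) < p_hi) ev_rows[[length(ev_rows) + 1L]] <- emit(hi, lo, sample(agg_nc, 1))
        else ev_rows[[length(ev_rows) + 1L]] <- emit(lo, hi, sample(agg_nc, 1))
      }
      n_sub <- stats::rpois(1, config$submissive_events_per_dyad)
      for (k in seq_len(n_sub)) {
        if (stats::runif(1) < config$submission_noise) {
          ev_rows[[length(ev_rows) + 1L]] <- emit(hi, lo, sample(sub_codes, 1))
        } else {
          ev_rows[[length(ev_rows) + 1L]] <- emit(lo, hi, sample(sub_codes, 1))
        }
      }
    }
  }
  focal_events <- do.call(rbind, ev_rows)
  focal_events <- annotate_events(focal_events, registry, individuals)

  truth <- list(p_reconcile = config$p_reconcile,
                mc_affiliation_p = config$mc_affiliation_p,
                ranks = ranks,
                aff_asymmetry_target = config$aff_asymmetry_target,
                agg_asymmetry_target = config$agg_asymmetry_target,
                proximity_regime = config$proximity_regime,
                seed = as.integer(seed))
  list(individuals = individuals, focal_events = focal_events,
       conflicts = conflicts, observations = observations, truth = truth)
}

#' Parameter-recovery report
#'
#' Compares what the analysis pipeline estimates on a generated dataset
#' with the generator's ground truth: the attracted fraction and group
#' CCT against `p_reconcile` (exact when the MC hazard is 0), the
#' affiliation/aggression asymmetry estimates against their targets, the
#' David's-score ordering against the latent ranks (Kendall tau per
#' pack), and the PC-vs-MC proximity contrast against the regime.
#'
#' @param dataset a generated dataset (with its `truth` element).
#' @param min_conflicts dyad filter used when labelling (default 1: keep
#'   all conflicts so the recovered fractions match the generator's).
#' @return list of class `pcmc_recovery` with elements
#'   `attracted_fraction`, `group_cct`, `asymmetry` (data.frame),
#'   `rank_tau` (per pack), `proximity` (PC and MC means).
#' @export
recovery_report <- function(dataset, min_conflicts = 1L) {
  truth <- dataset$truth
  pairs <- build_pcmc_pairs(dataset, min_conflicts = min_conflicts)
  concil <- conciliatory_table(pairs)
  grp <- group_cct(concil$cct)
  aff <- dyad_asymmetries(dataset$focal_events, "affiliative")
  agg <- dyad_asymmetries(dataset$focal_events, "aggressive")
  orient <- function(df) {
    # orient each dyad as (higher rank -> lower rank) to match the targets
    r <- truth$ranks
    sgn <- ifelse(r$rank[match(df$id_a, r$id)] < r$rank[match(df$id_b, r$id)], 1, -1)
    df$asymmetry * sgn
  }
  asym <- data.frame(
    class = c("affiliative", "aggressive"),
    target = c(truth$aff_asymmetry_target, truth$agg_asymmetry_target),
    estimate = c(mean(orient(aff), na.rm = TRUE), mean(orient(agg), na.rm = TRUE)))
  taus <- vapply(unique(truth$ranks$pack_id), function(p) {
    ids <- truth$ranks$id[truth$ranks$pack_id == p]
    if (length(ids) < 2) return(NA_real_)
    m <- submission_matrix(dataset$focal_events, ids)
    if (sum(m) == 0) return(NA_real_)
    ds <- davids_scores(m)
    stats::cor(-truth$ranks$rank[match(ids, truth$ranks$id)],
               ds$ds[match(ids, ds$id)], method = "kendall")
  }, numeric(1))
  out <- list(
    attracted_fraction = mean(pairs$label == "attracted"),
    p_reconcile = truth$p_reconcile,
    group_cct = grp$mean,
    asymmetry = asym,
    rank_tau = taus,
    proximity = c(pc = mean(pairs$pc_proximity_s, na.rm = TRUE),
                  mc = mean(pairs$mc_proximity_s, na.rm = TRUE)),
    regime = truth$proximity_regime,
    n_pairs = nrow(pairs))
  class(out) <- "pcmc_recovery"
  out
}

#' @export
print.pcmc_recovery <- function(x, ...) {
  cat(sprintf("recovery over %d PC-MC pairs:\n", x$n_pairs))
  cat(sprintf("  attracted fraction %.3f (true p_reconcile %.3f); group CCT %.3f\n",
              x$attracted_fraction, x$p_reconcile, x$group_cct))
  cat(sprintf("  asymmetry: aff %.3f (target %.2f), agg %.3f (target %.2f)\n",
              x$asymmetry$estimate[1], x$asymmetry$target[1],
              x$asymmetry$estimate[2], x$asymmetry$target[2]))
  cat(sprintf("  rank recovery: mean Kendall tau %.3f; proximity PC %.0f s vs MC %.0f s (%s)\n",
              mean(x$rank_tau, na.rm = TRUE), x$proximity["pc"], x$proximity["mc"], x$regime))
  invisible(x)
}
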