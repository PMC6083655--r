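#' Behavioural data model and delimited-text formats
#'
#' The pipeline works on four plain-text tables, all UTF-8, comma-delimited
#' with a header row, ISO-8601 datetimes and seconds as decimals:
#'
#' * `individuals.csv` — `id, pack_id, species (wolf|dog), sex
#'   (male|female|unknown)`
#' * `focal_events.csv` — one row per behavioural event within a focal
#'   session: `session_id, focal, pack_id, session_start,
#'   session_duration_s, time_s, actor, receiver, behaviour, duration_s`
#' * `conflicts.csv` — `conflict_id, pack_id, aggressor, victim,
#'   start_datetime, end_time_s, context (feeding|non_feeding), intensity
#'   (low|high), outcome (decided|undecided)`
#' * `pcmc_observations.csv` — one row per opponent-directed affiliative
#'   sub-event within a PC or MC observation (observations without any
#'   affiliation carry a single row with blank event fields):
#'   `obs_id, conflict_id, type (PC|MC), focal, start_datetime, duration_s,
#'   proximity_s, event_index, initiator (victim|aggressor), latency_s,
#'   event_duration_s, patterns (space-separated behaviour codes),
#'   any_contact`
#'
#' Times within an observation are seconds from its start, 0-based, with
#' half-open event intervals `[t, t + dur)`. Behaviour codes are resolved
#' against a registry (see [read_registry()]).
#'
#' @name pcmc-formats
NULL

BEHAVIOUR_CATEGORIES <- c("aggressive", "submissive", "dominant", "affiliative", "proximity")

#' Read or build a behaviour registry
#'
#' The registry maps each behaviour code to its category (aggressive,
#' submissive, dominant, affiliative or proximity), a physical-contact
#' flag and a free-text description. On disk it is a YAML mapping
#' `code: {category: ..., contact: ..., description: ...}`. Every code
#' appearing in a dataset must be registered; the category + contact pair
#' drives conflict- and reconciliation-intensity classification.
#'
#' @param path YAML file; `default_registry()` returns the registry
#'   shipped with the package (a generic canid ethogram).
#' @return a data.frame of class `pcmc_registry` with columns
#'   `behaviour`, `category`, `contact`, `description`.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) stop("empty registry: ", path, call. = FALSE)
  reg <- data.frame(
    behaviour = names(raw),
    category = vapply(raw, function(e) as.character(e$category), character(1)),
    contact = vapply(raw, function(e) isTRUE(e$contact), logical(1)),
    description = vapply(raw, function(e) as.character(e$description %||% ""), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  validate_registry(reg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_registry <- function(reg) {
  bad <- setdiff(reg$category, BEHAVIOUR_CATEGORIES)
  if (length(bad)) stop("unknown behaviour categories: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(reg$behaviour)) stop("duplicate behaviour codes in registry", call. = FALSE)
  class(reg) <- c("pcmc_registry", "data.frame")
  reg
}

#' @rdname read_registry
#' @export
default_registry <- function() {
  read_registry(system.file("extdata", "behaviour_registry.yaml", package = "pcmc"))
}

#' Write a registry back to YAML
#' @param registry a `pcmc_registry`.
#' @param path output file.
#' @export
write_registry <- function(registry, path) {
  lst <- lapply(seq_len(nrow(registry)), function(i) {
    list(category = registry$category[i],
         contact = registry$contact[i],
         description = registry$description[i])
  })
  names(lst) <- registry$behaviour
  yaml::write_yaml(lst, path)
  invisible(path)
}

parse_datetime <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) stop("unparseable ISO-8601 datetime(s): ",
                     paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  out
}

format_datetime <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

read_table_checked <- function(path, required_cols, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s (%s): missing column(s) %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read the individuals roster
#' @param path `individuals.csv` in the documented dialect.
#' @return data.frame `id, pack_id, species, sex`; unknown species/sex are
#'   kept as `"unknown"` rather than rejected (species only gates
#'   cross-species comparisons).
#' @export
read_individuals <- function(path) {
  df <- read_table_checked(path, c("id", "pack_id", "species", "sex"), "individuals")
  if (anyDuplicated(df$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  }
  df$species[!(df$species %in% c("wolf", "dog"))] <- "unknown"
  df$sex[!(df$sex %in% c("male", "female"))] <- "unknown"
  df
}

#' @rdname read_individuals
#' @param individuals data.frame as returned by `read_individuals`.
#' @export
write_individuals <- function(individuals, path) {
  utils::write.csv(individuals[c("id", "pack_id", "species", "sex")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read focal-session behavioural events
#'
#' Each row is one directed behaviour within a 10-minute focal session.
#' The focal individual must be actor or receiver of every event; events
#' must lie inside the session (`time_s + duration_s <= session_duration_s`)
#' and use registered behaviour codes. Violations are collected into a
#' validation report rather than silently dropped; structural problems
#' (missing columns, unknown individuals when a roster is supplied) raise
#' errors.
#'
#' @param path `focal_events.csv`.
#' @param registry a `pcmc_registry`; behaviour categories and contact
#'   flags are joined in from it.
#' @param individuals optional roster for id checking.
#' @return data.frame of events with attached `category`/`contact` columns
#'   and an attribute `"violations"` (data.frame `line, field, message`,
#'   zero rows when clean).
#' @export
read_focal_events <- function(path, registry, individuals = NULL) {
  cols <- c("session_id", "focal", "pack_id", "session_start", "session_duration_s",
            "time_s", "actor", "receiver", "behaviour", "duration_s")
  df <- read_table_checked(path, cols, "focal_events")
  df$session_start <- parse_datetime(df$session_start)
  annotate_events(df, registry, individuals)
}

annotate_events <- function(df, registry, individuals = NULL) {
  viol <- violations_frame()
  idx <- match(df$behaviour, registry$behaviour)
  unknown <- which(is.na(idx) & !is.na(df$behaviour))
  for (i in unknown) viol <- add_violation(viol, i, "behaviour",
                                           paste0("unregistered behaviour code '", df$behaviour[i], "'"))
  df$category <- registry$category[idx]
  df$contact <- registry$contact[idx]
  self <- which(!is.na(df$actor) & df$actor == df$receiver)
  for (i in self) viol <- add_violation(viol, i, "actor", "actor equals receiver")
  off_focal <- which(!(df$focal == df$actor | df$focal == df$receiver))
  for (i in off_focal) viol <- add_violation(viol, i, "focal", "focal is neither actor nor receiver")
  outside <- which(df$time_s < 0 | df$time_s + df$duration_s > df$session_duration_s)
  for (i in outside) viol <- add_violation(viol, i, "time_s", "event outside session window")
  if (!is.null(individuals)) {
    ids <- individuals$id
    bad <- which(!(df$actor %in% ids) | !(df$receiver %in% ids))
    if (length(bad)) {
      stop("unknown individual id(s) in events at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  df <- df[order(df$session_id, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "violations") <- viol
  df
}

violations_frame <- function() {
  data.frame(line = integer(0), field = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

add_violation <- function(viol, line, field, message) {
  rbind(viol, data.frame(line = line, field = field, message = message,
                         stringsAsFactors = FALSE))
}

#' @rdname read_focal_events
#' @param events annotated events data.frame.
#' @export
write_focal_events <- function(events, path) {
  out <- events[c("session_id", "focal", "pack_id", "session_start", "session_duration_s",
                  "time_s", "actor", "receiver", "behaviour", "duration_s")]
  out$session_start <- format_datetime(out$session_start)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the conflict log and its PC/MC observations
#'
#' Loads `conflicts.csv` and `pcmc_observations.csv`, resolves PC/MC
#' linkage by `conflict_id`, and reports pairs that cannot be matched.
#' A PC without its MC (or vice versa) is a warning and the pair is
#' excluded downstream; a duplicated `conflict_id` in the conflict table
#' is an error.
#'
#' @param conflicts_path,observations_path CSV files in the documented
#'   dialect.
#' @param registry registry used to sanity-check affiliative pattern codes.
#' @param individuals optional roster for id checks.
#' @return list with elements `conflicts`, `observations` (both
#'   data.frames) and `unmatched` (conflict_ids lacking a complete PC+MC
#'   pair).
#' @export
read_conflict_log <- function(conflicts_path, observations_path, registry,
                              individuals = NULL) {
  ccols <- c("conflict_id", "pack_id", "aggressor", "victim", "start_datetime",
             "end_time_s", "context", "intensity", "outcome")
  conf <- read_table_checked(conflicts_path, ccols, "conflicts")
  if (anyDuplicated(conf$conflict_id)) {
    stop("duplicate conflict_id: ",
         paste(unique(conf$conflict_id[duplicated(conf$conflict_id)]), collapse = ", "),
         call. = FALSE)
  }
  conf$start_datetime <- parse_datetime(conf$start_datetime)
  check_enum(conf$context, c("feeding", "non_feeding"), "context")
  check_enum(conf$intensity, c("low", "high"), "intensity")
  check_enum(conf$outcome, c("decided", "undecided"), "outcome")
  if (any(conf$aggressor == conf$victim)) stop("conflict with aggressor == victim", call. = FALSE)
  if (!is.null(individuals)) {
    bad <- !(conf$aggressor %in% individuals$id) | !(conf$victim %in% individuals$id)
    if (any(bad)) stop("unknown individual id(s) in conflicts", call. = FALSE)
  }

  ocols <- c("obs_id", "conflict_id", "type", "focal", "start_datetime", "duration_s",
             "proximity_s", "event_index", "initiator", "latency_s", "event_duration_s",
             "patterns", "any_contact")
  obs <- read_table_checked(observations_path, ocols, "pcmc_observations")
  obs$start_datetime <- parse_datetime(obs$start_datetime)
  check_enum(obs$type, c("PC", "MC"), "type")
  obs$any_contact <- as.logical(obs$any_contact)
  ev <- !is.na(obs$event_index)
  check_enum(obs$initiator[ev], c("victim", "aggressor"), "initiator")
  if (any(ev & (obs$latency_s < 0 | obs$latency_s >= obs$duration_s), na.rm = TRUE)) {
    stop("affiliative latency outside [0, duration)", call. = FALSE)
  }
  if (any(obs$proximity_s < 0 | obs$proximity_s > obs$duration_s, na.rm = TRUE)) {
    stop("proximity_s outside [0, duration]", call. = FALSE)
  }
  unknown_conf <- setdiff(obs$conflict_id, conf$conflict_id)
  if (length(unknown_conf)) {
    stop("observations reference unknown conflict_id(s): ",
         paste(utils::head(unknown_conf, 5), collapse = ", "), call. = FALSE)
  }
  codes <- unlist(strsplit(obs$patterns[ev & !is.na(obs$patterns)], " ", fixed = TRUE))
  unknown_codes <- setdiff(codes, registry$behaviour)
  if (length(unknown_codes)) {
    warning("unregistered affiliative pattern code(s): ",
            paste(unknown_codes, collapse = ", "), call. = FALSE)
  }

  have_pc <- unique(obs$conflict_id[obs$type == "PC"])
  have_mc <- unique(obs$conflict_id[obs$type == "MC"])
  unmatched <- union(setdiff(have_pc, have_mc), setdiff(have_mc, have_pc))
  if (length(unmatched)) {
    warning(length(unmatched), " conflict(s) lack a complete PC+MC pair and are excluded: ",
            paste(utils::head(unmatched, 5), collapse = ", "), call. = FALSE)
  }
  list(conflicts = conf, observations = obs, unmatched = unmatched)
}

check_enum <- function(x, allowed, what) {
  bad <- setdiff(stats::na.omit(unique(x)), allowed)
  if (length(bad)) {
    stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                 paste(bad, collapse = ", "), paste(allowed, collapse = "|")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname read_conflict_log
#' @param conflicts,observations data.frames in the in-memory layout.
#' @param path output file.
#' @export
write_conflicts <- function(conflicts, path) {
  out <- conflicts[c("conflict_id", "pack_id", "aggressor", "victim", "start_datetime",
                     "end_time_s", "context", "intensity", "outcome")]
  out$start_datetime <- format_datetime(out$start_datetime)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_conflict_log
#' @export
write_observations <- function(observations, path) {
  out <- observations[c("obs_id", "conflict_id", "type", "focal", "start_datetime",
                        "duration_s", "proximity_s", "event_index", "initiator",
                        "latency_s", "event_duration_s", "patterns", "any_contact")]
  out$start_datetime <- format_datetime(out$start_datetime)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a full dataset to a directory in the four-table dialect
#' @param dataset list with `individuals`, `focal_events`, `conflicts`,
#'   `observations`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_individuals(dataset$individuals, file.path(dir, "individuals.csv"))
  write_focal_events(dataset$focal_events, file.path(dir, "focal_events.csv"))
  write_conflicts(dataset$conflicts, file.path(dir, "conflicts.csv"))
  write_observations(dataset$observations, file.path(dir, "pcmc_observations.csv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @param registry behaviour registry used while reading.
#' @export
read_dataset <- function(dir, registry) {
  individuals <- read_individuals(file.path(dir, "individuals.csv"))
  focal_events <- read_focal_events(file.path(dir, "focal_events.csv"), registry, individuals)
  log <- read_conflict_log(file.path(dir, "conflicts.csv"),
                           file.path(dir, "pcmc_observations.csv"),
                           registry, individuals)
  list(individuals = individuals, focal_events = focal_events,
       conflicts = log$conflicts, observations = log$observations,
       unmatched = log$unmatched)
}

#' Validate a matched-control observation against its post-conflict one
#'
#' An MC is valid for its PC when it (a) follows the same focal
#' individual, (b) takes place on a later calendar day, (c) starts at the
#' same time of day within a tolerance, and (d) is preceded by a quiet
#' window: no agonistic interaction in the 10 minutes before its start.
#' Violations are data, not exceptions.
#'
#' @param pc,mc single-observation rows (one row each from the
#'   observations table; for multi-row observations pass any row).
#' @param agonistic_times POSIXct vector of the start times of agonistic
#'   interactions involving the focal (conflict starts and aggressive
#'   events); used for check (d).
#' @param tod_tolerance_s "same time of day" tolerance, seconds
#'   (default 1800 = 30 min).
#' @param quiet_window_s required quiet pre-window, seconds (default 600).
#' @return character vector of violation messages; length 0 means valid.
#' @export
validate_mc_match <- function(pc, mc, agonistic_times = as.POSIXct(character(0), tz = "UTC"),
                              tod_tolerance_s = 1800, quiet_window_s = 600) {
  stopifnot(pc$conflict_id[1] == mc$conflict_id[1])
  v <- character(0)
  if (pc$focal[1] != mc$focal[1]) v <- c(v, "MC focal differs from PC focal")
  pc_day <- as.Date(pc$start_datetime[1], tz = "UTC")
  mc_day <- as.Date(mc$start_datetime[1], tz = "UTC")
  if (!(mc_day > pc_day)) v <- c(v, "MC not on a later calendar day than PC")
  tod <- function(t) as.numeric(difftime(t, as.POSIXct(format(t, "%Y-%m-%d"), tz = "UTC"),
                                         units = "secs"))
  dtod <- abs(tod(mc$start_datetime[1]) - tod(pc$start_datetime[1]))
  dtod <- min(dtod, 86400 - dtod)
  if (dtod > tod_tolerance_s) {
    v <- c(v, sprintf("MC start time of day differs from PC by %.0f s (tolerance %.0f s)",
                      dtod, tod_tolerance_s))
  }
  if (length(agonistic_times)) {
    gap <- as.numeric(difftime(mc$start_datetime[1], agonistic_times, units = "secs"))
    if (any(gap > 0 & gap <= quiet_window_s, na.rm = TRUE)) {
      v <- c(v, sprintf("agonistic interaction within %.0f s before MC start", quiet_window_s))
    }
  }
  v
}

#' Validate a whole dataset
#'
#' Runs every structural check over a dataset list: event-level
#' violations, conflict invariants (aggressor != victim, intensity
#' consistent with contact), observation bounds, PC/MC linkage and
#' MC-match rules. Total by construction: every malformed record yields a
#' report row, never silent acceptance.
#'
#' @param dataset list as returned by [read_dataset()] or
#'   [generate_dataset()].
#' @param registry behaviour registry.
#' @inheritParams validate_mc_match
#' @return data.frame of class `pcmc_validation` with columns
#'   `scope, ref, message`; zero rows means the dataset is clean.
#' @export
validate_dataset <- function(dataset, registry, tod_tolerance_s = 1800,
                             quiet_window_s = 600) {
  rep <- data.frame(scope = character(0), ref = character(0), message = character(0),
                    stringsAsFactors = FALSE)
  note <- function(rep, scope, ref, message) {
    rbind(rep, data.frame(scope = scope, ref = as.character(ref), message = message,
                          stringsAsFactors = FALSE))
  }
  ev <- annotate_events(dataset$focal_events, registry, dataset$individuals)
  v <- attr(ev, "violations")
  if (nrow(v)) for (i in seq_len(nrow(v))) {
    rep <- note(rep, "focal_events", v$line[i], paste0(v$field[i], ": ", v$message[i]))
  }
  conf <- dataset$conflicts
  bad <- which(conf$aggressor == conf$victim)
  for (i in bad) rep <- note(rep, "conflicts", conf$conflict_id[i], "aggressor equals victim")
  obs <- dataset$observations
  evrow <- !is.na(obs$event_index)
  bad <- which(evrow & (obs$latency_s < 0 | obs$latency_s >= obs$duration_s))
  for (i in bad) rep <- note(rep, "observations", obs$obs_id[i], "latency outside [0, duration)")
  bad <- which(obs$proximity_s < 0 | obs$proximity_s > obs$duration_s)
  for (i in bad) rep <- note(rep, "observations", obs$obs_id[i], "proximity outside [0, duration]")

  agonistic <- conf$start_datetime
  for (cid in intersect(unique(obs$conflict_id[obs$type == "PC"]),
                        unique(obs$conflict_id[obs$type == "MC"]))) {
    pc <- obs[obs$conflict_id == cid & obs$type == "PC", , drop = FALSE][1, ]
    mc <- obs[obs$conflict_id == cid & obs$type == "MC", , drop = FALSE][1, ]
    for (msg in validate_mc_match(pc, mc, agonistic, tod_tolerance_s, quiet_window_s)) {
      rep <- note(rep, "mc_match", cid, msg)
    }
  }
  class(rep) <- c("pcmc_validation", "data.frame")
  rep
}

#' @export
print.pcmc_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("dataset valid: no violations\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    print.data.frame(utils::head(x, 50))
  }
  invisible(x)
}
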