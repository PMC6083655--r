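test_that("registry round-trips through YAML and rejects bad categories", {
  reg <- default_registry()
  expect_s3_class(reg, "pcmc_registry")
  expect_true(all(c("threat", "nose_touch", "crouch") %in% reg$behaviour))
  tmp <- tempfile(fileext = ".yaml")
  write_registry(reg, tmp)
  expect_equal(read_registry(tmp), reg)
  bad <- tempfile(fileext = ".yaml")
  writeLines("odd:\n  category: weird\n  contact: false", bad)
  expect_error(read_registry(bad), "unknown behaviour categories")
})

test_that("a written dataset rereads identically", {
  ds <- generate_dataset(scenario_config(pack_sizes = c(3L, 2L), n_conflicts = 15), seed = 12)
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_dataset(dir, default_registry())
  expect_equal(back$individuals, ds$individuals)
  expect_equal(back$conflicts, ds$conflicts)
  for (col in names(ds$observations)) {
    expect_equal(back$observations[[col]], ds$observations[[col]], info = col)
  }
  ev0 <- ds$focal_events; attr(ev0, "violations") <- NULL
  ev1 <- back$focal_events; attr(ev1, "violations") <- NULL
  expect_equal(ev1, ev0)
})

test_that("header-only event file parses to an empty collection", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(paste("session_id,focal,pack_id,session_start,session_duration_s",
                   "time_s,actor,receiver,behaviour,duration_s", sep = ","), tmp)
  ev <- read_focal_events(tmp, default_registry())
  expect_equal(nrow(ev), 0L)
  expect_equal(nrow(attr(ev, "violations")), 0L)
})

test_that("unknown behaviour codes are reported, not silently accepted", {
  ds <- make_tiny_dataset()
  ev <- ds$focal_events
  ev$behaviour[2] <- "teleport"
  ev2 <- annotate_events(ev, default_registry(), ds$individuals)
  v <- attr(ev2, "violations")
  expect_equal(nrow(v), 1L)
  expect_match(v$message, "unregistered")
  rep <- validate_dataset(list(individuals = ds$individuals, focal_events = ev,
                               conflicts = ds$conflicts, observations = ds$observations),
                          default_registry())
  expect_gte(nrow(rep), 1L)
})

test_that("conflict log linkage: missing MC warns, duplicates error", {
  reg <- default_registry()
  ds <- generate_dataset(scenario_config(pack_sizes = c(3L, 2L), n_conflicts = 5), seed = 8)
  dir <- tempfile(); write_dataset(ds, dir)
  log <- read_conflict_log(file.path(dir, "conflicts.csv"),
                           file.path(dir, "pcmc_observations.csv"), reg)
  expect_length(log$unmatched, 0)
  expect_equal(length(intersect(unique(log$observations$conflict_id[log$observations$type == "PC"]),
                                unique(log$observations$conflict_id[log$observations$type == "MC"]))), 5)
  # drop one MC -> warning and exclusion
  obs <- ds$observations[!(ds$observations$type == "MC" &
                           ds$observations$conflict_id == ds$conflicts$conflict_id[1]), ]
  write_observations(obs, file.path(dir, "pcmc_observations.csv"))
  expect_warning(
    log2 <- read_conflict_log(file.path(dir, "conflicts.csv"),
                              file.path(dir, "pcmc_observations.csv"), reg),
    "lack a complete PC\\+MC pair")
  expect_equal(log2$unmatched, ds$conflicts$conflict_id[1])
  # duplicated conflict id -> error
  conf2 <- rbind(ds$conflicts, ds$conflicts[1, ])
  write_conflicts(conf2, file.path(dir, "conflicts.csv"))
  expect_error(read_conflict_log(file.path(dir, "conflicts.csv"),
                                 file.path(dir, "pcmc_observations.csv"), reg),
               "duplicate conflict_id")
})

test_that("malformed rows fail loudly with their location", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("conflict_id,pack_id,aggressor,victim,start_datetime,end_time_s,context,intensity,outcome",
               "c1,p1,a,b,2013-13-45T99:00:00,10,non_feeding,high,decided"), tmp)
  obs <- tempfile(fileext = ".csv")
  writeLines(paste("obs_id,conflict_id,type,focal,start_datetime,duration_s,proximity_s",
                   "event_index,initiator,latency_s,event_duration_s,patterns,any_contact",
                   sep = ","), obs)
  expect_error(read_conflict_log(tmp, obs, default_registry()), "datetime")
  writeLines(c("conflict_id,pack_id,aggressor", "c1,p1,a"), tmp)
  expect_error(read_conflict_log(tmp, obs, default_registry()), "missing column")
})

test_that("MC match rules: valid case and each violation", {
  t0 <- as.POSIXct("2013-03-01 10:00:00", tz = "UTC")
  pc <- data.frame(conflict_id = "c1", focal = "v", start_datetime = t0)
  mc_ok <- data.frame(conflict_id = "c1", focal = "v", start_datetime = t0 + 86400 + 600)
  expect_length(validate_mc_match(pc, mc_ok), 0)
  # (d) aggression 5 minutes before the MC start
  expect_match(validate_mc_match(pc, mc_ok, agonistic_times = mc_ok$start_datetime - 300),
               "agonistic interaction within")
  # (b) same calendar day (also trips the time-of-day tolerance)
  mc_same <- mc_ok; mc_same$start_datetime <- t0 + 3600
  expect_true(any(grepl("later calendar day", validate_mc_match(pc, mc_same))))
  # (c) time of day outside tolerance
  mc_late <- mc_ok; mc_late$start_datetime <- t0 + 86400 + 7200
  expect_match(validate_mc_match(pc, mc_late), "time of day differs")
  # (a) different focal
  mc_focal <- mc_ok; mc_focal$focal <- "w"
  expect_match(validate_mc_match(pc, mc_focal)[1], "focal differs")
})
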