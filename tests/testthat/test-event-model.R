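test_that("event log CSV round-trips and sorts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,participant_id,sensor_id",
               "2021-03-01T08:00:00,p1,s_bedroom",
               "2021-03-01T08:00:30,p1,s_kitchen",
               "2021-03-01T08:00:45,p1,s_kitchen"), f)
  log <- read_event_log(f)
  expect_equal(nrow(log$events), 3L)
  expect_equal(log$participant_id, "p1")
  expect_equal(log$events$sensor_id, c("s_bedroom", "s_kitchen", "s_kitchen"))
  expect_equal(as.numeric(diff(log$events$timestamp), units = "secs"),
               c(30, 15))

  # write/read round-trip preserves content
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log, f2)
  log2 <- read_event_log(f2)
  expect_equal(log2$events$sensor_id, log$events$sensor_id)
  expect_equal(as.numeric(log2$events$timestamp),
               as.numeric(log$events$timestamp))

  # empty file with header only
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,participant_id,sensor_id", f3)
  expect_equal(nrow(read_event_log(f3)$events), 0L)
})

test_that("shuffled rows are restored to the order of an independent sort", {
  set.seed(11)
  n <- 1000L
  secs <- sample.int(5 * 86400, n)
  sens <- sample(c("s_a", "s_b", "s_c"), n, replace = TRUE)
  ts <- format(as.POSIXct("2021-03-01", tz = "UTC") + secs,
               "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,participant_id,sensor_id",
               paste(ts, "p1", sens, sep = ",")), f)
  log <- read_event_log(f, sort = TRUE)
  # oracle: plain lexicographic sort of the ISO strings
  o <- order(ts)
  expect_identical(log$events$sensor_id, sens[o])
  expect_identical(format(log$events$timestamp, "%Y-%m-%dT%H:%M:%S",
                          tz = "UTC"), ts[o])
})

test_that("malformed and inconsistent logs are rejected with context", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,participant_id,sensor_id",
               "2021-03-01T08:00:00,p1,s_a",
               "not-a-time,p1,s_a"), f)
  expect_error(read_event_log(f), "row 2")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,participant_id,sensor_id",
               "2021-03-01T08:00:00,p1,s_a",
               "2021-03-01T08:00:10,p2,s_a"), f2)
  expect_error(read_event_log(f2), "participant")
})

test_that("validation counts cool-down violations and unknown sensors", {
  topo <- flat5()
  # 8 s gap is the legal boundary; 5 s violates
  log <- event_log("p1", make_events(c(0, 8, 13), rep("s_kitchen", 3)))
  rep1 <- validate_event_log(log, topo)
  expect_equal(rep1$n_cooldown_violation, 1L)
  expect_equal(rep1$cooldown_violation_rows, 3L)
  log2 <- event_log("p1", make_events(c(0, 8), rep("s_kitchen", 2)))
  expect_equal(validate_event_log(log2, topo)$n_cooldown_violation, 0L)
  # interleaved other-sensor events do not reset the same-sensor clock
  log3 <- event_log("p1", make_events(c(0, 4, 7), c("s_kitchen", "s_hallway",
                                                    "s_kitchen")))
  expect_equal(validate_event_log(log3, topo)$n_cooldown_violation, 1L)
  # unknown sensor
  log4 <- event_log("p1", make_events(0, "s_garage"))
  expect_equal(validate_event_log(log4, topo)$n_unknown_sensor, 1L)
  # validation is pure: repeated calls agree and do not mutate
  expect_identical(validate_event_log(log, topo),
                   validate_event_log(log, topo))
  expect_equal(nrow(log$events), 3L)
})

test_that("cool-down cleaning drops exactly the violating events", {
  log <- event_log("p1", make_events(c(0, 5, 9, 20), rep("s_a", 4)))
  clean <- drop_cooldown_violations(log)
  expect_equal(as.numeric(clean$events$timestamp) -
                 as.numeric(clean$events$timestamp[1]), c(0, 9, 20))
  expect_equal(validate_event_log(clean)$n_cooldown_violation, 0L)
})

test_that("split_by_day partitions events at civil midnight", {
  # boundary: 23:59:55 and 00:00:05 next day land on different days
  log <- event_log("p1", make_events(c(86395, 86405), c("s_a", "s_b")))
  days <- split_by_day(log)
  expect_equal(length(days), 2L)
  expect_equal(vapply(days, function(d) nrow(d$events), integer(1)),
               c("2021-03-01" = 1L, "2021-03-02" = 1L))
  # all on one date
  log2 <- event_log("p1", make_events(c(10, 20, 30), rep("s_a", 3)))
  expect_equal(length(split_by_day(log2)), 1L)
  # partition property on a sparse month: counts sum, order preserved
  set.seed(7)
  secs <- sort(sample.int(30 * 86400, 500))
  log3 <- event_log("p1", make_events(secs, sample(letters[1:3], 500, TRUE)))
  days3 <- split_by_day(log3)
  expect_equal(sum(vapply(days3, function(d) nrow(d$events), integer(1))),
               500L)
  recon <- do.call(rbind, lapply(days3, `[[`, "events"))
  expect_equal(as.numeric(recon$timestamp),
               as.numeric(log3$events$timestamp))
  # empty log
  expect_equal(length(split_by_day(event_log("p1", make_events(numeric(),
                                                               character())))),
               0L)
})

test_that("topology JSON round-trips with loops and both directions", {
  topo <- flat5()
  expect_false(topo$transitions["bedroom", "bathroom"])
  expect_false(topo$transitions["bathroom", "bedroom"])
  expect_true(topo$transitions["bedroom", "bedroom"])  # loops always possible
  f <- withr::local_tempfile(fileext = ".json")
  write_topology(topo, f)
  topo2 <- read_topology(f)
  expect_identical(topo2$rooms, topo$rooms)
  expect_identical(topo2$transitions, topo$transitions)
  expect_identical(sort(names(topo2$sensors)), sort(names(topo$sensors)))
})

test_that("topology schema violations are rejected", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"rooms": ["a"], "sensors": {"s1": "b"}, "connections": []}', f)
  expect_error(read_topology(f), "unlisted room")
  writeLines('{"rooms": ["a", "a"], "sensors": {"s1": "a"}, "connections": []}',
             f)
  expect_error(read_topology(f), "duplicate")
  # one-room flat: loops only
  writeLines('{"rooms": ["a"], "sensors": {"s1": "a"}, "connections": []}', f)
  t1 <- read_topology(f)
  expect_identical(t1$transitions, matrix(TRUE, 1, 1,
                                          dimnames = list("a", "a")))
})

test_that("assessment records are typed and bounded", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,date,sppb,tug",
               "p1,2021-03-01,6,17.87",
               "p1,2021-09-01,7,16.12"), f)
  a <- read_assessments(f)
  expect_s3_class(a$date, "Date")
  expect_equal(a$sppb, c(6, 7))
  writeLines(c("participant_id,date,sppb,tug",
               "p1,2021-03-01,13,17.0"), f)
  expect_error(read_assessments(f), "SPPB")
  writeLines(c("participant_id,date,sppb,tug",
               "p1,2021-03-01,6,-1"), f)
  expect_error(read_assessments(f), "TUG")
})
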