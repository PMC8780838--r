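test_that("generated topologies are deterministic, connected, and have an
          impossible pair", {
  t1 <- generate_topology(5, seed = 12)
  t2 <- generate_topology(5, seed = 12)
  expect_identical(t1$transitions, t2$transitions)
  expect_identical(t1$sensors, t2$sensors)
  expect_false(identical(t1$transitions,
                         generate_topology(5, seed = 13)$transitions))
  # bedroom <-> bathroom never directly connected
  expect_false(t1$transitions["bedroom", "bathroom"])
  # hub adjacency: every room reachable from the hallway
  expect_true(all(t1$transitions["hallway", ]))
  # loops everywhere
  expect_true(all(diag(t1$transitions)))
  t_one <- generate_topology(1, seed = 1)
  expect_equal(t_one$n, 1L)
  expect_identical(unname(t_one$transitions[1, 1]), TRUE)
})

test_that("an immobile resident with entry-only emission fires at most once
          a day", {
  topo <- generate_topology(1, seed = 2)
  model <- resident_model(topo, retrigger_rate = c("living room" = 0),
                          default_rate = 0, night_rate = 0)
  sim <- simulate_participant(model, days = 10, seed = 5)
  expect_true(all(sim$truth$daily_events <= 1))
})

test_that("emitted logs respect the cool-down and the topology", {
  for (seed in c(3, 17)) {
    topo <- generate_topology(5, seed = seed)
    sim <- simulate_participant(resident_model(topo), days = 20, seed = seed)
    rep <- validate_event_log(sim$log, topo)
    expect_equal(rep$n_cooldown_violation, 0L)
    expect_equal(rep$n_unknown_sensor, 0L)
    expect_equal(rep$n_out_of_order, 0L)
    # resident reachability: consecutive rooms always connected
    ridx <- match(topo$sensors[sim$log$events$sensor_id], topo$rooms)
    pairs <- cbind(ridx[-length(ridx)], ridx[-1])
    expect_true(all(topo$transitions[pairs]))
  }
})

test_that("same seed reproduces the identical log", {
  topo <- generate_topology(5, seed = 9)
  m <- resident_model(topo)
  s1 <- simulate_participant(m, days = 15, seed = 77, slope = -1e-3)
  s2 <- simulate_participant(m, days = 15, seed = 77, slope = -1e-3)
  expect_identical(s1$log$events, s2$log$events)
  expect_identical(s1$truth$daily_events, s2$truth$daily_events)
})

test_that("injected activity decline is recoverable from daily counts", {
  slope <- -0.003
  topo <- generate_topology(5, seed = 30)
  m <- resident_model(topo)
  rel_err <- vapply(1:5, function(seed) {
    sim <- simulate_participant(m, days = 300, seed = seed, slope = slope)
    counts <- sim$truth$daily_events
    f <- fit_linear_trend(seq_along(counts) - 1, as.numeric(counts))
    # expected daily count declines as count0 * (1 + slope * t)
    a_rel <- f$a / f$b
    abs(a_rel - slope) / abs(slope)
  }, numeric(1))
  expect_lt(mean(rel_err), 0.3)
})

test_that("doubling the re-trigger rate roughly doubles diagonal mass", {
  topo <- generate_topology(5, seed = 40)
  base_rates <- c("living room" = 0.3, "bedroom" = 0.2, "kitchen" = 0.35,
                  "bathroom" = 0.35, "hallway" = 0.15)
  diag_mass <- function(mult, seed) {
    m <- resident_model(topo, retrigger_rate = base_rates * mult,
                        night_rate = 0)
    sim <- simulate_participant(m, days = 20, seed = seed)
    dd <- daily_matrices(sim$log, topo, mask = FALSE)
    mean(vapply(dd, function(A) sum(diag(unclass(A))), numeric(1)))
  }
  r <- vapply(1:6, function(s) diag_mass(2, s) / diag_mass(1, s), numeric(1))
  expect_gt(mean(r), 1.6)
  expect_lt(mean(r), 2.4)
})

test_that("cohort simulation is deterministic and honours group structure", {
  spec <- cohort_spec(n_intervention = 2, n_control = 1, study_days = 12,
                      seed = 6)
  d1 <- simulate_cohort(spec)
  d2 <- simulate_cohort(spec)
  expect_equal(length(d1$participants), 3L)
  expect_identical(lapply(d1$participants, function(p) p$log$events),
                   lapply(d2$participants, function(p) p$log$events))
  expect_identical(d1$assessments, d2$assessments)
  groups <- vapply(d1$participants, `[[`, character(1), "group")
  expect_equal(sum(groups == "intervention"), 2L)
  expect_equal(sum(groups == "control"), 1L)
  # injected slopes recorded in the ground truth
  for (p in d1$participants)
    expect_equal(p$truth$slope,
                 if (p$group == "intervention") spec$intervention_slope
                 else spec$control_slope)
  # empty cohort
  d0 <- simulate_cohort(cohort_spec(n_intervention = 0, n_control = 0))
  expect_equal(length(d0$participants), 0L)
  expect_equal(nrow(d0$assessments), 0L)
})

test_that("assessments stay within instrument bounds", {
  ds <- simulate_cohort(cohort_spec(n_intervention = 3, n_control = 3,
                                    study_days = 120, seed = 14))
  a <- ds$assessments
  expect_true(all(a$sppb >= 0 & a$sppb <= 12))
  expect_true(all(a$sppb == round(a$sppb)))
  expect_true(all(a$tug > 0))
  expect_equal(length(unique(a$participant_id)), 6L)
})

test_that("visitor noise adds impossible transitions that masking absorbs", {
  topo <- generate_topology(5, seed = 50)
  sim <- simulate_participant(resident_model(topo), days = 15, seed = 51)
  # rate 0: identity
  same <- inject_visitor_noise(sim$log, topo, rate = 0)
  expect_identical(same$log$events, sim$log$events)
  expect_equal(length(same$indices), 0L)
  # same seed: same injections
  c1 <- inject_visitor_noise(sim$log, topo, rate = 40, seed = 3)
  c2 <- inject_visitor_noise(sim$log, topo, rate = 40, seed = 3)
  expect_identical(c1$log$events, c2$log$events)
  expect_gt(length(c1$indices), 0L)
  # masked daily matrices move less than unmasked ones under contamination
  l1 <- function(a, b) sum(abs(unclass(a) - unclass(b)))
  um_clean <- daily_matrices(sim$log, topo, mask = FALSE)
  um_cont <- daily_matrices(c1$log, topo, mask = FALSE)
  m_clean <- daily_matrices(sim$log, topo, mask = TRUE)
  m_cont <- daily_matrices(c1$log, topo, mask = TRUE)
  days <- intersect(names(um_clean), names(um_cont))
  d_unmasked <- sum(vapply(days, function(d) l1(um_cont[[d]], um_clean[[d]]),
                           numeric(1)))
  d_masked <- sum(vapply(days, function(d) l1(m_cont[[d]], m_clean[[d]]),
                         numeric(1)))
  expect_lt(d_masked, d_unmasked)
})
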