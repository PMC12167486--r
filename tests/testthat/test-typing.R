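test_that("events carry the right conditions and actions", {
  # 1 OD1 agent against a fixed background so route costs are scripted
  net2 <- network_config(canon$routes, c(OD1 = 2, OD2 = 0), canon$od_menu)
  script <- c("Local1", "Local1", "Expressway", "Expressway")
  roster <- list(llm_agent("L1", "OD1", scripted_responder(script)),
                 fixed_agent("F1", "OD1", "Expressway"))
  log <- run_trial(net2, roster, days = 1, intervals = 4, seed = 1)
  ev <- extract_events(log, net2, "L1", 1:4)
  expect_equal(nrow(ev), 3L)
  # interval 1: Local1 has 1 user (15.0096), Expressway 1 user (5.0046):
  # L1 sat on the worse route and stayed
  expect_equal(ev$condition[1], "prev_on_worse")
  expect_equal(ev$action[1], "stay")
  # interval 2 same state; switch at interval 3
  expect_equal(ev$condition[2], "prev_on_worse")
  expect_equal(ev$action[2], "switch")
  # interval 3: both on Expressway (2 users, 5.074) vs empty Local1 (15):
  # the agent sat on the better route and stayed
  expect_equal(ev$condition[3], "prev_on_better")
  expect_equal(ev$action[3], "stay")
})

test_that("a tie in previous costs is excluded from conditioning", {
  # symmetric two-route costs: craft equal costs via equal parameters
  routes <- list(route_spec("Local1", 10, 5, 0.1, 4, "OD1"),
                 route_spec("Expressway", 10, 5, 0.1, 4, c("OD1", "OD2")),
                 route_spec("Local2", 10, 5, 0.1, 4, "OD2"))
  net <- network_config(routes, c(OD1 = 2, OD2 = 0),
                        list(OD1 = c("Local1", "Expressway"),
                             OD2 = c("Local2", "Expressway")))
  roster <- list(fixed_agent("F1", "OD1", "Local1"),
                 fixed_agent("F2", "OD1", "Expressway"))
  log <- run_trial(net, roster, days = 1, intervals = 3, seed = 1)
  ev <- extract_events(log, net, "F1", 1:3)
  expect_true(all(ev$condition == "tie"))
  tv <- estimate_type_vector(ev)
  expect_equal(tv$n_worse, 0L)
  expect_equal(tv$n_better, 0L)
  expect_true(tv$imputed_c && tv$imputed_s)
  expect_equal(tv$c_minus, 0)
  expect_equal(tv$s_minus, 1)
})

test_that("estimated vectors match planted conditional probabilities", {
  # simulate events directly from planted probabilities (independent of the
  # game dynamics), then check the estimator recovers them
  gen_events <- function(c_minus, s_minus, n, seed) {
    set.seed(seed)
    cond <- sample(c("prev_on_worse", "prev_on_better"), n, replace = TRUE)
    p_sw <- ifelse(cond == "prev_on_worse", c_minus, 1 - s_minus)
    data.frame(agent_id = "X", t = seq_len(n) + 1, day = 1, interval = 1,
               condition = cond,
               action = ifelse(runif(n) < p_sw, "switch", "stay"))
  }
  tv <- estimate_type_vector(gen_events(0.8, 0.6, 10000, 123))
  expect_equal(tv$c_minus, 0.8, tolerance = 0.02 / 0.8)
  expect_equal(tv$s_minus, 0.6, tolerance = 0.02 / 0.6)
  expect_false(tv$imputed_c || tv$imputed_s)
  # complements follow the identity C- + S+ = C+ + S- = 1 by construction
  expect_equal(tv$c_minus + (1 - tv$c_minus), 1)
})

test_that("degenerate trajectories classify to the expected vertices", {
  # never-switching agent with both conditions observed -> status quo (0, 1)
  ev <- data.frame(agent_id = "A", t = 2:5, day = 1, interval = 2:5,
                   condition = c("prev_on_worse", "prev_on_better",
                                 "prev_on_worse", "prev_on_better"),
                   action = "stay")
  tv <- estimate_type_vector(ev)
  expect_equal(tv$c_minus, 0)
  expect_equal(tv$s_minus, 1)
  cl <- classify_type(tv)
  expect_equal(cl$label, "status_quo")
  expect_equal(cl$distance, 0)
})

test_that("classification picks the nearest vertex with documented ties", {
  expect_equal(classify_type(list(c_minus = 0.9, s_minus = 0.95))$label,
               "naive")
  expect_equal(classify_type(list(c_minus = 0.1, s_minus = 0.05))$label,
               "strategic")
  expect_equal(classify_type(list(c_minus = 0.95, s_minus = 0.1))$label,
               "exploratory")
  expect_equal(classify_type(list(c_minus = 0.5, s_minus = 0.5))$label,
               "status_quo")
  # brute-force nearest-vertex oracle on a grid
  vertices <- list(naive = c(1, 1), strategic = c(0, 0),
                   exploratory = c(1, 0), status_quo = c(0, 1))
  for (cm in seq(0, 1, by = 0.2))
    for (sm in seq(0, 1, by = 0.2)) {
      d <- vapply(vertices, function(v) sum((c(cm, sm) - v)^2), numeric(1))
      mind <- min(d)
      candidates <- names(vertices)[d - mind < 1e-12]
      got <- classify_type(list(c_minus = cm, s_minus = sm))$label
      expect_true(got %in% candidates)
      if (length(candidates) > 1)
        expect_equal(got, intersect(c("status_quo", "naive", "strategic",
                                      "exploratory"), candidates)[1])
    }
})

test_that("archetypes at eps = 0 are classified to their planted vertex", {
  spec <- population_spec(c(naive = 0.4, strategic = 0.2, exploratory = 0.2,
                            status_quo = 0.2), noise_eps = 0)
  gen <- generate_trials(canon, spec, n_trials = 1, seed = 21, days = 10)
  tab <- windowed_type_table(gen$logs[[1]], canon, list(all = 1:40))
  merged <- merge(tab$agents, gen$manifest$agents, by = "agent_id")
  # exact classification whenever both conditions were observed
  seen_both <- merged$n_worse >= 1 & merged$n_better >= 1
  expect_true(all(merged$label.x[seen_both] == merged$label.y[seen_both]))
  expect_true(any(seen_both))
})

test_that("windowed classification ignores records outside the window", {
  spec <- population_spec(c(naive = 0.5, exploratory = 0.5), noise_eps = 0.1)
  log <- run_trial(canon, generate_roster(spec)$roster, days = 10, seed = 3)
  before <- windowed_type_table(log, canon, list(late = 21:40))$agents
  # perturb early records (outside the window): flip routes and wreck costs
  log2 <- log
  idx <- which((log2$day - 1) * 4 + log2$interval <= 20)
  flip <- idx[log2$agent_id[idx] == "A01"]
  log2$route[flip] <- ifelse(log2$route[flip] == "Local1", "Expressway",
                             "Local1")
  log2$travel_cost[idx] <- 999
  after <- windowed_type_table(log2, canon, list(late = 21:40))$agents
  expect_equal(after$label, before$label)
  expect_equal(after$c_minus, before$c_minus)
})

test_that("type proportions sum to one in every window", {
  spec <- population_spec(c(naive = 0.4, strategic = 0.2, exploratory = 0.2,
                            status_quo = 0.2), noise_eps = 0.05)
  log <- run_trial(canon, generate_roster(spec)$roster, days = 10, seed = 13)
  tab <- windowed_type_table(log, canon, list(early = 1:20, late = 21:40))
  sums <- aggregate(proportion ~ window, tab$proportions, sum)
  expect_equal(sums$proportion, c(1, 1))
  # 15 fixed agents are all status quo in any window
  fix_log <- pinned_log(ue_assignment(), days = 10)
  fix_tab <- windowed_type_table(fix_log, canon,
                                 list(early = 1:20, late = 21:40))
  sq <- fix_tab$proportions[fix_tab$proportions$type == "status_quo", ]
  expect_equal(sq$proportion, c(1, 1))
})
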