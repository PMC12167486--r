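#' Run one multi-day route-choice trial
#'
#' Plays `days * intervals` rounds of simultaneous route choice. Each round
#' every agent receives an observation of the previous round (per-route user
#' counts and travel times, its own previous route, and the interval index),
#' returns a route from its OD menu, and incurs the full BPR travel cost of
#' that route at the round's realized occupancy. Feedback is instantaneous
#' and days are continuous: the first interval of a day observes the last
#' interval of the previous day, and a route change across the day boundary
#' counts as a switch.
#'
#' At the very first interval no history exists: observations carry zero
#' counts/costs and `has_history = FALSE`; stochastic policies then choose
#' uniformly at random on their menu.
#'
#' @param network A [network_config()].
#' @param roster List of [agent_spec()] objects whose OD memberships match
#'   the network demands.
#' @param days,intervals Horizon: number of days and decision intervals per
#'   day (defaults 40 and 4).
#' @param seed Integer seed; identical inputs reproduce the log exactly.
#' @param trial_id Identifier recorded in every row of the log.
#'
#' @return A `trial_log`: a data frame with one row per agent-interval and
#'   columns `trial_id, day, interval, agent_id, od_group, route,
#'   travel_cost, switched`, plus attributes `horizon` and `config_digest`.
#' @export
#' @examples
#' net <- canonical_network()
#' roster <- pinned_roster(net, solve_user_equilibrium(net)[[1]]$assignment)
#' log <- run_trial(net, roster, days = 2, seed = 1)
#' interval_system_cost(log)
run_trial <- function(network, roster, days = 40L, intervals = 4L,
                      seed = 1L, trial_id = "T1") {
  stopifnot(days >= 1L, intervals >= 1L)
  validate_roster(roster, network)
  ids <- vapply(roster, `[[`, character(1), "agent_id")
  ods <- vapply(roster, `[[`, character(1), "od_group")
  locals <- vapply(ods, function(od) network$od_menu[[od]][1], character(1))
  route_ids <- names(network$routes)
  n_agents <- length(roster)
  n_steps <- days * intervals
  horizon_len <- n_steps

  out_route <- character(n_agents * n_steps)
  out_cost <- numeric(n_agents * n_steps)
  out_switch <- logical(n_agents * n_steps)
  out_day <- integer(n_agents * n_steps)
  out_int <- integer(n_agents * n_steps)

  prev_route <- rep(NA_character_, n_agents)
  prev_totals <- setNames(rep(0L, length(route_ids)), route_ids)
  prev_local_counts <- setNames(rep(0L, length(route_ids)), route_ids)
  prev_costs <- setNames(rep(0, length(route_ids)), route_ids)

  with_seed(seed, {
    for (t in seq_len(n_steps)) {
      day <- (t - 1L) %/% intervals + 1L
      itv <- (t - 1L) %% intervals + 1L
      choices <- character(n_agents)
      for (i in seq_len(n_agents)) {
        obs <- new_observation(
          od_group = ods[i], local_route = locals[i],
          n_local_prev = prev_local_counts[[locals[i]]],
          n_expwy_prev = prev_totals[["Expressway"]],
          cost_local_prev = prev_costs[[locals[i]]],
          cost_expwy_prev = prev_costs[["Expressway"]],
          own_prev_route = prev_route[i],
          time_index = t, horizon_len = horizon_len,
          has_history = t > 1L)
        r <- act(roster[[i]], obs)
        if (!is.character(r) || length(r) != 1L ||
            !r %in% network$od_menu[[ods[i]]])
          stop(sprintf(
            "agent %s returned an off-menu route at day %d interval %d",
            ids[i], day, itv))
        choices[i] <- r
      }
      totals <- setNames(rep(0L, length(route_ids)), route_ids)
      tab <- table(choices)
      totals[names(tab)] <- as.integer(tab)
      costs <- vapply(route_ids, function(id)
        bpr_cost(network$routes[[id]], totals[[id]]), numeric(1))
      # per-route counts restricted to each route's own users; for the local
      # roads this is the owning OD's count (the expressway pools groups)
      local_counts <- totals

      idx <- (t - 1L) * n_agents + seq_len(n_agents)
      out_route[idx] <- choices
      out_cost[idx] <- costs[choices]
      out_switch[idx] <- if (t == 1L) FALSE else choices != prev_route
      out_day[idx] <- day
      out_int[idx] <- itv

      prev_route <- choices
      prev_totals <- totals
      prev_local_counts <- local_counts
      prev_costs <- costs
    }
  })

  log <- data.frame(
    trial_id = trial_id,
    day = out_day, interval = out_int,
    agent_id = rep(ids, n_steps), od_group = rep(ods, n_steps),
    route = out_route, travel_cost = out_cost, switched = out_switch,
    stringsAsFactors = FALSE)
  structure(log, class = c("trial_log", "data.frame"),
            horizon = c(days = days, intervals = intervals),
            config_digest = config_digest(network))
}

new_observation <- function(od_group, local_route, n_local_prev, n_expwy_prev,
                            cost_local_prev, cost_expwy_prev, own_prev_route,
                            time_index, horizon_len, has_history) {
  structure(list(od_group = od_group, local_route = local_route,
                 n_local_prev = n_local_prev, n_expwy_prev = n_expwy_prev,
                 cost_local_prev = cost_local_prev,
                 cost_expwy_prev = cost_expwy_prev,
                 own_prev_route = own_prev_route, time_index = time_index,
                 horizon_len = horizon_len, has_history = has_history),
            class = "observation")
}

#' @export
print.trial_log <- function(x, ...) {
  h <- attr(x, "horizon")
  cat(sprintf("trial log: %d records (%d days x %d intervals, %d agents)\n",
              nrow(x), h[["days"]], h[["intervals"]],
              length(unique(x$agent_id))))
  invisible(x)
}

# interval index 1..D*K from (day, interval) columns
global_interval <- function(log) {
  h <- attr(log, "horizon")
  (log$day - 1L) * h[["intervals"]] + log$interval
}

#' Per-interval total system travel time
#'
#' @param log A `trial_log`.
#' @return Data frame with columns `day`, `interval`, `total_cost` (the sum
#'   of all agents' travel costs in that interval), in chronological order.
#' @export
interval_system_cost <- function(log) {
  agg <- aggregate(travel_cost ~ day + interval, data = as.data.frame(log),
                   FUN = sum)
  agg <- agg[order(agg$day, agg$interval), ]
  rownames(agg) <- NULL
  names(agg)[3] <- "total_cost"
  agg
}

#' Per-agent daily travel cost
#'
#' @param log A `trial_log`.
#' @return Data frame `agent_id`, `day`, `daily_cost` (sum of the agent's
#'   interval costs within the day).
#' @export
daily_agent_cost <- function(log) {
  agg <- aggregate(travel_cost ~ agent_id + day, data = as.data.frame(log),
                   FUN = sum)
  agg <- agg[order(agg$agent_id, agg$day), ]
  rownames(agg) <- NULL
  names(agg)[3] <- "daily_cost"
  agg
}

log_columns <- c("trial_id", "day", "interval", "agent_id", "od_group",
                 "route", "travel_cost", "switched")

#' Write / read a trial log as CSV
#'
#' The CSV dialect is fixed: header
#' `trial_id,day,interval,agent_id,od_group,route,travel_cost,switched`,
#' UTF-8, one decision record per row, costs serialized with 17 significant
#' digits so that `read_trial_log(write_trial_log(x))` reproduces `x`
#' field-for-field.
#'
#' @param log A `trial_log`.
#' @param path Output file path.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   returns a validated `trial_log`.
#' @export
write_trial_log <- function(log, path) {
  df <- as.data.frame(log)[, log_columns]
  df$travel_cost <- sprintf("%.17g", df$travel_cost)
  df$switched <- ifelse(df$switched, "true", "false")
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(log_columns, names(df))
  if (length(missing))
    stop("malformed trial log: missing column(s) ",
         paste(missing, collapse = ", "))
  df <- df[, log_columns]
  if (!is.numeric(df$travel_cost))
    stop("malformed trial log: travel_cost is not numeric")
  df$switched <- df$switched %in% c("true", "TRUE", TRUE)
  df$day <- as.integer(df$day)
  df$interval <- as.integer(df$interval)
  if (anyNA(df$day) || anyNA(df$interval))
    stop("malformed trial log: non-integer day/interval")
  days <- max(df$day)
  intervals <- max(df$interval)
  log <- structure(df, class = c("trial_log", "data.frame"),
                   horizon = c(days = days, intervals = intervals),
                   config_digest = NA_character_)
  validate_trial_log(log)
  log
}

#' Validate the internal consistency of a trial log
#'
#' Checks that every (day, interval) slice contains exactly the same agent
#' set (demand conservation) and, when a network is supplied, that every
#' recorded travel cost equals the BPR cost recomputed from the slice's own
#' per-route occupancies.
#'
#' @param log A `trial_log`.
#' @param network Optional [network_config()] for cost recomputation.
#' @param tol Absolute tolerance for cost recomputation.
#' @return `log`, invisibly; errors on violation.
#' @export
validate_trial_log <- function(log, network = NULL, tol = 1e-8) {
  key <- paste(log$day, log$interval)
  slices <- split(log$agent_id, key)
  ref <- sort(slices[[1]])
  for (s in slices)
    if (!identical(sort(s), ref))
      stop("trial log violates per-interval agent conservation")
  if (!is.null(network)) {
    for (k in unique(key)) {
      rows <- log[key == k, ]
      totals <- table(factor(rows$route, levels = names(network$routes)))
      costs <- vapply(names(network$routes), function(id)
        bpr_cost(network$routes[[id]], as.integer(totals[[id]])), numeric(1))
      if (any(abs(rows$travel_cost - costs[rows$route]) > tol))
        stop("trial log costs are inconsistent with the BPR function at ", k)
    }
  }
  invisible(log)
}
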