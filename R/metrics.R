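#' Sorensen-Dice coefficient between two route-count vectors
#'
#' `sdc(a, b) = 2 * sum_j min(a_j, b_j) / (sum(a) + sum(b))`: the multiset
#' overlap of two distributions of users over routes. Symmetric, in `[0, 1]`,
#' and equal to 1 exactly when the vectors coincide (given equal totals).
#' It is a similarity coefficient, not a metric.
#'
#' @param a,b Named non-negative numeric vectors over the same route set.
#' @return Coefficient in `[0, 1]`.
#' @export
#' @examples
#' sdc(c(Local1 = 5, Expressway = 5, Local2 = 5),
#'     c(Local1 = 4, Expressway = 7, Local2 = 4)) # 13/15
sdc <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) || !setequal(names(a), names(b)))
    stop("a and b must be named over the same route set")
  b <- b[names(a)]
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  tot <- sum(a) + sum(b)
  if (tot == 0) stop("sdc is undefined for two all-zero vectors")
  2 * sum(pmin(a, b)) / tot
}

# per-interval per-route counts; resolution "route" pools ODs (3 columns),
# "od" keeps the expressway split by group (4 columns)
interval_counts <- function(log, routes, resolution = c("route", "od")) {
  resolution <- match.arg(resolution)
  key <- interaction(log$day, log$interval, drop = TRUE, lex.order = TRUE)
  f_route <- factor(log$route, levels = routes)
  if (resolution == "route") {
    m <- table(key, f_route)
  } else {
    m <- table(key, interaction(log$od_group, f_route, lex.order = TRUE))
  }
  ord <- order(vapply(strsplit(levels(key), ".", fixed = TRUE),
                      function(p) as.integer(p[1]) * 1e6 + as.integer(p[2]),
                      numeric(1)))
  m[ord, , drop = FALSE]
}

#' Convergence of a trial toward user equilibrium and system optimum
#'
#' For every decision interval, computes the Sorensen-Dice coefficient of
#' the realized route-count vector against the UE reference (UESDC) and the
#' SO reference (SOSDC) of the network. Counts are aggregated over OD groups
#' into 3-component route vectors (the headline convention); set
#' `resolution = "od"` for the 4-component OD-resolved variant.
#'
#' @param log A `trial_log`.
#' @param network The [network_config()] the trial was played on.
#' @param daily If `TRUE`, average the per-interval coefficients within each
#'   day (one value per day).
#' @param resolution `"route"` (default) or `"od"`.
#' @return Data frame `day`, `interval` (dropped when `daily`), `uesdc`,
#'   `sosdc`.
#' @export
convergence_series <- function(log, network, daily = FALSE,
                               resolution = c("route", "od")) {
  resolution <- match.arg(resolution)
  ue <- solve_user_equilibrium(network)
  if (!length(ue)) stop("network has no pure user equilibrium")
  ue <- ue[[1]]$assignment
  so <- solve_system_optimum(network)$assignment
  ref <- function(a) {
    if (resolution == "route") route_totals(a)
    else {
      v <- as.vector(t(a)); names(v) <- as.vector(outer(
        colnames(a), rownames(a), function(r, o) paste(o, r, sep = ".")))
      v
    }
  }
  ue_ref <- ref(ue); so_ref <- ref(so)
  counts <- interval_counts(log, names(network$routes), resolution)
  if (resolution == "od") {
    ue_ref <- ue_ref[colnames(counts)]
    so_ref <- so_ref[colnames(counts)]
  }
  n <- nrow(counts)
  uesdc <- sosdc <- numeric(n)
  for (i in seq_len(n)) {
    v <- setNames(as.numeric(counts[i, ]), colnames(counts))
    uesdc[i] <- sdc(v, ue_ref)
    sosdc[i] <- sdc(v, so_ref)
  }
  h <- attr(log, "horizon")
  K <- h[["intervals"]]
  out <- data.frame(day = (seq_len(n) - 1L) %/% K + 1L,
                    interval = (seq_len(n) - 1L) %% K + 1L,
                    uesdc = uesdc, sosdc = sosdc)
  if (daily) {
    out <- aggregate(cbind(uesdc, sosdc) ~ day, data = out, FUN = mean)
  }
  out
}

#' Trailing moving average with prefix partial windows
#'
#' Point `i` is the mean of the last `min(i, window)` values: before a full
#' window is available the mean of the prefix is used, so the output has the
#' same length as the input.
#'
#' @param x Numeric series.
#' @param window Positive integer window, at most `length(x)`.
#' @return Numeric series of the same length.
#' @export
#' @examples
#' moving_average(c(1, 2, 3, 4), 2) # 1.0 1.5 2.5 3.5
moving_average <- function(x, window) {
  if (window < 1) stop("window must be >= 1")
  if (window > length(x)) stop("window exceeds series length")
  cs <- cumsum(x)
  n <- seq_along(x)
  lag <- c(rep(0, window), cs[seq_len(length(x) - window)])
  (cs - lag) / pmin(n, window)
}

#' Route-switch statistics
#'
#' A switch is a record with `switched = TRUE` (the route differs from the
#' agent's route in the immediately preceding interval, including across day
#' boundaries); it is attributed to the day of the later interval.
#'
#' @param log A `trial_log`.
#' @return List with `per_agent_day` (agent x day switch counts),
#'   `per_day_mean` (population mean switches per day), and `per_agent`
#'   (total switches and mean daily switch frequency per agent).
#' @export
switch_stats <- function(log) {
  df <- as.data.frame(log)
  df$sw <- as.numeric(df$switched)
  per_agent_day <- aggregate(sw ~ agent_id + day, data = df, FUN = sum)
  names(per_agent_day)[3] <- "switches"
  per_day_mean <- aggregate(switches ~ day, data = per_agent_day, FUN = mean)
  names(per_day_mean)[2] <- "mean_switches"
  D <- max(df$day)
  per_agent <- aggregate(switches ~ agent_id, data = per_agent_day, FUN = sum)
  names(per_agent)[2] <- "total_switches"
  per_agent$daily_mean <- per_agent$total_switches / D
  list(per_agent_day = per_agent_day[order(per_agent_day$agent_id,
                                           per_agent_day$day), ],
       per_day_mean = per_day_mean[order(per_day_mean$day), ],
       per_agent = per_agent[order(per_agent$agent_id), ])
}

#' Regression of travel cost on switching frequency
#'
#' Ordinary least squares of per-agent mean daily travel cost on per-agent
#' total number of switches, one point per agent. A positive slope indicates
#' that frequent switchers incur higher costs (network instability).
#'
#' @param log A `trial_log` with at least 3 agents.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (slope
#'   t-test), `n` and the underlying `lm` fit.
#' @export
cost_switch_regression <- function(log) {
  costs <- daily_agent_cost(log)
  mean_cost <- aggregate(daily_cost ~ agent_id, data = costs, FUN = mean)
  sw <- switch_stats(log)$per_agent
  df <- merge(mean_cost, sw, by = "agent_id")
  if (nrow(df) < 3L) stop("regression needs at least 3 agents")
  if (stats::var(df$total_switches) == 0)
    stop("switch counts have zero variance; regression is degenerate")
  fit <- lm(daily_cost ~ total_switches, data = df)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(s$coefficients[2, 4]),
       n = nrow(df), fit = fit)
}

#' Route occupancy series
#'
#' Per-(day, interval) user counts with OD resolution retained, daily means
#' per route, and mean occupancies over the final intervals of the trial
#' (for comparison against the UE and SO points).
#'
#' @param log A `trial_log`.
#' @param last_n Number of final intervals summarized in `last_mean`
#'   (default 10).
#' @return List with `per_interval` (day, interval, od_group, route, count),
#'   `daily_route_mean` (day, route, mean count pooled over ODs) and
#'   `last_mean` (od_group, route, mean count over the last `last_n`
#'   intervals).
#' @export
occupancy_series <- function(log, last_n = 10L) {
  df <- as.data.frame(log)
  df$n <- 1
  per <- aggregate(n ~ day + interval + od_group + route, data = df,
                   FUN = sum)
  names(per)[5] <- "count"
  per <- per[order(per$day, per$interval, per$od_group, per$route), ]
  rownames(per) <- NULL
  h <- attr(log, "horizon")
  K <- h[["intervals"]]
  per$t <- (per$day - 1L) * K + per$interval
  daily <- aggregate(count ~ day + route, data = per, FUN = sum)
  daily$mean_count <- daily$count / K
  daily$count <- NULL
  t_max <- max(per$t)
  tail_df <- per[per$t > t_max - last_n, ]
  last_mean <- aggregate(count ~ od_group + route, data = tail_df,
                         FUN = function(x) sum(x) / last_n)
  names(last_mean)[3] <- "mean_count"
  per$t <- NULL
  list(per_interval = per, daily_route_mean = daily, last_mean = last_mean)
}
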