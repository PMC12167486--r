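#' Extract conditional switch/stay transition events for one agent
#'
#' Every interval after the first in the window yields one event. Its
#' condition compares the previous interval's travel times of the agent's
#' two menu routes (recomputed from the log's own per-route occupancies):
#' `prev_on_worse` when the agent sat on the route with the longer time,
#' `prev_on_better` when on the shorter, `tie` on exact equality. The action
#' is `switch` when the agent's route differs from its previous-interval
#' route. Only intervals inside `window` are used, so classification is
#' invariant to records outside it.
#'
#' @param log A `trial_log`.
#' @param network The [network_config()] of the trial (needed to price the
#'   route the agent did not take).
#' @param agent_id Agent to extract.
#' @param window Integer vector of global interval indices (1 .. days *
#'   intervals), e.g. `1:40`.
#' @return Data frame `agent_id`, `t`, `day`, `interval`, `condition`,
#'   `action`.
#' @export
extract_events <- function(log, network, agent_id, window = NULL) {
  h <- attr(log, "horizon")
  n_int <- h[["days"]] * h[["intervals"]]
  if (is.null(window)) window <- seq_len(n_int)
  if (!length(window)) stop("window must be a non-empty interval range")
  window <- sort(unique(as.integer(window)))
  if (min(window) < 1L || max(window) > n_int)
    stop("window outside the trial horizon")
  t_all <- global_interval(log)
  mine <- log[log$agent_id == agent_id, ]
  if (!nrow(mine)) stop("agent not present in log: ", agent_id)
  t_mine <- t_all[log$agent_id == agent_id]
  mine <- mine[order(t_mine), ]
  menu <- network$od_menu[[mine$od_group[1]]]

  # per-interval cost of each menu route, from each slice's own occupancies
  totals <- table(factor(t_all, levels = seq_len(n_int)),
                  factor(log$route, levels = names(network$routes)))
  menu_costs <- vapply(menu, function(id)
    bpr_cost(network$routes[[id]], as.integer(totals[, id])), numeric(n_int))
  steps <- window[-1]
  cond <- action <- character(length(steps))
  for (k in seq_along(steps)) {
    t <- steps[k]
    prev <- window[k]  # the preceding window element
    own_prev <- mine$route[prev]
    own_cost <- menu_costs[prev, own_prev]
    alt_cost <- menu_costs[prev, menu[menu != own_prev]]
    cond[k] <- if (own_cost > alt_cost) "prev_on_worse"
               else if (own_cost < alt_cost) "prev_on_better"
               else "tie"
    action[k] <- if (mine$route[t] != own_prev) "switch" else "stay"
  }
  data.frame(agent_id = agent_id, t = steps,
             day = (steps - 1L) %/% h[["intervals"]] + 1L,
             interval = (steps - 1L) %% h[["intervals"]] + 1L,
             condition = cond, action = action, stringsAsFactors = FALSE)
}

#' Estimate the conditional switch/stay probability vector
#'
#' `c_minus` is the fraction of `prev_on_worse` events where the agent
#' switched (to the previously cheaper route); `s_minus` the fraction of
#' `prev_on_better` events where it stayed. By construction the complements
#' satisfy `C- + S+ = C+ + S- = 1`. Tie events carry no weight. A condition
#' that never occurred gives no evidence of switching, so its component is
#' imputed to the non-switching value (`c_minus = 0` when no worse-route
#' events; `s_minus = 1` when no better-route events) and flagged.
#'
#' @param events Event data frame from [extract_events()] (one agent).
#' @return An object of class `type_vector`: list with `c_minus`, `s_minus`,
#'   `n_worse`, `n_better`, `imputed_c`, `imputed_s`.
#' @export
estimate_type_vector <- function(events) {
  worse <- events[events$condition == "prev_on_worse", ]
  better <- events[events$condition == "prev_on_better", ]
  n_worse <- nrow(worse)
  n_better <- nrow(better)
  imputed_c <- n_worse == 0L
  imputed_s <- n_better == 0L
  c_minus <- if (imputed_c) 0 else mean(worse$action == "switch")
  s_minus <- if (imputed_s) 1 else mean(better$action == "stay")
  structure(list(c_minus = c_minus, s_minus = s_minus,
                 n_worse = n_worse, n_better = n_better,
                 imputed_c = imputed_c, imputed_s = imputed_s),
            class = "type_vector")
}

#' @export
print.type_vector <- function(x, ...) {
  cat(sprintf("type vector (C-, S-) = (%.3f, %.3f)  [n_worse=%d, n_better=%d%s]\n",
              x$c_minus, x$s_minus, x$n_worse, x$n_better,
              if (x$imputed_c || x$imputed_s) ", imputed" else ""))
  invisible(x)
}

type_labels <- c("status_quo", "naive", "strategic", "exploratory")

#' Classify a type vector into one of four decision types
#'
#' Nearest vertex in Euclidean distance on the `(C-, S-)` plane among
#' naive `(1,1)`, strategic `(0,0)`, exploratory `(1,0)` and status quo
#' `(0,1)`. Distance ties are broken in the fixed order status_quo, naive,
#' strategic, exploratory (so the fully ambiguous `(0.5, 0.5)` is labelled
#' status_quo).
#'
#' @param vector A `type_vector` (or a list with `c_minus`, `s_minus`).
#' @return List with `label` and `distance` (to the chosen vertex).
#' @export
classify_type <- function(vector) {
  p <- c(vector$c_minus, vector$s_minus)
  d <- vapply(type_labels, function(l) {
    v <- archetype_vertices[[l]]
    sqrt(sum((p - v)^2))
  }, numeric(1))
  best <- type_labels[which.min(d)]  # which.min keeps the first on ties
  list(label = best, distance = unname(min(d)))
}

#' Classify every agent within analysis windows
#'
#' Runs [extract_events()], [estimate_type_vector()] and [classify_type()]
#' per agent per window, and tabulates the proportion of each decision type
#' in each window (proportions sum to 1).
#'
#' @param log A `trial_log`.
#' @param network The [network_config()] of the trial.
#' @param windows Named list of interval-index windows, e.g.
#'   `list(early = 1:40, late = 121:160)` (the early/late convention for a
#'   40-day, 4-interval trial).
#' @return List with `agents` (agent_id, window, c_minus, s_minus, n_worse,
#'   n_better, imputed flags, label) and `proportions` (window x type).
#' @export
windowed_type_table <- function(log, network,
                                windows = list(early = 1:40,
                                               late = 121:160)) {
  if (is.null(names(windows)))
    names(windows) <- paste0("w", seq_along(windows))
  ids <- sort(unique(log$agent_id))
  rows <- list()
  for (w in names(windows))
    for (id in ids) {
      ev <- extract_events(log, network, id, windows[[w]])
      tv <- estimate_type_vector(ev)
      cl <- classify_type(tv)
      rows[[length(rows) + 1L]] <- data.frame(
        agent_id = id, window = w, c_minus = tv$c_minus,
        s_minus = tv$s_minus, n_worse = tv$n_worse, n_better = tv$n_better,
        imputed_c = tv$imputed_c, imputed_s = tv$imputed_s,
        label = cl$label, stringsAsFactors = FALSE)
    }
  agents <- do.call(rbind, rows)
  props <- do.call(rbind, lapply(names(windows), function(w) {
    lab <- factor(agents$label[agents$window == w], levels = type_labels)
    p <- as.numeric(table(lab)) / length(lab)
    data.frame(window = w, type = type_labels, proportion = p,
               stringsAsFactors = FALSE)
  }))
  list(agents = agents, proportions = props)
}
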