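#' Specify a synthetic agent population
#'
#' A population is a planted mixture of the four decision-type archetypes
#' with a common behavioral noise level. Proportions are converted to
#' integer counts by largest-remainder rounding at generation time.
#'
#' @param mix Named numeric vector of proportions over
#'   `c("status_quo", "naive", "strategic", "exploratory")` (missing types
#'   count as 0); must sum to 1.
#' @param noise_eps Symmetric action-flip noise in `[0, 0.5)` applied to all
#'   archetype agents.
#' @param n_agents Total population size (default 15).
#' @param od_split Named integer vector of agents per OD group (default
#'   `c(OD1 = 9, OD2 = 6)`); must sum to `n_agents`.
#' @param seed Integer seed recorded in manifests.
#' @return An object of class `population_spec`.
#' @export
#' @examples
#' population_spec(c(status_quo = 0.4, naive = 0.227,
#'                   strategic = 0.173, exploratory = 0.2), noise_eps = 0.05)
population_spec <- function(mix, noise_eps = 0, n_agents = 15L,
                            od_split = c(OD1 = 9L, OD2 = 6L), seed = 1L) {
  full <- setNames(rep(0, length(type_labels)), type_labels)
  if (is.null(names(mix)) || !all(names(mix) %in% type_labels))
    stop("mix must be named over the four decision types")
  if (any(mix < 0)) stop("mix proportions must be non-negative")
  full[names(mix)] <- mix
  if (abs(sum(full) - 1) > 1e-8) stop("mix proportions must sum to 1")
  if (sum(od_split) != n_agents) stop("od_split must sum to n_agents")
  if (noise_eps < 0 || noise_eps >= 0.5) stop("noise_eps must be in [0, 0.5)")
  structure(list(mix = full, noise_eps = noise_eps,
                 n_agents = as.integer(n_agents),
                 od_split = setNames(as.integer(od_split), names(od_split)),
                 seed = as.integer(seed)),
            class = "population_spec")
}

# largest-remainder (Hamilton) apportionment of n among proportions p;
# remainder ties resolved in the fixed type_labels order
largest_remainder <- function(p, n) {
  quota <- p * n
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    rem <- quota - counts
    ord <- order(-rem, seq_along(p))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Generate an archetype roster with its ground-truth manifest
#'
#' Type counts come from deterministic largest-remainder rounding of the
#' mixture; types are laid out over agents in the fixed label order and
#' agents are assigned to OD groups by id order (the first `od_split[1]`
#' agents to the first group, and so on). The manifest records everything
#' needed to score a recovery experiment.
#'
#' @param spec A [population_spec()].
#' @return List with `roster` (list of [agent_spec()]) and `manifest`
#'   (data frame: agent_id, od_group, label, c_minus, s_minus, eps, seed).
#' @export
generate_roster <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  counts <- largest_remainder(spec$mix, spec$n_agents)
  labels <- rep(names(spec$mix), counts)
  ods <- rep(names(spec$od_split), spec$od_split)
  ids <- sprintf("A%02d", seq_len(spec$n_agents))
  roster <- vector("list", spec$n_agents)
  man <- vector("list", spec$n_agents)
  for (i in seq_len(spec$n_agents)) {
    v <- archetype_vertices[[labels[i]]]
    roster[[i]] <- archetype_agent(ids[i], ods[i], type = labels[i],
                                   eps = spec$noise_eps)
    man[[i]] <- data.frame(agent_id = ids[i], od_group = ods[i],
                           label = labels[i], c_minus = v[1], s_minus = v[2],
                           eps = spec$noise_eps, seed = spec$seed,
                           stringsAsFactors = FALSE)
  }
  list(roster = roster, manifest = do.call(rbind, man))
}

#' Generate a batch of synthetic trials
#'
#' Runs the game engine `n_trials` times on independent sub-seeds drawn
#' deterministically from `seed`. The manifest records the planted types and
#' every sub-seed, so the whole batch is reproducible byte-for-byte.
#'
#' @param network A [network_config()].
#' @param spec A [population_spec()] compatible with the network demands.
#' @param n_trials Number of trials.
#' @param seed Master seed.
#' @param days,intervals Horizon per trial.
#' @return List with `logs` (list of `trial_log`) and `manifest` (list with
#'   `agents` data frame, `trial_seeds`, `config_digest`).
#' @export
generate_trials <- function(network, spec, n_trials, seed = spec$seed,
                            days = 40L, intervals = 4L) {
  ros <- generate_roster(spec)
  trial_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            n_trials))
  logs <- vector("list", n_trials)
  for (i in seq_len(n_trials))
    logs[[i]] <- run_trial(network, ros$roster, days = days,
                           intervals = intervals, seed = trial_seeds[i],
                           trial_id = sprintf("S%03d", i))
  list(logs = logs,
       manifest = list(agents = ros$manifest, trial_seeds = trial_seeds,
                       master_seed = seed,
                       config_digest = config_digest(network)))
}

#' Parameter-recovery experiment for the decision-type classifier
#'
#' Generates trials from a planted mixture, classifies every agent in every
#' trial over the given interval window, and scores the labels against the
#' manifest.
#'
#' @param network A [network_config()].
#' @param spec A [population_spec()].
#' @param n_trials Number of independent trials.
#' @param window Interval-index window used for classification (default the
#'   full horizon).
#' @param seed Master seed.
#' @param days,intervals Horizon per trial.
#' @return List with `confusion` (planted x predicted counts), `accuracy`,
#'   `per_type` (precision/recall per planted type) and `agents` (long
#'   per-trial classification table).
#' @export
#' @examples
#' \donttest{
#' net <- canonical_network()
#' spec <- population_spec(c(status_quo = 0.4, naive = 0.2, strategic = 0.2,
#'                           exploratory = 0.2))
#' recovery_experiment(net, spec, n_trials = 1, seed = 7)$accuracy
#' }
recovery_experiment <- function(network, spec, n_trials, window = NULL,
                                seed = spec$seed, days = 40L,
                                intervals = 4L) {
  gen <- generate_trials(network, spec, n_trials, seed = seed, days = days,
                         intervals = intervals)
  planted <- setNames(gen$manifest$agents$label, gen$manifest$agents$agent_id)
  rows <- list()
  for (i in seq_along(gen$logs)) {
    log <- gen$logs[[i]]
    wname <- "recovery"
    wlist <- list(window %||% seq_len(days * intervals))
    names(wlist) <- wname
    cls <- windowed_type_table(log, network, wlist)$agents
    cls$trial <- i
    cls$planted <- planted[cls$agent_id]
    rows[[i]] <- cls
  }
  agents <- do.call(rbind, rows)
  confusion <- table(planted = factor(agents$planted, levels = type_labels),
                     predicted = factor(agents$label, levels = type_labels))
  accuracy <- sum(diag(confusion)) / sum(confusion)
  per_type <- data.frame(
    type = type_labels,
    recall = vapply(type_labels, function(l) {
      n <- sum(confusion[l, ])
      if (n == 0) NA_real_ else confusion[l, l] / n
    }, numeric(1)),
    precision = vapply(type_labels, function(l) {
      n <- sum(confusion[, l])
      if (n == 0) NA_real_ else confusion[l, l] / n
    }, numeric(1)),
    row.names = NULL)
  list(confusion = confusion, accuracy = accuracy, per_type = per_type,
       agents = agents)
}
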