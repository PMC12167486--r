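#' Agent specifications
#'
#' An agent couples an identifier and OD membership with a decision policy.
#' Available policies:
#' \describe{
#'   \item{fixed}{always plays a pinned route.}
#'   \item{archetype}{win-stay/lose-shift behavior parameterised by the
#'     conditional switch probabilities `(c_minus, s_minus)` plus a symmetric
#'     action-flip noise `eps` (see [archetype_policy()]).}
#'   \item{best_response}{inertial best response: switches (with probability
#'     `p_act`) only when joining the other route would have been strictly
#'     cheaper in the previous interval, evaluating the move at destination
#'     occupancy plus one.}
#'   \item{rl}{frozen greedy actor-critic policy from [rl_pretrain()].}
#'   \item{llm}{text-protocol adapter: renders the observation as a feedback
#'     message, queries a response provider, and parses a route name.}
#' }
#'
#' @param agent_id Character identifier.
#' @param od_group OD-group identifier (e.g. `"OD1"`).
#' @param policy One of `"fixed"`, `"archetype"`, `"best_response"`, `"rl"`,
#'   `"llm"`.
#' @param params Policy-specific parameter list.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(agent_id, od_group,
                       policy = c("fixed", "archetype", "best_response",
                                  "rl", "llm"),
                       params = list()) {
  policy <- match.arg(policy)
  if (policy == "fixed" && is.null(params$route))
    stop("fixed policy requires params$route")
  if (policy == "archetype") {
    stopifnot(!is.null(params$c_minus), !is.null(params$s_minus))
    eps <- params$eps %||% 0
    if (params$c_minus < 0 || params$c_minus > 1 ||
        params$s_minus < 0 || params$s_minus > 1)
      stop("archetype probabilities must lie in [0, 1]")
    if (eps < 0 || eps >= 0.5)
      stop("archetype noise eps must lie in [0, 0.5)")
    params$eps <- eps
  }
  structure(list(agent_id = agent_id, od_group = od_group, policy = policy,
                 params = params),
            class = "agent_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname agent_spec
#' @param route Pinned route id (must be on the OD menu).
#' @export
fixed_agent <- function(agent_id, od_group, route)
  agent_spec(agent_id, od_group, "fixed", list(route = route))

#' @rdname agent_spec
#' @param type Archetype label (`"naive"`, `"strategic"`, `"exploratory"`,
#'   `"status_quo"`) or `NULL` when `c_minus`/`s_minus` are given directly.
#' @param c_minus,s_minus Conditional probabilities of switching off the
#'   worse route and of staying on the better route.
#' @param eps Symmetric action-flip noise probability in `[0, 0.5)`.
#' @export
archetype_agent <- function(agent_id, od_group, type = NULL,
                            c_minus = NULL, s_minus = NULL, eps = 0) {
  if (!is.null(type)) {
    v <- archetype_vertices[[match.arg(type, names(archetype_vertices))]]
    c_minus <- v[1]; s_minus <- v[2]
  }
  agent_spec(agent_id, od_group, "archetype",
             list(c_minus = c_minus, s_minus = s_minus, eps = eps,
                  type = type))
}

# (C-, S-) vertices of the four decision-type archetypes
archetype_vertices <- list(
  naive = c(1, 1), strategic = c(0, 0),
  exploratory = c(1, 0), status_quo = c(0, 1))

#' @rdname agent_spec
#' @param network Network used to evaluate anticipated deviation costs.
#' @param p_act Probability of acting on a profitable deviation (behavioral
#'   inertia; 1 = immediate, deterministic reaction).
#' @export
best_response_agent <- function(agent_id, od_group, network, p_act = 0.5)
  agent_spec(agent_id, od_group, "best_response",
             list(network = network, p_act = p_act))

#' @rdname agent_spec
#' @param policy_obj A frozen `rl_policy` from [rl_pretrain()].
#' @export
rl_agent <- function(agent_id, od_group, policy_obj)
  agent_spec(agent_id, od_group, "rl", list(policy = policy_obj))

#' @rdname agent_spec
#' @param responder Function `function(prompt)` returning a character
#'   response naming a route (a live or mock language-model backend).
#' @export
llm_agent <- function(agent_id, od_group, responder)
  agent_spec(agent_id, od_group, "llm", list(responder = responder))

#' Query an agent for its route choice
#'
#' Uniform protocol used by [run_trial()]: given the observation of the
#' previous interval, return a route id on the agent's OD menu. Stochastic
#' policies draw from the global RNG, so choices are reproducible under
#' [run_trial()]'s seed.
#'
#' @param spec An [agent_spec()].
#' @param obs An observation as built by the engine.
#' @return A route id.
#' @export
act <- function(spec, obs) {
  switch(spec$policy,
    fixed = spec$params$route,
    archetype = archetype_policy(spec$params$c_minus, spec$params$s_minus,
                                 spec$params$eps, obs),
    best_response = best_response_policy(spec$params$network,
                                         spec$params$p_act, obs),
    rl = rl_act(spec$params$policy, obs),
    llm = llm_adapter(spec$params$responder, obs),
    stop("unknown policy: ", spec$policy))
}

obs_menu <- function(obs) c(obs$local_route, "Expressway")

obs_other <- function(obs, route) {
  menu <- obs_menu(obs)
  menu[menu != route]
}

obs_route_cost <- function(obs, route)
  if (route == obs$local_route) obs$cost_local_prev else obs$cost_expwy_prev

obs_route_count <- function(obs, route)
  if (route == obs$local_route) obs$n_local_prev else obs$n_expwy_prev

#' Win-stay/lose-shift archetype policy
#'
#' If the agent's previous route had the longer previous-interval travel
#' time of its two menu routes (it sat on the "worse" route), it switches
#' with probability `c_minus`; if it sat on the "better" route it stays with
#' probability `s_minus`. Exact cost ties mean "neither worse nor better":
#' the agent stays. The realized action is then flipped with probability
#' `eps`. With no history the choice is uniform on the menu.
#'
#' The four pure vertices are naive `(1,1)` (always the previously cheaper
#' route), strategic `(0,0)` (always the previously costlier route),
#' exploratory `(1,0)` (switch every interval) and status quo `(0,1)`
#' (never switch).
#'
#' @param c_minus,s_minus Conditional probabilities in `[0, 1]`.
#' @param eps Flip noise in `[0, 0.5)`.
#' @param obs Observation.
#' @return A route id.
#' @export
archetype_policy <- function(c_minus, s_minus, eps, obs) {
  menu <- obs_menu(obs)
  if (!obs$has_history) return(sample(menu, 1L))
  own <- obs$own_prev_route
  alt <- obs_other(obs, own)
  own_cost <- obs_route_cost(obs, own)
  alt_cost <- obs_route_cost(obs, alt)
  p_switch <- if (own_cost > alt_cost) c_minus
              else if (own_cost < alt_cost) 1 - s_minus
              else 0
  route <- if (runif(1) < p_switch) alt else own
  if (eps > 0 && runif(1) < eps) route <- obs_other(obs, route)
  route
}

best_response_policy <- function(network, p_act, obs) {
  menu <- obs_menu(obs)
  if (!obs$has_history) return(sample(menu, 1L))
  own <- obs$own_prev_route
  alt <- obs_other(obs, own)
  own_cost <- obs_route_cost(obs, own)
  alt_cost_joined <- bpr_cost(network$routes[[alt]],
                              obs_route_count(obs, alt) + 1L)
  if (alt_cost_joined < own_cost && runif(1) < p_act) alt else own
}

#' Render an observation as a textual feedback message
#'
#' The message mirrors the feedback page a participant sees: previous user
#' counts and travel times on both menu routes, the agent's own previous
#' route, and the interval index.
#'
#' @param obs Observation.
#' @return A character scalar.
#' @export
render_observation_prompt <- function(obs) {
  menu <- obs_menu(obs)
  if (!obs$has_history)
    return(paste0(
      "Decision interval 1 of ", obs$horizon_len, ". No traffic feedback is ",
      "available yet. Choose one route: ", menu[1], " or ", menu[2], ".",
      " Answer with the route name only."))
  paste0(
    "Decision interval ", obs$time_index, " of ", obs$horizon_len,
    ". Last interval: ", menu[1], " carried ", obs$n_local_prev,
    " users (travel time ", sprintf("%.2f", obs$cost_local_prev),
    " min); ", menu[2], " carried ", obs$n_expwy_prev,
    " users (travel time ", sprintf("%.2f", obs$cost_expwy_prev),
    " min). You took ", obs$own_prev_route,
    ". Choose one route: ", menu[1], " or ", menu[2], ".",
    " Answer with the route name only.")
}

parse_route_response <- function(text, menu) {
  hits <- menu[vapply(menu, function(m)
    grepl(m, text, ignore.case = TRUE), logical(1))]
  if (length(hits) == 1L) return(hits)
  # generic "local" / "expressway" wording
  if (length(hits) == 0L) {
    is_local <- grepl("local", text, ignore.case = TRUE)
    is_exp <- grepl("express", text, ignore.case = TRUE)
    if (xor(is_local, is_exp))
      return(if (is_local) menu[menu != "Expressway"] else "Expressway")
  }
  NA_character_
}

#' Text-protocol (LLM) adapter
#'
#' Renders the observation into a prompt, obtains a response from the
#' provider, and parses a route name. An unparseable response triggers one
#' re-ask; a second failure is an error that preserves the transcript.
#'
#' @param responder Function `function(prompt)` returning character text.
#' @param obs Observation.
#' @return A route id.
#' @seealso [mock_responder()], [scripted_responder()]
#' @export
llm_adapter <- function(responder, obs) {
  menu <- obs_menu(obs)
  prompt <- render_observation_prompt(obs)
  transcript <- character()
  for (attempt in 1:2) {
    resp <- responder(prompt)
    transcript <- c(transcript, prompt, resp)
    route <- parse_route_response(resp, menu)
    if (!is.na(route)) return(route)
    prompt <- paste0("Your answer could not be parsed. Reply with exactly ",
                     "one of: ", menu[1], " or ", menu[2], ".")
  }
  stop("llm adapter: unparseable response after retry; transcript:\n",
       paste(transcript, collapse = "\n---\n"))
}

#' Mock response providers for the text-protocol adapter
#'
#' `mock_responder(answer)` always replies with `answer`;
#' `scripted_responder(answers)` replays a fixed sequence of replies, one per
#' call, erroring when exhausted.
#'
#' @param answer,answers Character reply / vector of replies.
#' @return A responder function for [llm_agent()].
#' @export
mock_responder <- function(answer) function(prompt) answer

#' @rdname mock_responder
#' @export
scripted_responder <- function(answers) {
  i <- 0L
  function(prompt) {
    i <<- i + 1L
    if (i > length(answers)) stop("scripted responder exhausted")
    answers[i]
  }
}

#' Build a roster of fixed agents pinned to an assignment
#'
#' Convenience for benchmark logs: creates one fixed agent per user, pinned
#' so that every interval reproduces the given assignment exactly.
#'
#' @param network A [network_config()].
#' @param assignment An [od_assignment()] valid for the network.
#' @return List of [agent_spec()] objects.
#' @export
pinned_roster <- function(network, assignment) {
  validate_assignment(assignment, network)
  roster <- list()
  k <- 0L
  for (od in names(network$od_demands))
    for (r in network$od_menu[[od]])
      for (j in seq_len(assignment[od, r])) {
        k <- k + 1L
        roster[[k]] <- fixed_agent(sprintf("A%02d", k), od, r)
      }
  roster
}

validate_roster <- function(roster, network) {
  stopifnot(length(roster) > 0L,
            all(vapply(roster, inherits, logical(1), "agent_spec")))
  ids <- vapply(roster, `[[`, character(1), "agent_id")
  if (anyDuplicated(ids)) stop("duplicate agent ids in roster")
  ods <- vapply(roster, `[[`, character(1), "od_group")
  tab <- table(factor(ods, levels = names(network$od_demands)))
  for (od in names(network$od_demands))
    if (tab[[od]] != network$od_demands[[od]])
      stop(sprintf("roster has %d %s agents but the network demands %d",
                   tab[[od]], od, network$od_demands[[od]]))
  invisible(roster)
}
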