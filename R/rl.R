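#' Hyperparameters for IA2C pretraining
#'
#' Defaults: two hidden layers of width 64 (tanh) for both actor and
#' critic, Adam with learning rate 3e-4 decayed linearly to 10% over
#' training, discount 0.99, entropy bonus 0.01 annealed linearly to zero
#' over the first 80% of episodes, rewards scaled by 0.01 (reward =
#' -cost/100), and 3000 pretraining episodes of one full trial (160 steps)
#' each.
#'
#' @param learning_rate Adam step size.
#' @param discount Discount factor in `(0, 1]`.
#' @param entropy_coef Initial entropy-bonus coefficient.
#' @param hidden_width Hidden-layer width of both networks.
#' @param pretrain_episodes Number of self-play episodes.
#' @param reward_scale Multiplier applied to the negative travel cost.
#' @param lr_decay_to Final learning rate as a fraction of the initial one.
#' @param entropy_anneal_frac Fraction of training over which the entropy
#'   coefficient is annealed to zero.
#' @return An object of class `rl_hyperparams`.
#' @export
rl_hyperparams <- function(learning_rate = 3e-4, discount = 0.99,
                           entropy_coef = 0.01, hidden_width = 64L,
                           pretrain_episodes = 3000L, reward_scale = 0.01,
                           lr_decay_to = 0.1, entropy_anneal_frac = 0.8) {
  stopifnot(learning_rate > 0, discount > 0, discount <= 1,
            entropy_coef >= 0, hidden_width >= 1, pretrain_episodes >= 0,
            reward_scale > 0, lr_decay_to > 0, lr_decay_to <= 1,
            entropy_anneal_frac > 0)
  structure(list(learning_rate = learning_rate, discount = discount,
                 entropy_coef = entropy_coef,
                 hidden_width = as.integer(hidden_width),
                 pretrain_episodes = as.integer(pretrain_episodes),
                 reward_scale = reward_scale, lr_decay_to = lr_decay_to,
                 entropy_anneal_frac = entropy_anneal_frac),
            class = "rl_hyperparams")
}

# route roles: (OD1 local, shared expressway, OD2 local); the shared route
# is the one on both menus
network_roles <- function(network) {
  ods <- names(network$od_demands)
  shared <- intersect(network$od_menu[[ods[1]]], network$od_menu[[ods[2]]])
  if (length(shared) != 1L)
    stop("network must have exactly one shared route")
  locals <- vapply(ods, function(od)
    setdiff(network$od_menu[[od]], shared), character(1))
  list(shared = shared, locals = locals, ods = ods)
}

#' Pretrain independent actor-critic route-choice policies
#'
#' Runs self-play episodes of the commuting game in which every agent
#' independently maximizes its own discounted return (reward = negative
#' travel cost) by one-step-TD advantage actor-critic. The observation is
#' the previous interval's per-route counts and travel times, the agent's
#' own previous route (one-hot) and the interval index, scaled to roughly
#' unit range. After pretraining the policies are frozen: deployment via
#' [rl_agent()] uses greedy (mode) actions with no further updates.
#'
#' @param network A [network_config()].
#' @param hp An [rl_hyperparams()].
#' @param days,intervals Episode horizon (one episode = one trial).
#' @param seed Integer seed for initialization and exploration.
#' @return List of class `rl_pretraining` with `policies` (one `rl_policy`
#'   per agent, ordered OD1 agents first), `history` (mean per-interval
#'   system travel time per episode) and `hp`.
#' @export
#' @examples
#' \donttest{
#' net <- canonical_network()
#' fit <- rl_pretrain(net, rl_hyperparams(pretrain_episodes = 100), seed = 1)
#' tail(fit$history, 3)
#' }
rl_pretrain <- function(network, hp = rl_hyperparams(), days = 40L,
                        intervals = 4L, seed = 1L) {
  stopifnot(inherits(hp, "rl_hyperparams"))
  roles <- network_roles(network)
  route_list <- lapply(c(roles$locals[1], roles$shared, roles$locals[2]),
                       function(id) {
    r <- network$routes[[id]]
    list(a = r$free_flow_time, alpha = r$alpha, s = r$capacity,
         beta = r$beta)
  })
  od_vec <- rep(seq_along(roles$ods), network$od_demands[roles$ods])
  horizon_len <- as.integer(days * intervals)
  res <- ia2c_train(route_list, as.integer(od_vec),
                    hp$pretrain_episodes, horizon_len, hp$learning_rate,
                    hp$discount, hp$entropy_coef, hp$hidden_width,
                    hp$reward_scale, hp$lr_decay_to, hp$entropy_anneal_frac,
                    as.integer(seed))
  policies <- lapply(seq_along(res$policies), function(i) {
    p <- res$policies[[i]]
    od <- roles$ods[p$od]
    structure(list(W1 = p$W1, b1 = as.numeric(p$b1), W2 = p$W2,
                   b2 = as.numeric(p$b2), W3 = p$W3, b3 = as.numeric(p$b3),
                   od_group = od,
                   demand_od = network$od_demands[[od]],
                   demand_total = sum(network$od_demands),
                   a_local = network$routes[[roles$locals[p$od]]]$free_flow_time,
                   a_expwy = network$routes[[roles$shared]]$free_flow_time,
                   horizon_len = horizon_len),
              class = "rl_policy")
  })
  structure(list(policies = policies, history = res$history, hp = hp,
                 seed = as.integer(seed)),
            class = "rl_pretraining")
}

rl_features <- function(policy, obs) {
  f <- numeric(7)
  if (obs$has_history) {
    f[1] <- obs$n_local_prev / policy$demand_od
    f[2] <- obs$n_expwy_prev / policy$demand_total
    f[3] <- obs$cost_local_prev / policy$a_local
    f[4] <- obs$cost_expwy_prev / policy$a_expwy
    f[5] <- as.numeric(obs$own_prev_route == obs$local_route)
    f[6] <- as.numeric(obs$own_prev_route == "Expressway")
  }
  f[7] <- (obs$time_index - 1) / policy$horizon_len
  f
}

#' Greedy action of a frozen actor-critic policy
#'
#' Returns the mode of the frozen actor's action distribution (no sampling,
#' no parameter updates): the local road when its logit is at least the
#' expressway's, else the expressway.
#'
#' @param policy An `rl_policy` from [rl_pretrain()].
#' @param obs Observation.
#' @return A route id.
#' @export
rl_act <- function(policy, obs) {
  f <- rl_features(policy, obs)
  h1 <- tanh(policy$W1 %*% f + policy$b1)
  h2 <- tanh(policy$W2 %*% h1 + policy$b2)
  z <- policy$W3 %*% h2 + policy$b3
  if (z[1] >= z[2]) obs$local_route else "Expressway"
}

#' Build a deployment roster from pretrained policies
#'
#' @param network A [network_config()].
#' @param pretraining An `rl_pretraining` from [rl_pretrain()].
#' @return List of [agent_spec()] objects (one frozen rl agent per user).
#' @export
rl_roster <- function(network, pretraining) {
  stopifnot(inherits(pretraining, "rl_pretraining"))
  lapply(seq_along(pretraining$policies), function(i) {
    p <- pretraining$policies[[i]]
    rl_agent(sprintf("RL%02d", i), p$od_group, p)
  })
}
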