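#' Define a congestible route
#'
#' A route is described by the parameters of its Bureau of Public Roads (BPR)
#' volume-delay function, `c(n) = a * (1 + alpha * (n / s)^beta)`, together
#' with the set of origin-destination (OD) groups allowed to use it.
#'
#' @param route_id Character scalar naming the route (e.g. `"Local1"`).
#' @param free_flow_time Free-flow travel time `a` in minutes; must be positive.
#' @param capacity Nominal capacity `s` in users; must be positive.
#' @param alpha Dimensionless congestion coefficient, `alpha >= 0`.
#' @param beta Dimensionless congestion exponent, `beta >= 1`.
#' @param accessible_to Character vector of OD-group identifiers that may use
#'   the route.
#'
#' @return An object of class `route_spec`.
#' @seealso [bpr_cost()], [network_config()]
#' @export
#' @examples
#' local1 <- route_spec("Local1", 15, 5, 0.15, 4, "OD1")
#' bpr_cost(local1, 0:5)
route_spec <- function(route_id, free_flow_time, capacity, alpha, beta,
                       accessible_to) {
  stopifnot(is.character(route_id), length(route_id) == 1L)
  if (free_flow_time <= 0) stop("free_flow_time must be > 0")
  if (capacity <= 0) stop("capacity must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  if (beta < 1) stop("beta must be >= 1")
  structure(
    list(route_id = route_id, free_flow_time = free_flow_time,
         capacity = capacity, alpha = alpha, beta = beta,
         accessible_to = as.character(accessible_to)),
    class = "route_spec")
}

#' BPR travel cost of a route at a given occupancy
#'
#' Evaluates the volume-delay function `a * (1 + alpha * (n / s)^beta)`.
#' The cost is strictly increasing in `n` when `alpha > 0` and equals the
#' free-flow time at `n = 0`.
#'
#' @param route A [route_spec()].
#' @param n Non-negative integer occupancy (vectorised).
#'
#' @return Travel time in minutes, same length as `n`.
#' @export
#' @examples
#' expwy <- route_spec("Expressway", 5, 3, 0.075, 4, c("OD1", "OD2"))
#' bpr_cost(expwy, 6) # 11.0
bpr_cost <- function(route, n) {
  stopifnot(inherits(route, "route_spec"))
  if (any(n < 0)) stop("occupancy n must be non-negative")
  route$free_flow_time *
    (1 + route$alpha * (n / route$capacity)^route$beta)
}

#' Assemble a two-OD road network
#'
#' The network holds exactly three routes; each OD group chooses between its
#' own local road and a shared expressway (a two-route menu per group).
#'
#' @param routes List of [route_spec()] objects (exactly 3).
#' @param od_demands Named integer vector of user counts per OD group.
#' @param od_menu Named list mapping each OD group to its ordered pair of
#'   route ids (local road first, expressway second).
#'
#' @return An object of class `network_config`.
#' @seealso [canonical_network()], [read_network_config()]
#' @export
network_config <- function(routes, od_demands, od_menu) {
  stopifnot(length(routes) == 3L,
            all(vapply(routes, inherits, logical(1), "route_spec")))
  ids <- vapply(routes, `[[`, character(1), "route_id")
  if (anyDuplicated(ids)) stop("duplicate route ids")
  names(routes) <- ids
  od_demands <- setNames(as.integer(od_demands), names(od_demands))
  if (any(od_demands < 0)) stop("od_demands must be non-negative")
  if (!setequal(names(od_demands), names(od_menu)))
    stop("od_demands and od_menu must cover the same OD groups")
  od_menu <- od_menu[names(od_demands)]
  for (od in names(od_menu)) {
    menu <- od_menu[[od]]
    if (length(menu) != 2L) stop("each OD menu must have exactly 2 routes")
    if (!all(menu %in% ids)) stop("od_menu refers to unknown routes")
    for (r in menu)
      if (!od %in% routes[[r]]$accessible_to)
        stop(sprintf("route %s is not accessible to %s", r, od))
  }
  structure(list(routes = routes, od_demands = od_demands, od_menu = od_menu),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("Road network:", length(x$routes), "routes,",
      sum(x$od_demands), "users\n")
  for (r in x$routes)
    cat(sprintf("  %-10s a=%g s=%g alpha=%g beta=%g [%s]\n", r$route_id,
                r$free_flow_time, r$capacity, r$alpha, r$beta,
                paste(r$accessible_to, collapse = ",")))
  for (od in names(x$od_demands))
    cat(sprintf("  %s: %d users, menu {%s}\n", od, x$od_demands[[od]],
                paste(x$od_menu[[od]], collapse = ", ")))
  invisible(x)
}

#' The canonical 15-user two-OD network
#'
#' Local roads have BPR parameters a = 15, alpha = 0.15, s = 5, beta = 4;
#' the shared expressway has a = 5, alpha = 0.075, s = 3, beta = 4.
#' Demands are 9 users (OD1, menu Local1/Expressway) and 6 users
#' (OD2, menu Local2/Expressway).
#'
#' @return A [network_config()].
#' @export
#' @examples
#' net <- canonical_network()
#' solve_system_optimum(net)
canonical_network <- function() {
  path <- system.file("extdata", "canonical_network.json",
                      package = "commutegame", mustWork = TRUE)
  read_network_config(path)
}

#' Read / write a network configuration as JSON
#'
#' The JSON schema has keys `routes` (array of objects with `id`, `a`,
#' `alpha`, `s`, `beta`, `accessible_to`), `od_demands` and `od_menu`.
#'
#' @param path File path.
#' @return `read_network_config()` returns a [network_config()];
#'   `write_network_config()` returns `path` invisibly.
#' @export
read_network_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  routes <- lapply(j$routes, function(r)
    route_spec(r$id, r$a, r$s, r$alpha, r$beta, unlist(r$accessible_to)))
  network_config(routes, unlist(j$od_demands),
                 lapply(j$od_menu, unlist))
}

#' @rdname read_network_config
#' @param network A [network_config()] to serialize.
#' @export
write_network_config <- function(network, path) {
  j <- list(
    routes = lapply(unname(network$routes), function(r)
      list(id = r$route_id, a = r$free_flow_time, alpha = r$alpha,
           s = r$capacity, beta = r$beta, accessible_to = r$accessible_to)),
    od_demands = as.list(network$od_demands),
    od_menu = network$od_menu)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# A short human-readable fingerprint of a network configuration, recorded in
# trial logs so an analysis can detect config mismatches.
config_digest <- function(network) {
  parts <- vapply(network$routes, function(r)
    sprintf("%s:%g:%g:%g:%g", r$route_id, r$free_flow_time, r$capacity,
            r$alpha, r$beta), character(1))
  dem <- paste(sprintf("%s=%d", names(network$od_demands),
                       network$od_demands), collapse = ",")
  paste0(paste(parts, collapse = ";"), "|", dem)
}

#' Construct a per-OD route assignment
#'
#' @param counts Integer matrix with one row per OD group and one column per
#'   route (dimnames required): the number of users of each OD group on each
#'   route.
#' @param network Optional [network_config()] to validate against (demand
#'   conservation and menu accessibility).
#'
#' @return An integer matrix of class `od_assignment`.
#' @export
#' @examples
#' net <- canonical_network()
#' ue <- od_assignment(rbind(OD1 = c(Local1 = 4, Expressway = 5, Local2 = 0),
#'                           OD2 = c(Local1 = 0, Expressway = 2, Local2 = 4)),
#'                     net)
#' route_costs(ue, net)
od_assignment <- function(counts, network = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OD-group rownames and route colnames")
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("assignment counts must be non-negative")
  x <- structure(counts, class = c("od_assignment", "matrix"))
  if (!is.null(network)) validate_assignment(x, network)
  x
}

validate_assignment <- function(assignment, network) {
  ods <- names(network$od_demands)
  ids <- names(network$routes)
  if (!setequal(rownames(assignment), ods) ||
      !setequal(colnames(assignment), ids))
    stop("assignment rows/columns do not match the network's ODs/routes")
  for (od in ods) {
    row <- assignment[od, ]
    if (sum(row) != network$od_demands[[od]])
      stop(sprintf("assignment violates demand conservation for %s", od))
    off <- setdiff(ids, network$od_menu[[od]])
    if (any(row[off] != 0))
      stop(sprintf("assignment places %s users on an inaccessible route", od))
  }
  invisible(assignment)
}

# Per-route total occupancies; the expressway pools both OD groups.
route_totals <- function(assignment)
  setNames(as.integer(colSums(assignment)), colnames(assignment))

#' Route costs at an assignment
#'
#' Applies the BPR function to each route's total occupancy. Shared routes
#' (the expressway) pool users across OD groups.
#'
#' @param assignment An [od_assignment()].
#' @param network A [network_config()].
#' @return Named numeric vector of travel times in minutes.
#' @export
route_costs <- function(assignment, network) {
  validate_assignment(assignment, network)
  totals <- route_totals(assignment)[names(network$routes)]
  vapply(names(network$routes), function(id)
    bpr_cost(network$routes[[id]], totals[[id]]), numeric(1))
}

#' Enumerate all integer route assignments
#'
#' With a two-route menu per OD group the search space is the product of
#' `demand + 1` splits per group, ordered lexicographically by each group's
#' count on the first menu route (first OD group slowest).
#'
#' @param network A [network_config()].
#' @return List of [od_assignment()] objects.
#' @export
enumerate_assignments <- function(network) {
  ods <- names(network$od_demands)
  ids <- names(network$routes)
  grids <- lapply(ods, function(od) 0:network$od_demands[[od]])
  # lexicographic: first OD varies slowest
  idx <- expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)[, rev(seq_along(ods)), drop = FALSE]
  names(idx) <- ods
  lapply(seq_len(nrow(idx)), function(i) {
    m <- matrix(0L, nrow = length(ods), ncol = length(ids),
                dimnames = list(ods, ids))
    for (od in ods) {
      menu <- network$od_menu[[od]]
      k <- idx[i, od]
      m[od, menu[1]] <- k
      m[od, menu[2]] <- network$od_demands[[od]] - k
    }
    od_assignment(m)
  })
}

#' Test an assignment for discrete user equilibrium
#'
#' An assignment is a (pure, atomic) user equilibrium when no single user can
#' strictly reduce their own travel time by unilaterally switching to the
#' other route on their menu, the deviation being evaluated at the
#' destination route's occupancy plus one.
#'
#' @param assignment An [od_assignment()].
#' @param network A [network_config()].
#' @return Logical scalar with attribute `"deviations"`: a data frame of
#'   profitable moves (od_group, from, to, cost_now, cost_after), empty when
#'   the assignment is an equilibrium.
#' @export
is_user_equilibrium <- function(assignment, network) {
  validate_assignment(assignment, network)
  totals <- route_totals(assignment)
  dev <- list()
  for (od in names(network$od_demands)) {
    menu <- network$od_menu[[od]]
    for (r in menu) {
      if (assignment[od, r] == 0L) next
      alt <- setdiff(menu, r)
      cost_now <- bpr_cost(network$routes[[r]], totals[[r]])
      cost_after <- bpr_cost(network$routes[[alt]], totals[[alt]] + 1L)
      if (cost_after < cost_now)
        dev[[length(dev) + 1L]] <- data.frame(
          od_group = od, from = r, to = alt,
          cost_now = cost_now, cost_after = cost_after)
    }
  }
  dev <- if (length(dev)) do.call(rbind, dev)
  else data.frame(od_group = character(), from = character(),
                  to = character(), cost_now = numeric(),
                  cost_after = numeric())
  structure(nrow(dev) == 0L, deviations = dev)
}

equilibrium_result <- function(assignment, network, kind, certified) {
  costs <- route_costs(assignment, network)
  totals <- route_totals(assignment)
  total_cost <- sum(totals * costs)
  structure(
    list(assignment = assignment, route_costs = costs,
         route_totals = totals, total_cost = total_cost,
         system_mean_cost = total_cost / sum(totals),
         kind = kind, certified = certified),
    class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("%s state (%scertified)\n", x$kind,
              if (x$certified) "" else "not "))
  for (id in names(x$route_totals))
    cat(sprintf("  %-10s %2d users  %.2f min\n", id,
                x$route_totals[[id]], x$route_costs[[id]]))
  cat(sprintf("  system: %d users, total %.2f, mean %.2f min/user\n",
              sum(x$route_totals), x$total_cost, x$system_mean_cost))
  invisible(x)
}

#' Solve the discrete user equilibrium by exhaustive enumeration
#'
#' Filters [enumerate_assignments()] through [is_user_equilibrium()] and
#' returns every pure equilibrium in enumeration (lexicographic) order.
#' Discrete congestion games may admit several or no pure equilibria; an
#' empty list is returned (with a message) rather than an error.
#'
#' @param network A [network_config()].
#' @return List of `equilibrium_result` objects with `kind = "UE"`.
#' @export
#' @examples
#' solve_user_equilibrium(canonical_network())[[1]]
solve_user_equilibrium <- function(network) {
  hits <- Filter(function(a) isTRUE(is_user_equilibrium(a, network)[1]),
                 enumerate_assignments(network))
  if (!length(hits)) message("no pure-strategy user equilibrium found")
  lapply(hits, equilibrium_result, network = network, kind = "UE",
         certified = TRUE)
}

#' Solve the system optimum by exhaustive enumeration
#'
#' Minimizes total system travel time `sum_j n_j * c_j(n_j)` over every
#' enumerated integer assignment; exact ties keep the lexicographically
#' first assignment.
#'
#' @param network A [network_config()].
#' @return An `equilibrium_result` with `kind = "SO"`.
#' @export
solve_system_optimum <- function(network) {
  best <- NULL
  best_cost <- Inf
  for (a in enumerate_assignments(network)) {
    totals <- route_totals(a)
    costs <- vapply(names(network$routes), function(id)
      bpr_cost(network$routes[[id]], totals[[id]]), numeric(1))
    tc <- sum(totals * costs)
    if (tc < best_cost) {
      best <- a
      best_cost <- tc
    }
  }
  equilibrium_result(best, network, "SO", certified = TRUE)
}
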