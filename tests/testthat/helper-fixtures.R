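# Shared fixtures, built in code.

canon <- canonical_network()

ue_assignment <- function() {
  od_assignment(rbind(OD1 = c(Local1 = 4L, Expressway = 5L, Local2 = 0L),
                      OD2 = c(Local1 = 0L, Expressway = 2L, Local2 = 4L)),
                canon)
}

so_assignment <- function() {
  od_assignment(rbind(OD1 = c(Local1 = 5L, Expressway = 4L, Local2 = 0L),
                      OD2 = c(Local1 = 0L, Expressway = 1L, Local2 = 5L)),
                canon)
}

# plain-formula BPR, independent of the package implementation
bpr_ref <- function(a, alpha, s, beta, n) a * (1 + alpha * (n / s)^beta)

pinned_log <- function(assignment, days = 2L, intervals = 4L, seed = 1L)
  run_trial(canon, pinned_roster(canon, assignment), days = days,
            intervals = intervals, seed = seed)

# build an observation by hand
make_obs <- function(od_group = "OD1", local_route = "Local1",
                     n_local = 4, n_expwy = 7, cost_local = 15.92,
                     cost_expwy = 16.12, own_prev = "Local1",
                     time_index = 2, horizon_len = 160,
                     has_history = TRUE) {
  structure(list(od_group = od_group, local_route = local_route,
                 n_local_prev = n_local, n_expwy_prev = n_expwy,
                 cost_local_prev = cost_local, cost_expwy_prev = cost_expwy,
                 own_prev_route = own_prev, time_index = time_index,
                 horizon_len = horizon_len, has_history = has_history),
            class = "observation")
}
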