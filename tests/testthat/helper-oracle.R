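# Independent numerical oracle for the analytic PK engine: adaptive-step
# ODE integration (deSolve::lsoda) of
#   dC/dt = R(t)/V - k(t) C        (one compartment)
#   dA/dt = ...                    (two compartments, amounts)
# integrated piece by piece between event times so the discontinuous
# forcing functions are exact.  Tolerances are far below the 1e-6
# agreement the engine is checked against.

ode_profile_oracle <- function(params, schedule, times, c0 = 0) {
  grid <- sort(unique(c(breakpoints(schedule), times)))
  inf <- schedule$infusions
  ses <- schedule$sessions
  rate_at <- function(t) {
    if (!nrow(inf)) return(0)
    sum(inf$amount[inf$start < t & t < inf$start + inf$duration] /
          inf$duration[inf$start < t & t < inf$start + inf$duration])
  }
  dial_at <- function(t) {
    if (!nrow(ses)) return(0)
    i <- which(ses$start < t & t < ses$end)
    if (length(i)) ses$clearance_scale[i] else 0
  }
  conc <- numeric(length(grid))
  conc[1] <- c0
  for (j in seq_len(length(grid) - 1L)) {
    mid <- (grid[j] + grid[j + 1L]) / 2
    R <- rate_at(mid)
    k <- (params$cl_residual + params$cl_dialysis * dial_at(mid)) /
      params$v_central
    deriv <- function(t, y, p) list(R / params$v_central - k * y)
    out <- deSolve::lsoda(c(C = conc[j]), times = c(grid[j], grid[j + 1L]),
                          func = deriv, parms = NULL,
                          rtol = 1e-11, atol = 1e-12)
    conc[j + 1L] <- out[nrow(out), "C"]
  }
  conc[match(round(times, 9), round(grid, 9))]
}

ode_profile_oracle_2cmt <- function(params, schedule, times) {
  grid <- sort(unique(c(breakpoints(schedule), times)))
  inf <- schedule$infusions
  ses <- schedule$sessions
  rate_at <- function(t) {
    if (!nrow(inf)) return(0)
    sum(inf$amount[inf$start < t & t < inf$start + inf$duration] /
          inf$duration[inf$start < t & t < inf$start + inf$duration])
  }
  dial_at <- function(t) {
    if (!nrow(ses)) return(0)
    i <- which(ses$start < t & t < ses$end)
    if (length(i)) ses$clearance_scale[i] else 0
  }
  v1 <- params$v_central
  st <- c(A1 = 0, A2 = 0)
  conc <- numeric(length(grid))
  for (j in seq_len(length(grid) - 1L)) {
    mid <- (grid[j] + grid[j + 1L]) / 2
    R <- rate_at(mid)
    ke <- (params$cl_residual + params$cl_dialysis * dial_at(mid)) / v1
    k12 <- params$q_inter / v1
    k21 <- params$q_inter / params$v_peripheral
    deriv <- function(t, y, p) {
      list(c(R - (ke + k12) * y[1] + k21 * y[2],
             k12 * y[1] - k21 * y[2]))
    }
    out <- deSolve::lsoda(st, times = c(grid[j], grid[j + 1L]),
                          func = deriv, parms = NULL,
                          rtol = 1e-11, atol = 1e-12)
    st <- c(A1 = unname(out[nrow(out), "A1"]),
            A2 = unname(out[nrow(out), "A2"]))
    conc[j + 1L] <- st[1] / v1
  }
  conc[match(round(times, 9), round(grid, 9))]
}

# non-pathological random schedule for property tests
random_schedule <- function(horizon = 72) {
  n_inf <- sample(1:4, 1)
  starts <- sort(runif(n_inf, 0, horizon - 3))
  inf <- infusion_events(starts,
                         runif(n_inf, 0.5, 1.5),
                         runif(n_inf, 100, 1500))
  n_ses <- sample(0:2, 1)
  ses <- if (n_ses > 0) {
    s0 <- sort(runif(n_ses, 0, horizon - 5))
    s0 <- s0[c(TRUE, diff(s0) > 5)]          # keep sessions apart
    dialysis_sessions(s0, s0 + runif(length(s0), 2, 4))
  } else dialysis_sessions()
  event_schedule(inf, ses, horizon)
}

random_params <- function() {
  structural_params(cl_residual = runif(1, 0.01, 1),
                    v_central = runif(1, 2, 20),
                    cl_dialysis = runif(1, 0, 3))
}
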