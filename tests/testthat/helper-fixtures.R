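# Shared fixtures, memoized so expensive simulations run once per suite.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

default_sim <- function() memo("sim", simulate_gait(synthetic_gait_spec()))

pinhole_sim <- function() memo("sim_pinhole", simulate_gait(
  synthetic_gait_spec(camera = list(mode = "pinhole", side = "left",
                                    distance = 3.3, height = 1.3,
                                    focal = 495))))

long_sim <- function() memo("sim_long",
                            simulate_gait(synthetic_gait_spec(bout_length = 40)))

sim_scaling <- function(sim = default_sim())
  compute_scaling(sim$truth$tape_px$a, sim$truth$tape_px$b,
                  sim$truth$tape_distance_m)

default_run <- function() memo("run", analyze_pose(default_sim()$pose,
                                                   sim_scaling()))

mocap_run <- function() memo("run_mocap", analyze_markers(default_sim()$markers))

# Tiny trajectory_set builder for hand-made cases: `points` is a named
# list of n x 2 matrices (x, y columns).
make_ts <- function(time, points, rate = 1 / diff(time[1:2]),
                    provenance = "mocap") {
  nm <- names(points)
  x <- sapply(nm, function(p) points[[p]][, 1])
  y <- sapply(nm, function(p) points[[p]][, 2])
  if (is.null(dim(x))) {x <- matrix(x, 1L, dimnames = list(NULL, nm))
                        y <- matrix(y, 1L, dimnames = list(NULL, nm))}
  structure(list(time = time, x = x, y = y, sampling_rate = rate,
                 provenance = provenance),
            class = "trajectory_set")
}

# Exhaustive minimal-cost event pairing (oracle for match_events):
# maximizes the number of within-tolerance pairs, then minimizes the
# summed absolute difference.
brute_match <- function(a, b, tol) {
  best <- list(n = -1L, cost = Inf)
  rec <- function(i, used_b, n_pairs, cost) {
    if (i > length(a)) {
      if (n_pairs > best$n ||
          (n_pairs == best$n && cost < best$cost - 1e-12))
        best <<- list(n = n_pairs, cost = cost)
      return(invisible())
    }
    rec(i + 1L, used_b, n_pairs, cost)
    for (j in seq_along(b))
      if (!used_b[j] && abs(a[i] - b[j]) <= tol) {
        used_b[j] <- TRUE
        rec(i + 1L, used_b, n_pairs + 1L, cost + abs(a[i] - b[j]))
        used_b[j] <- FALSE
      }
  }
  rec(1L, logical(length(b)), 0L, 0)
  best
}

# Independent two-way mean squares via lm/anova (oracle for the ICC path).
anova_ms <- function(x, y) {
  d <- data.frame(value = c(x, y),
                  subject = factor(rep(seq_along(x), 2L)),
                  rater = factor(rep(1:2, each = length(x))))
  tab <- stats::anova(stats::lm(value ~ subject + rater, data = d))
  list(msr = tab["subject", "Mean Sq"], msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}
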