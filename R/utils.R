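#' Numerically stable log-mean-exp
#' @param x Numeric vector of log values.
#' @return `log(mean(exp(x)))` computed without underflow.
#' @keywords internal
logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# Gauss-Legendre nodes/weights on [a, b]; unit-interval rules are cached
# since the same node count is reused thousands of times per fit.
.gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n, a, b) {
  if (b <= a) return(list(x = numeric(0), w = numeric(0)))
  key <- as.character(n)
  g <- .gl_cache[[key]]
  if (is.null(g)) {
    g <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- g
  }
  h <- (b - a) / 2
  list(x = (a + b) / 2 + h * g$x, w = h * g$w)
}

#' Piecewise-linear subject trajectory with dose steps
#'
#' Represents a TTC trajectory \eqn{m(t) = a + b t + s(t)} where \eqn{s(t)}
#' is a left-continuous step function encoding dose-level offsets: value
#' `step_values[j]` applies on `[step_times[j], step_times[j+1])`, with
#' `step_times[1] == 0`.
#'
#' @param intercept,slope Linear part of the trajectory (TTC, TTC/month).
#' @param step_times Non-decreasing change points, starting at 0 (months).
#' @param step_values Offset on each interval (TTC units); same length as
#'   `step_times`.
#' @return An object of class `ttc_trajectory`, callable via [traj_eval()].
#' @export
make_trajectory <- function(intercept, slope, step_times = 0, step_values = 0) {
  stopifnot(length(step_times) == length(step_values),
            length(step_times) >= 1, step_times[1] == 0,
            !is.unsorted(step_times))
  structure(list(intercept = intercept, slope = slope,
                 step_times = as.numeric(step_times),
                 step_values = as.numeric(step_values)),
            class = "ttc_trajectory")
}

#' Evaluate a trajectory at time points
#' @param traj A [make_trajectory()] object.
#' @param t Times (months, >= 0).
#' @return `m(t)`, evaluated left-continuously at change points.
#' @export
traj_eval <- function(traj, t) {
  stopifnot(inherits(traj, "ttc_trajectory"), all(t >= 0))
  idx <- findInterval(t, traj$step_times, left.open = TRUE)
  idx[idx == 0L] <- 1L  # t = 0 belongs to the first interval
  traj$intercept + traj$slope * t + traj$step_values[idx]
}

# Integral of the step component of a trajectory from 0 to each t (closed form).
traj_step_integral <- function(traj, t) {
  st <- traj$step_times
  sv <- traj$step_values
  ends <- c(st[-1], Inf)
  vapply(t, function(ti) {
    len <- pmax(0, pmin(ends, ti) - pmin(st, ti))
    sum(len * sv)
  }, numeric(1))
}

new_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
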