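#' Derive independent per-source seeds from a master seed
#'
#' One master seed spawns a fixed-order set of sub-seeds (TCR, E, I), so
#' that enabling or disabling one noise source never perturbs the stream of
#' another.
#'
#' @param seed master seed
#' @param n number of streams
#' @return integer vector of sub-seeds
#' @export
derive_stream_seeds <- function(seed, n = 3) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Ornstein-Uhlenbeck process at integration resolution
#'
#' Pre-integrates `dx = (mu - x)/tau dt + sigma sqrt(dt) xi` with forward
#' Euler at the grid's `dt`, starting from `x(0) = mu`. The resulting series
#' is inserted into the model equations with zero-order hold. The stationary
#' variance of the exact process is `sigma^2 tau / 2`.
#'
#' @param params an [ou_params()] object
#' @param grid a [sim_grid()] object; `grid$seed` seeds the stream
#' @return numeric vector of length `grid$n_steps`
#' @examples
#' x <- ou_process(ou_params(mu = 1, sigma = 0), sim_grid(100, seed = 1))
#' all(x == 1)
#' @export
ou_process <- function(params, grid) {
  stopifnot(inherits(params, "ou_params"), inherits(grid, "sim_grid"))
  n <- grid$n_steps
  dt <- grid$dt
  if (params$sigma == 0) return(rep(params$mu, n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(grid$seed)
  eps <- rnorm(n) * params$sigma * sqrt(dt)
  a <- 1 - dt / params$tau
  drv <- params$mu * dt / params$tau
  as.numeric(stats::filter(drv + eps, a, method = "recursive",
                           init = params$mu))
}

#' Delay ring buffer
#'
#' Fixed-delay buffer: a value pushed at step `i` is read back exactly
#' `n_steps = round(delay/dt)` steps later. The history is pre-filled with
#' `init`, so a system resting at a fixed point stays there.
#'
#' @param delay delay (ms)
#' @param dt integration step (ms)
#' @param init value the history is filled with
#' @return an object of class `delay_buffer` with `$read()`, `$push(v)`,
#'   and `$n_steps`
#' @export
delay_buffer <- function(delay, dt, init = 0) {
  n_steps <- as.integer(round(delay / dt))
  if (n_steps < 1) stop("delay must be at least one integration step")
  buf <- rep(init, n_steps)
  head <- 1L
  obj <- list(
    n_steps = n_steps,
    read = function() buf[head],
    push = function(v) {
      buf[head] <<- v
      head <<- if (head == n_steps) 1L else head + 1L
      invisible(NULL)
    })
  class(obj) <- "delay_buffer"
  obj
}

#' Forward-Euler integration with optional delayed state access
#'
#' Reference integrator for small systems (the production node models run
#' in compiled code). `rhs(t, state, delayed)` must return the derivative
#' vector; `delayed` is a function `delayed(delay_ms)` returning the full
#' state vector `delay_ms` ago (history before t = 0 equals `state0`).
#'
#' @param rhs derivative callback
#' @param state0 initial state vector
#' @param grid a [sim_grid()]
#' @param delays numeric vector of delays (ms) the rhs may request; access
#'   to other delays is an error
#' @return list with `time` (ms), `state` (matrix, dt resolution),
#'   `time_samp`, `state_samp` (subsampled at `dt_samp`)
#' @export
euler_integrate <- function(rhs, state0, grid, delays = numeric(0)) {
  stopifnot(inherits(grid, "sim_grid"))
  n <- grid$n_steps
  dt <- grid$dt
  d <- length(state0)
  out <- matrix(NA_real_, n + 1, d)
  out[1, ] <- state0
  dsteps <- as.integer(round(delays / dt))
  names(dsteps) <- as.character(delays)
  state <- state0
  for (i in seq_len(n)) {
    delayed <- function(delay_ms) {
      k <- as.integer(round(delay_ms / dt))
      if (!(k %in% dsteps)) stop("delay not declared: ", delay_ms)
      j <- i - k
      if (j < 1) state0 else out[j, ]
    }
    dx <- rhs((i - 1) * dt, state, delayed)
    if (!all(is.finite(dx)))
      stop(sprintf("non-finite derivative at t = %g ms", (i - 1) * dt))
    state <- state + dt * dx
    if (!all(is.finite(state)))
      stop(sprintf("state diverged at t = %g ms", i * dt))
    out[i + 1, ] <- state
  }
  keep <- seq(1 + grid$samp_every, n + 1, by = grid$samp_every)
  list(time = (0:n) * dt, state = out,
       time_samp = (keep - 1) * dt, state_samp = out[keep, , drop = FALSE])
}
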