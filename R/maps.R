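# Chaotic maps used as neuron transfer functions and for generator seeding.
# All maps operate on the open unit interval; every step is passed through
# sanitize_unit() so trajectories can never be captured by the absorbing
# fixed points at 0 and 1.

# Clamp width: 2^-32, well below any statistical resolution used here.
.MAP_EPS <- 2^-32

#' Clamp values into the open unit interval
#'
#' Maps any real value into `[2^-32, 1 - 2^-32]`. Applied after every chaotic
#' map step so that a trajectory landing exactly on 0 or 1 (both fixed points
#' of the maps used here) is nudged back inside instead of dying.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, strictly inside (0, 1).
#' @export
sanitize_unit <- function(x) {
  pmin(pmax(x, .MAP_EPS), 1 - .MAP_EPS)
}

# Valid control-parameter range per map. The cubic map is used at the fixed
# chaotic value 2.59, so its "range" is degenerate.
.map_control_range <- function(map_id) {
  switch(map_id,
    logistic = c(3.58, 4),
    pwlcm    = c(0, 0.5),
    lts      = c(0, 4),
    cubic    = c(2.59, 2.59),
    stop("unknown map id: ", map_id, call. = FALSE)
  )
}

.check_unit <- function(t, name = "T") {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0) || any(t > 1)) {
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  }
}

#' Logistic map step
#'
#' One iteration of the logistic map `T -> G * T * (1 - T)`, chaotic for
#' control values between 3.58 and 4.
#'
#' @param t Current state(s) in `[0, 1]`.
#' @param control Control parameter G, in `[3.58, 4]`.
#' @return Next state(s), sanitized into (0, 1).
#' @examples
#' step_logistic(0.2, 4) # 0.64
#' @export
step_logistic <- function(t, control) {
  .check_unit(t)
  if (any(control < 3.58) || any(control > 4)) {
    stop("logistic control parameter must lie in [3.58, 4]", call. = FALSE)
  }
  sanitize_unit(control * t * (1 - t))
}

#' Piecewise linear chaotic map (PWLCM) step
#'
#' Three-branch piecewise-linear map, symmetric about `T = 0.5`:
#' `T/G` for `T < G`, `(T - G)/(0.5 - G)` for `G <= T < 0.5`, and `F(1 - T)`
#' for `T >= 0.5`. Every branch is linear onto the unit interval, so the map
#' preserves Lebesgue measure: a uniform input stays uniform.
#'
#' @param t Current state(s) in `[0, 1]`.
#' @param control Range-control parameter G, strictly inside (0, 0.5).
#' @return Next state(s), sanitized into (0, 1).
#' @examples
#' step_pwlcm(0.1, 0.25) # 0.4
#' step_pwlcm(0.7, 0.25) # equals step_pwlcm(0.3, 0.25)
#' @export
step_pwlcm <- function(t, control) {
  .check_unit(t)
  if (any(control <= 0) || any(control >= 0.5)) {
    stop("PWLCM control parameter must lie in (0, 0.5)", call. = FALSE)
  }
  t2 <- ifelse(t < 0.5, t, 1 - t)
  sanitize_unit(ifelse(t2 < control, t2 / control, (t2 - control) / (0.5 - control)))
}

#' Logistic-tent system (LTS) step
#'
#' Modular combination of the logistic map and a tent-like term:
#' for `T < 0.5`, `(G*T*(1-T) + (4-G)*T/2) mod 1`; for `T >= 0.5`,
#' `(G*T*(1-T) + (4-G)*(1-T)/2) mod 1`.
#'
#' @param t Current state(s) in `[0, 1]`.
#' @param control Control parameter G, strictly inside (0, 4).
#' @return Next state(s), sanitized into (0, 1).
#' @examples
#' step_lts(0.25, 2) # 0.625
#' @export
step_lts <- function(t, control) {
  .check_unit(t)
  if (any(control <= 0) || any(control >= 4)) {
    stop("LTS control parameter must lie in (0, 4)", call. = FALSE)
  }
  r <- ifelse(
    t < 0.5,
    control * t * (1 - t) + (4 - control) * t / 2,
    control * t * (1 - t) + (4 - control) * (1 - t) / 2
  )
  sanitize_unit(r %% 1)
}

#' Cubic map step
#'
#' One iteration of `T -> lambda * T * (1 - T^2)`; chaotic at the default
#' `lambda = 2.59`, which is the value used to seed the keystream generator.
#'
#' @param t Current state(s) in `[0, 1]`.
#' @param control Control parameter lambda, in `(0, 3*sqrt(3)/2]` so the map
#'   cannot leave the unit interval.
#' @return Next state(s), sanitized into (0, 1).
#' @examples
#' step_cubic(0.5, 2.59) # 0.97125
#' @export
step_cubic <- function(t, control = 2.59) {
  .check_unit(t)
  if (any(control <= 0) || any(control > 3 * sqrt(3) / 2)) {
    stop("cubic control parameter must lie in (0, 3*sqrt(3)/2]", call. = FALSE)
  }
  sanitize_unit(control * t * (1 - t^2))
}

.map_step <- function(map_id, t, control) {
  switch(map_id,
    logistic = step_logistic(t, control),
    pwlcm    = step_pwlcm(t, control),
    lts      = step_lts(t, control),
    cubic    = step_cubic(t, control),
    stop("unknown map id: ", map_id, call. = FALSE)
  )
}

#' Iterate a chaotic map with warm-up discard
#'
#' Applies the chosen map `n` times from `t0` and returns the last
#' `n - discard` states in order. Used with `discard = 50` to run the cubic
#' map past its transient before its outputs are harvested to build the
#' keystream generator.
#'
#' @param map_id One of `"logistic"`, `"pwlcm"`, `"lts"`, `"cubic"`.
#' @param t0 Initial state in `[0, 1]`.
#' @param n Total number of iterations (>= `discard`).
#' @param discard Number of leading states to drop (default 0).
#' @param control Control parameter for the map (default: cubic's 2.59).
#' @return Numeric vector of length `n - discard`, each value in (0, 1).
#' @examples
#' iterate_map("logistic", 0.2, n = 2, control = 4) # 0.64, 0.9216
#' @export
iterate_map <- function(map_id, t0, n, discard = 0, control = 2.59) {
  map_id <- match.arg(map_id, c("logistic", "pwlcm", "lts", "cubic"))
  if (n < 0 || discard < 0 || n < discard) {
    stop("need n >= discard >= 0", call. = FALSE)
  }
  .check_unit(t0, "t0")
  out <- numeric(n)
  t <- t0
  for (i in seq_len(n)) {
    t <- .map_step(map_id, t, control)
    out[i] <- t
  }
  if (discard > 0) out <- out[-seq_len(discard)]
  out
}
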