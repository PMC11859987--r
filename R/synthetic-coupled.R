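# Coupled-process generator: ground truth for the directionality of the
# transfer-entropy estimators. X evolves autonomously; Y is driven by the
# lagged X, so information flows X -> Y by construction.

#' Specify a coupled process pair
#'
#' @param n_steps Series length (>= 50).
#' @param coupling_strength Coupling coefficient `a` in `[0, 1]`; 0 gives two
#'   independent processes.
#' @param lag Driver lag in steps (>= 1, < `n_steps`).
#' @param noise_sd Innovation standard deviation (> 0).
#' @param map_type `"linear_var"` for a linear vector-autoregression,
#'   `"logistic"` for coupled noisy logistic maps (the nonlinear case).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(n_steps = 2000L, coupling_strength = 0.8, lag = 1L,
                          noise_sd = 1, map_type = c("linear_var", "logistic"),
                          seed = 1L) {
  map_type <- match.arg(map_type)
  if (!is_count(n_steps) || n_steps < 50) abort("n_steps must be a count >= 50")
  if (!is_scalar_num(coupling_strength) || coupling_strength < 0 ||
    coupling_strength > 1) {
    abort("coupling_strength must be in [0, 1]")
  }
  if (!is_count(lag) || lag < 1) abort("lag must be an integer >= 1")
  if (lag >= n_steps) abort("lag must be smaller than n_steps")
  if (!is_scalar_num(noise_sd) || noise_sd <= 0) abort("noise_sd must be > 0")
  structure(
    list(
      n_steps = as.integer(n_steps), coupling_strength = coupling_strength,
      lag = as.integer(lag), noise_sd = noise_sd, map_type = map_type,
      seed = as.integer(seed)
    ),
    class = "coupling_spec"
  )
}

#' Generate a driver/response pair with known causal direction
#'
#' For `map_type = "linear_var"`:
#' `x[t] = 0.6 x[t-1] + e_x`, `y[t] = a x[t-lag] + e_y` with independent
#' Gaussian innovations of standard deviation `noise_sd`. For
#' `map_type = "logistic"`: `x[t] = f(x[t-1])`,
#' `y[t] = f((1-a) y[t-1] + a x[t-lag])` with `f(u) = 4u(1-u)` and small
#' truncated Gaussian perturbations keeping the state in `(0, 1)`.
#'
#' @param spec A [coupling_spec()].
#' @return A tibble with columns `t`, `x` (driver) and `y` (response).
#' @examples
#' pair <- gen_coupled_pair(coupling_spec(n_steps = 500, seed = 7))
#' head(pair)
#' @export
gen_coupled_pair <- function(spec) {
  if (!inherits(spec, "coupling_spec")) spec <- do.call(coupling_spec, spec)
  n <- spec$n_steps
  a <- spec$coupling_strength
  lag <- spec$lag
  withr::with_seed(spec$seed, {
    if (spec$map_type == "linear_var") {
      ex <- rnorm(n, sd = spec$noise_sd)
      ey <- rnorm(n, sd = spec$noise_sd)
      x <- numeric(n)
      x[1] <- ex[1]
      for (t in 2:n) x[t] <- 0.6 * x[t - 1] + ex[t]
      y <- ey
      idx <- (lag + 1):n
      y[idx] <- a * x[idx - lag] + ey[idx]
    } else {
      f <- function(u) 4 * u * (1 - u)
      ex <- rnorm(n, sd = 0.01 * spec$noise_sd)
      ey <- rnorm(n, sd = 0.01 * spec$noise_sd)
      clamp <- function(u) pmin(pmax(u, 1e-6), 1 - 1e-6)
      x <- numeric(n)
      y <- numeric(n)
      x[1] <- 0.3
      y[1] <- 0.6
      for (t in 2:n) {
        x[t] <- clamp(f(x[t - 1]) + ex[t])
        xd <- if (t - lag >= 1) x[t - lag] else 0.5
        y[t] <- clamp(f(clamp((1 - a) * y[t - 1] + a * xd)) + ey[t])
      }
    }
  })
  tibble(t = seq_len(n), x = x, y = y)
}
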