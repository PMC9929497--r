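#' Synthetic flock configuration
#'
#' Study-condition defaults for the simulator: 8 birds flying 60 s at 5 Hz
#' and 10 m/s along a smoothly wandering common heading, followers planted at
#' the modelled upwash optimum (lateral +-1.3 m, 0.5 m behind, co-planar)
#' with 0.05 m Gaussian observation noise per axis.
#'
#' @param n_birds Number of birds (>= 2).
#' @param duration Flight duration (s).
#' @param rate_hz Sampling rate (Hz).
#' @param speed Ground speed (m/s).
#' @param heading_sd Heading random-walk step s.d. (rad per sample).
#' @param template Formation: `"echelon"` (single diagonal line), `"V"`
#'   (two arms off an apex bird), `"line"` (alias of echelon), `"cluster"`
#'   (loose 3D blob, no planted leaders) or `"none"` (all solo).
#' @param offset_ew Magnitude (m) of the planted lateral offset of each
#'   follower from its leader (sign set by the template arm).
#' @param offset_ns Planted anteroposterior offset (m, negative = behind).
#' @param offset_ud Planted vertical offset (m).
#' @param noise_sd Gaussian observation noise s.d. per axis (m).
#' @param noise_ar AR(1) coefficient in `[0, 1)` for temporally smooth
#'   (GNSS-like) noise; 0 = white.
#' @param pursuit_gain First-order pursuit gain in `(0, 1]`: each sample a
#'   follower closes this fraction of the gap to its planted slot.
#' @param leader_switch_prob Per-sample probability that a planted follower
#'   redraws its leader uniformly among the other birds.
#' @param solo_fraction Fraction of birds flying solo, far outside any wake
#'   region.
#' @param seed Integer RNG seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_birds = 8, duration = 60, rate_hz = 5, speed = 10,
                       heading_sd = 0.01,
                       template = c("echelon", "V", "line", "cluster",
                                    "none"),
                       offset_ew = 1.3, offset_ns = -0.5, offset_ud = 0,
                       noise_sd = 0.05, noise_ar = 0, pursuit_gain = 1,
                       leader_switch_prob = 0, solo_fraction = 0, seed) {
  template <- match.arg(template)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_birds >= 2, duration > 0, rate_hz > 0, speed > 0,
            heading_sd >= 0, noise_sd >= 0, noise_ar >= 0, noise_ar < 1,
            pursuit_gain > 0, pursuit_gain <= 1,
            leader_switch_prob >= 0, leader_switch_prob <= 1,
            solo_fraction >= 0, solo_fraction <= 1)
  if (offset_ns >= 0) {
    stop("offset_ns must be negative (followers fly behind)", call. = FALSE)
  }
  structure(list(n_birds = as.integer(n_birds), duration = duration,
                 rate_hz = rate_hz, speed = speed, heading_sd = heading_sd,
                 template = template, offset_ew = offset_ew,
                 offset_ns = offset_ns, offset_ud = offset_ud,
                 noise_sd = noise_sd, noise_ar = noise_ar,
                 pursuit_gain = pursuit_gain,
                 leader_switch_prob = leader_switch_prob,
                 solo_fraction = solo_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

# Planted leader and offset side per bird under a template. Bird 1 is the
# apex/lead bird. Returns a list(leader = integer (NA for none), side).
.template_slots <- function(template, n) {
  leader <- rep(NA_integer_, n)
  side <- rep(1, n)
  if (template %in% c("echelon", "line")) {
    if (n >= 2) leader[2:n] <- 1:(n - 1)
  } else if (template == "V") {
    for (i in seq_len(n)[-1]) {
      leader[i] <- if (i <= 3) 1L else i - 2L
      side[i] <- if (i %% 2 == 0) -1 else 1
    }
  }
  list(leader = leader, side = side)
}

#' Simulate a flock with planted wake structure
#'
#' The lead bird flies a heading random walk at constant speed; each planted
#' follower pursues a slot at the configured offset in its current leader's
#' instantaneous flight frame (first-order pursuit), with optional uniform
#' leader re-draws; solo birds fly the common heading far outside any wake
#' region. Gaussian (optionally AR(1)) observation noise is added to every
#' emitted position, so with `noise_sd = 0` and `pursuit_gain = 1` the
#' planted geometry is exact by construction. Fully deterministic given the
#' seed.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_flock`: `positions` (tibble `bird_id`, `t`,
#'   `x`, `y`, `z`), `truth` (tibble `follower`, `t`, `leader`, `NA` when no
#'   planted leader) and `config`.
#' @examples
#' sim <- simulate_flock(sim_config(n_birds = 3, duration = 5, seed = 1))
#' head(sim$positions)
#' @export
simulate_flock <- function(cfg = sim_config(seed = 1)) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, .simulate_flock_impl(cfg))
}

.simulate_flock_impl <- function(cfg) {
  n <- cfg$n_birds
  dt <- 1 / cfg$rate_hz
  steps <- as.integer(round(cfg$duration * cfg$rate_hz)) + 1L
  tvec <- (seq_len(steps) - 1L) * dt
  ids <- sprintf("b%02d", seq_len(n))
  n_solo <- as.integer(round(cfg$solo_fraction * n))
  solo <- if (n_solo > 0) (n - n_solo + 1L):n else integer()
  n_form <- n - n_solo

  slots <- .template_slots(cfg$template, n_form)
  leader_of <- matrix(NA_integer_, nrow = steps, ncol = n)
  if (n_form >= 2 && !cfg$template %in% c("cluster", "none")) {
    for (i in 2:n_form) {
      cur <- slots$leader[i]
      # re-draw pool restricted to already-built birds so chained pursuit
      # stays causally computable; the exact uniform null lives in
      # simulate_null_assignments()
      pool <- seq_len(i - 1L)
      for (s in seq_len(steps)) {
        if (cfg$leader_switch_prob > 0 &&
            stats::runif(1) < cfg$leader_switch_prob) {
          cur <- pool[sample.int(length(pool), 1L)]
        }
        leader_of[s, i] <- cur
      }
    }
  }

  # lead-bird path
  theta <- cumsum(c(stats::runif(1, -pi, pi),
                    stats::rnorm(steps - 1L, 0, cfg$heading_sd)))
  hx <- cos(theta)
  hy <- sin(theta)
  px <- cumsum(c(0, cfg$speed * dt * hx[-steps]))
  py <- cumsum(c(0, cfg$speed * dt * hy[-steps]))
  pz <- rep(100, steps)

  X <- matrix(0, steps, n); Y <- matrix(0, steps, n); Z <- matrix(100, steps, n)
  X[, 1] <- px; Y[, 1] <- py; Z[, 1] <- pz
  HX <- matrix(hx, steps, n); HY <- matrix(hy, steps, n)

  if (cfg$template == "cluster" && n_form >= 2) {
    for (i in 2:n_form) {
      ox <- stats::runif(1, -5, 5); oy <- stats::runif(1, -5, 5)
      oz <- stats::runif(1, -2, 2)
      X[, i] <- px + ox * hy + oy * hx   # lateral/longitudinal in lead frame
      Y[, i] <- py - ox * hx + oy * hy
      Z[, i] <- pz + oz
    }
  } else if (n_form >= 2 && cfg$template != "none") {
    for (i in 2:n_form) {
      ew_i <- slots$side[i] * cfg$offset_ew
      for (s in seq_len(steps)) {
        l <- leader_of[s, i]
        # leader's instantaneous heading (already computed: topological order)
        lhx <- HX[s, l]; lhy <- HY[s, l]
        tx <- X[s, l] + ew_i * lhy + cfg$offset_ns * lhx
        ty <- Y[s, l] - ew_i * lhx + cfg$offset_ns * lhy
        tz <- Z[s, l] - cfg$offset_ud
        if (s == 1L || cfg$pursuit_gain == 1) {
          X[s, i] <- tx; Y[s, i] <- ty; Z[s, i] <- tz
        } else {
          g <- cfg$pursuit_gain
          X[s, i] <- X[s - 1L, i] + g * (tx - X[s - 1L, i])
          Y[s, i] <- Y[s - 1L, i] + g * (ty - Y[s - 1L, i])
          Z[s, i] <- Z[s - 1L, i] + g * (tz - Z[s - 1L, i])
        }
        if (s < steps) {
          dxs <- if (s == 1L) c(lhx, lhy) else
            c(X[s, i] - X[s - 1L, i], Y[s, i] - Y[s - 1L, i])
          nrm <- sqrt(sum(dxs^2))
          if (nrm > 1e-12) {
            HX[s + 1L, i] <- dxs[1] / nrm; HY[s + 1L, i] <- dxs[2] / nrm
          }
        }
      }
    }
  }
  for (k in seq_along(solo)) {
    i <- solo[k]
    off <- 30 + 10 * k
    X[, i] <- px + off * hy
    Y[, i] <- py - off * hx
    Z[, i] <- pz
    leader_of[, i] <- NA_integer_
  }
  if (cfg$template == "none" && n_form >= 2) {
    for (i in 2:n_form) {
      off <- 30 + 10 * i
      X[, i] <- px + off * hy
      Y[, i] <- py - off * hx
    }
  }

  if (cfg$noise_sd > 0) {
    noise <- function() {
      e <- matrix(stats::rnorm(steps * n, 0, cfg$noise_sd), steps, n)
      if (cfg$noise_ar > 0) {
        e <- apply(e, 2, function(col) {
          as.numeric(stats::filter(col, cfg$noise_ar, method = "recursive"))
        }) * sqrt(1 - cfg$noise_ar^2)
      }
      e
    }
    X <- X + noise(); Y <- Y + noise(); Z <- Z + noise()
  }

  positions <- tibble::tibble(
    bird_id = rep(ids, each = steps),
    t = rep(tvec, times = n),
    x = as.numeric(X), y = as.numeric(Y), z = as.numeric(Z)
  )
  truth <- tibble::tibble(
    follower = rep(ids, each = steps),
    t = rep(tvec, times = n),
    leader = ids[as.integer(leader_of)]
  )
  structure(list(positions = positions, truth = truth, config = cfg),
            class = "sim_flock")
}

#' @export
print.sim_flock <- function(x, ...) {
  cat(sprintf("Simulated flock: %d birds, %g s at %g Hz (template %s)\n",
              x$config$n_birds, x$config$duration, x$config$rate_hz,
              x$config$template))
  invisible(x)
}

#' Simulate a flock with no leader preference
#'
#' Every planted follower redraws its leader uniformly among the other birds
#' at a per-sample switch probability, so no leader is preferred in
#' expectation — the planted null for calibrating the preference bootstrap.
#'
#' @param n_birds Number of birds (>= 3).
#' @param duration Flight duration (s).
#' @param switch_prob Per-sample leader re-draw probability.
#' @param seed Integer RNG seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_flock` (see [simulate_flock()]).
#' @export
make_null_preference <- function(n_birds = 8, duration = 60,
                                 switch_prob = 0.1, seed, ...) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_birds >= 3)
  simulate_flock(sim_config(n_birds = n_birds, duration = duration,
                            leader_switch_prob = switch_prob,
                            pursuit_gain = 0.5, seed = seed, ...))
}

#' Null assignment streams for bootstrap calibration
#'
#' Generates per-snapshot in-wake assignment tables directly under the
#' no-preference null: each focal bird's flight is a sequence of in-wake
#' bouts whose lengths are geometric (mean `1/switch_prob` samples) and
#' whose leaders are drawn uniformly from the other birds. This is the exact
#' generative counterpart of the bootstrap null in [leader_preference()],
#' so observed proportions should escape the 95% interval for about 5% of
#' (bird, leader) cells.
#'
#' @param n_birds Flock size (each focal bird chooses among `n_birds - 1`
#'   leaders).
#' @param n_focal Number of independent focal birds to generate.
#' @param n_samples Snapshots per focal bird.
#' @param switch_prob Per-sample probability of ending the current bout.
#' @param rate_hz Sampling rate (Hz).
#' @param seed Integer RNG seed.
#' @return A tibble shaped like [assign_leaders()] output (`follower`, `t`,
#'   `state`, `leader`, `ew`, `ns`, `ud`, `output`), all snapshots in-wake.
#' @export
simulate_null_assignments <- function(n_birds = 8, n_focal = 20,
                                      n_samples = 600, switch_prob = 0.1,
                                      rate_hz = 5, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_birds >= 3, n_focal >= 1, n_samples >= 1)
  pool <- sprintf("L%02d", seq_len(n_birds - 1L))
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_focal), function(f) {
      switch <- c(TRUE, stats::runif(n_samples - 1L) < switch_prob)
      bout <- cumsum(switch)
      leaders <- sample(pool, max(bout), replace = TRUE)[bout]
      tibble::tibble(follower = sprintf("F%03d", f),
                     t = (seq_len(n_samples) - 1L) / rate_hz,
                     state = "in_wake", leader = leaders,
                     ew = 1.3, ns = -0.5, ud = 0, output = 1)
    })
  })
}
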