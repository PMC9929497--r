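#' @importFrom rlang .data :=
#' @keywords internal
"_PACKAGE"

# Snap timestamps to the nominal sampling grid. Returns integer sample
# indices relative to the earliest timestamp; errors if any fix sits further
# than `tol` seconds from the grid.
.snap_to_grid <- function(t, rate_hz, tol = 1e-3) {
  t0 <- min(t)
  idx <- round((t - t0) * rate_hz)
  off <- abs(t - (t0 + idx / rate_hz))
  if (any(off > tol)) {
    bad <- which.max(off)
    stop(sprintf(paste0("timestamp %.6f is %.4f s away from the %g Hz grid ",
                        "(tolerance %g s)"),
                 t[bad], off[bad], rate_hz, tol), call. = FALSE)
  }
  as.integer(idx)
}

#' Smoothed flight heading of one bird at one snapshot
#'
#' The heading at time `t` is estimated from three consecutive fixes:
#' `alpha` is the direction of the horizontal displacement into `t`
#' (`x(t) - x(t-1)`), `beta` the direction out of `t` (`x(t+1) - x(t)`), and
#' `gamma` their circular mean, computed as the arctangent of the summed unit
#' vectors so that wraparound at +-pi is handled correctly. Angles are
#' mathematical convention (radians counter-clockwise from east, in
#' `(-pi, pi]`). Only the horizontal channel enters the heading; vertical
#' motion is ignored.
#'
#' @param traj Data frame with columns `t`, `x`, `y` (and optionally `z`),
#'   one bird, timestamps strictly increasing.
#' @param t Timestamp (s) at which to estimate the heading; must have both a
#'   predecessor and a successor sample.
#' @return A list with `alpha`, `beta`, `gamma` (radians).
#' @examples
#' traj <- data.frame(t = 0:2 / 5, x = c(0, 1, 1), y = c(0, 0, 1))
#' mean_heading(traj, 1 / 5) # alpha east, beta north, gamma 45 degrees
#' @export
mean_heading <- function(traj, t) {
  stopifnot(is.data.frame(traj), all(c("t", "x", "y") %in% names(traj)))
  i <- which(abs(traj$t - t) < 1e-9)
  if (length(i) != 1L) stop("no sample at timestamp ", t, call. = FALSE)
  if (i == 1L || i == nrow(traj)) {
    stop("heading needs both a predecessor and a successor sample",
         call. = FALSE)
  }
  d1 <- c(traj$x[i] - traj$x[i - 1L], traj$y[i] - traj$y[i - 1L])
  d2 <- c(traj$x[i + 1L] - traj$x[i], traj$y[i + 1L] - traj$y[i])
  if (all(d1 == 0) || all(d2 == 0)) {
    stop("degenerate heading: zero-length displacement (bird stationary)",
         call. = FALSE)
  }
  alpha <- atan2(d1[2], d1[1])
  beta <- atan2(d2[2], d2[1])
  u <- d1 / sqrt(sum(d1^2)) + d2 / sqrt(sum(d2^2))
  if (sqrt(sum(u^2)) < 1e-12) {
    stop("degenerate heading: opposing displacement vectors", call. = FALSE)
  }
  list(alpha = alpha, beta = beta, gamma = atan2(u[2], u[1]))
}

# Vectorised smoothed headings for every bird at every interior grid index.
# Returns bird_id, idx, t, gamma (NA where degenerate), hx, hy (unit heading).
.bird_headings <- function(pos) {
  pos |>
    dplyr::arrange(.data$bird_id, .data$idx) |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::mutate(
      dx1 = .data$x - dplyr::lag(.data$x),
      dy1 = .data$y - dplyr::lag(.data$y),
      dx2 = dplyr::lead(.data$x) - .data$x,
      dy2 = dplyr::lead(.data$y) - .data$y,
      contig = dplyr::lag(.data$idx) == .data$idx - 1L &
        dplyr::lead(.data$idx) == .data$idx + 1L
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$contig) & .data$contig) |>
    dplyr::mutate(
      n1 = sqrt(.data$dx1^2 + .data$dy1^2),
      n2 = sqrt(.data$dx2^2 + .data$dy2^2),
      ux = .data$dx1 / .data$n1 + .data$dx2 / .data$n2,
      uy = .data$dy1 / .data$n1 + .data$dy2 / .data$n2,
      un = sqrt(.data$ux^2 + .data$uy^2),
      ok = .data$n1 > 0 & .data$n2 > 0 & .data$un > 1e-12,
      gamma = ifelse(.data$ok, atan2(.data$uy, .data$ux), NA_real_),
      hx = ifelse(.data$ok, .data$ux / .data$un, NA_real_),
      hy = ifelse(.data$ok, .data$uy / .data$un, NA_real_)
    ) |>
    dplyr::select("bird_id", "idx", "t", "gamma", "hx", "hy")
}

#' Position of a follower in a leader's flight frame
#'
#' Translates so the leader sits at the origin and rotates the horizontal
#' plane so the leader's smoothed heading points along +y. The components are
#' `ew` (lateral; + = follower right of the leader's track), `ns`
#' (anteroposterior; + = follower ahead) and `ud` (vertical, computed as
#' leader z minus follower z; the rotation never touches the vertical
#' channel). `dist3d` is the Euclidean norm, identical to the distance in
#' absolute coordinates.
#'
#' @param leader,follower Data frames with columns `t`, `x`, `y`, `z` for one
#'   bird each.
#' @param t Timestamp (s) present in both; the leader needs interior
#'   neighbours for its heading.
#' @return A one-row tibble: `t`, `ew`, `ns`, `ud`, `dist3d`.
#' @export
relative_position <- function(leader, follower, t) {
  h <- mean_heading(leader, t)
  il <- which(abs(leader$t - t) < 1e-9)
  jf <- which(abs(follower$t - t) < 1e-9)
  if (length(jf) != 1L) {
    stop("follower has no sample at timestamp ", t, call. = FALSE)
  }
  dx <- follower$x[jf] - leader$x[il]
  dy <- follower$y[jf] - leader$y[il]
  hx <- cos(h$gamma)
  hy <- sin(h$gamma)
  zl <- if ("z" %in% names(leader)) leader$z[il] else 0
  zf <- if ("z" %in% names(follower)) follower$z[jf] else 0
  ud <- zl - zf
  tibble::tibble(t = t,
                 ew = dx * hy - dy * hx,
                 ns = dx * hx + dy * hy,
                 ud = ud,
                 dist3d = sqrt(dx^2 + dy^2 + ud^2))
}

#' Leader-relative coordinates for every ordered dyad
#'
#' For every ordered pair (follower, leader) and every snapshot where the
#' leader has a valid smoothed heading (interior, contiguous fixes) and the
#' follower has a fix, computes the follower's position in the leader's
#' flight frame. First and last snapshots of each bird are dropped (no
#' heading there); gaps in the sampling grid yield no rows — there is no
#' interpolation.
#'
#' @param positions Long-format data frame `bird_id`, `t`, `x`, `y`, `z`
#'   (metres, shared local tangent frame), e.g. from [read_positions()] or
#'   [simulate_flock()].
#' @param rate_hz Nominal sampling rate (Hz) used to snap timestamps to the
#'   grid (tolerance 1 ms).
#' @return A tibble: `follower`, `leader`, `t`, `ew`, `ns`, `ud`, `dist3d`,
#'   one row per ordered dyad and usable snapshot.
#' @export
relative_positions <- function(positions, rate_hz = 5) {
  pos <- .validate_positions(positions, rate_hz)
  if (length(unique(pos$bird_id)) < 2L) {
    stop("need at least two birds", call. = FALSE)
  }
  heads <- .bird_headings(pos) |>
    dplyr::filter(!is.na(.data$gamma))
  if (nrow(heads) == 0L) {
    stop("insufficient data: no bird has three contiguous fixes",
         call. = FALSE)
  }
  leaders <- heads |>
    dplyr::inner_join(dplyr::select(pos, "bird_id", "idx",
                                    lx = "x", ly = "y", lz = "z"),
                      by = c("bird_id", "idx")) |>
    dplyr::rename(leader = "bird_id")
  followers <- pos |>
    dplyr::select(follower = "bird_id", "idx",
                  fx = "x", fy = "y", fz = "z")
  rel <- dplyr::inner_join(followers, leaders, by = "idx",
                           relationship = "many-to-many") |>
    dplyr::filter(.data$follower != .data$leader) |>
    dplyr::mutate(
      dx = .data$fx - .data$lx,
      dy = .data$fy - .data$ly,
      ew = .data$dx * .data$hy - .data$dy * .data$hx,
      ns = .data$dx * .data$hx + .data$dy * .data$hy,
      ud = .data$lz - .data$fz,
      dist3d = sqrt(.data$dx^2 + .data$dy^2 + .data$ud^2)
    ) |>
    dplyr::arrange(.data$follower, .data$leader, .data$idx) |>
    dplyr::select("follower", "leader", "t", "ew", "ns", "ud", "dist3d")
  if (nrow(rel) == 0L) {
    stop("insufficient data: fewer than 3 shared snapshots", call. = FALSE)
  }
  rel
}

# Validate and normalise a positions table: character bird ids, numeric
# finite coordinates, unique (bird, t), timestamps snapped to the grid.
.validate_positions <- function(positions, rate_hz) {
  stopifnot(is.data.frame(positions))
  need <- c("bird_id", "t", "x", "y", "z")
  miss <- setdiff(need, names(positions))
  if (length(miss) > 0L) {
    stop("positions are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pos <- tibble::as_tibble(positions)[need]
  pos$bird_id <- as.character(pos$bird_id)
  for (cc in c("t", "x", "y", "z")) {
    if (!is.numeric(pos[[cc]]) || any(!is.finite(pos[[cc]]))) {
      stop("column '", cc, "' must be finite numeric", call. = FALSE)
    }
  }
  dup <- duplicated(pos[c("bird_id", "t")])
  if (any(dup)) {
    stop("duplicated (bird_id, timestamp) at row ", which(dup)[1L],
         call. = FALSE)
  }
  pos$idx <- .snap_to_grid(pos$t, rate_hz)
  pos
}
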