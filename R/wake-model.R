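#' Wake model configuration
#'
#' Parameters of the knowledge-based in-wake fuzzy model. Defaults encode the
#' literature-derived anchor geometry for a northern bald ibis flock: lateral wingtip
#' alignment peaks at +-1.3 m (a 20 cm wingtip overlap given the 1.5 m
#' wingspan) and vanishes inside +-0.8 m and beyond +-1.8 m; the
#' anteroposterior optimum sits 0.1 m behind the leader and decays to zero at
#' 5 m; co-planarity vanishes at half a wingspan (+-0.75 m) of vertical
#' offset.
#'
#' @param ew_inner_zero,ew_peak,ew_outer_zero Lateral anchors (m): membership
#'   of `wingtip_aligned` is 0 on `[-ew_inner_zero, ew_inner_zero]`, 1 at
#'   `+-ew_peak` and 0 again beyond `+-ew_outer_zero`.
#' @param ew_peak_halfwidth Half-width (m) of an optional flat top around the
#'   alignment peak; 0 gives a point peak.
#' @param ns_peak Anteroposterior optimum (m, negative = behind); `close`
#'   rises from 0 at `ns = 0` to 1 here.
#' @param ns_far_zero Distance (m, negative) at which `close` reaches 0 and
#'   `distant` reaches 1.
#' @param too_close_peak Apex (m, negative) of the narrow `too_close` spike
#'   between `ns_peak` and 0.
#' @param plane_zero Vertical offset (m) at which `same_plane` reaches 0.
#' @param in_wake,not_in_wake Crisp consequent values of the output variable
#'   `flying`.
#' @param tau Decision threshold: a follower is in-wake when the winning
#'   defuzzified output strictly exceeds `tau`. The default 0 classifies any
#'   positive upwash credit as in-wake; raise it (e.g. 0.5) to suppress
#'   high-frequency leader switching.
#' @param wingspan Species wingspan (m), used only to express the wingtip
#'   overlap implied by `ew_peak`.
#' @param tnorm Antecedent conjunction, `"min"` (default) or `"prod"`.
#' @return A list of class `wake_config`.
#' @export
wake_config <- function(ew_inner_zero = 0.8, ew_peak = 1.3,
                        ew_outer_zero = 1.8, ew_peak_halfwidth = 0,
                        ns_peak = -0.1, ns_far_zero = -5,
                        too_close_peak = -0.05,
                        plane_zero = 0.75,
                        in_wake = 1, not_in_wake = 0,
                        tau = 0, wingspan = 1.5,
                        tnorm = c("min", "prod")) {
  tnorm <- match.arg(tnorm)
  if (!(0 < ew_inner_zero && ew_inner_zero < ew_peak &&
        ew_peak < ew_outer_zero)) {
    stop("lateral anchors must satisfy 0 < inner zero < peak < outer zero",
         call. = FALSE)
  }
  if (ew_peak_halfwidth < 0 ||
      ew_peak - ew_peak_halfwidth <= ew_inner_zero ||
      ew_peak + ew_peak_halfwidth >= ew_outer_zero) {
    stop("peak plateau must fit strictly between the lateral zeros",
         call. = FALSE)
  }
  if (!(ns_far_zero < ns_peak && ns_peak < 0)) {
    stop("anteroposterior anchors must satisfy far zero < peak < 0",
         call. = FALSE)
  }
  if (!(ns_peak < too_close_peak && too_close_peak < 0)) {
    stop("too_close apex must lie strictly between the optimum and 0",
         call. = FALSE)
  }
  if (plane_zero <= 0) stop("plane_zero must be positive", call. = FALSE)
  if (!(tau >= 0 && tau < 1)) stop("tau must lie in [0, 1)", call. = FALSE)
  if (in_wake == not_in_wake) {
    stop("consequent values must be distinct", call. = FALSE)
  }
  structure(list(ew_inner_zero = ew_inner_zero, ew_peak = ew_peak,
                 ew_outer_zero = ew_outer_zero,
                 ew_peak_halfwidth = ew_peak_halfwidth,
                 ns_peak = ns_peak, ns_far_zero = ns_far_zero,
                 too_close_peak = too_close_peak, plane_zero = plane_zero,
                 in_wake = in_wake, not_in_wake = not_in_wake,
                 tau = tau, wingspan = wingspan, tnorm = tnorm),
            class = "wake_config")
}

#' Build the in-wake fuzzy rule base
#'
#' Constructs the five-rule zero-order Takagi-Sugeno system over the three
#' leader-relative coordinates: `bird_ew` (lateral displacement, terms
#' `wingtip_aligned` / `wingtip_misaligned`), `bird_ns` (anteroposterior
#' distance, terms `too_close` / `close` / `distant`) and `bird_plane`
#' (vertical offset, terms `same_plane` / `different_plane`). The paired
#' terms are exact pointwise complements. All `bird_ns` memberships are zero
#' for non-negative values: a follower can only be in-wake behind its leader.
#'
#' Rules: (1) aligned AND close AND same plane -> in_wake; (2) misaligned ->
#' not_in_wake; (3) too close -> not_in_wake; (4) distant -> not_in_wake;
#' (5) different plane -> not_in_wake.
#'
#' @param cfg A [wake_config()].
#' @return A [fuzzy_rulebase()] with five rules.
#' @export
wake_rulebase <- function(cfg = wake_config()) {
  stopifnot(inherits(cfg, "wake_config"))
  h <- cfg$ew_peak_halfwidth
  ew_x <- c(-cfg$ew_outer_zero,
            -cfg$ew_peak - h, if (h > 0) -cfg$ew_peak + h,
            -cfg$ew_inner_zero, cfg$ew_inner_zero,
            cfg$ew_peak - h, if (h > 0) cfg$ew_peak + h,
            cfg$ew_outer_zero)
  ew_m <- c(0, 1, if (h > 0) 1, 0, 0, 1, if (h > 0) 1, 0)
  aligned <- fuzzy_mf(ew_x, ew_m)
  close <- fuzzy_mf(c(cfg$ns_far_zero, cfg$ns_peak, 0), c(0, 1, 0))
  too_close <- fuzzy_mf(c(cfg$ns_peak, cfg$too_close_peak, 0), c(0, 1, 0))
  distant <- fuzzy_mf(c(cfg$ns_far_zero, cfg$ns_peak), c(1, 0),
                      left = 1, right = 0)
  same_plane <- fuzzy_mf(c(-cfg$plane_zero, 0, cfg$plane_zero), c(0, 1, 0))

  vars <- list(
    fuzzy_variable("bird_ew",
                   list(wingtip_aligned = aligned,
                        wingtip_misaligned = fuzzy_complement(aligned)),
                   universe = c(-cfg$ew_outer_zero, cfg$ew_outer_zero)),
    fuzzy_variable("bird_ns",
                   list(too_close = too_close, close = close,
                        distant = distant),
                   universe = c(cfg$ns_far_zero, 0)),
    fuzzy_variable("bird_plane",
                   list(same_plane = same_plane,
                        different_plane = fuzzy_complement(same_plane)),
                   universe = c(-cfg$plane_zero, cfg$plane_zero))
  )
  rules <- list(
    fuzzy_rule(list(c("bird_ew", "wingtip_aligned"),
                    c("bird_ns", "close"),
                    c("bird_plane", "same_plane")),
               "in_wake", cfg$in_wake),
    fuzzy_rule(list(c("bird_ew", "wingtip_misaligned")),
               "not_in_wake", cfg$not_in_wake),
    fuzzy_rule(list(c("bird_ns", "too_close")), "not_in_wake",
               cfg$not_in_wake),
    fuzzy_rule(list(c("bird_ns", "distant")), "not_in_wake",
               cfg$not_in_wake),
    fuzzy_rule(list(c("bird_plane", "different_plane")), "not_in_wake",
               cfg$not_in_wake)
  )
  fuzzy_rulebase(vars, rules, zero_strength_output = cfg$not_in_wake,
                 tnorm = cfg$tnorm)
}

#' Score dyads with the in-wake model
#'
#' Runs the fuzzy inference system on leader-relative coordinates. One row
#' per input row, with the five rule strengths, the defuzzified output in
#' `[0, 1]` and a `zero_fire` flag marking snapshots where no rule fired (the
#' output then falls back to the `not_in_wake` consequent). Since every
#' anteroposterior membership vanishes for `ns >= 0`, the output is 0 for any
#' follower at or ahead of its candidate leader.
#'
#' @param rels Data frame with columns `ew`, `ns`, `ud` (metres; typically
#'   [relative_positions()] output, whose identifier columns are carried
#'   through).
#' @param base A [fuzzy_rulebase()] from [wake_rulebase()].
#' @return A tibble: the input columns plus `r1`..`r5`, `output`,
#'   `zero_fire`.
#' @examples
#' score_dyads(data.frame(ew = 1.3, ns = -0.1, ud = 0), wake_rulebase())
#' @export
score_dyads <- function(rels, base = wake_rulebase()) {
  stopifnot(is.data.frame(rels),
            all(c("ew", "ns", "ud") %in% names(rels)))
  res <- defuzzify(base, list(bird_ew = rels$ew, bird_ns = rels$ns,
                              bird_plane = rels$ud))
  strengths <- res$strengths
  colnames(strengths) <- paste0("r", seq_len(ncol(strengths)))
  dplyr::bind_cols(tibble::as_tibble(rels), tibble::as_tibble(strengths),
                   tibble::tibble(output = res$output,
                                  zero_fire = res$zero_fire))
}

#' Assign at most one wake provider per follower and snapshot
#'
#' Implements the single-upwash constraint: for each follower at each
#' snapshot, the candidate leader with the highest defuzzified output wins.
#' If the winning output strictly exceeds `tau` the follower is `in_wake`
#' behind that leader; otherwise, if any candidate flies ahead (`ns > 0`) the
#' follower is `not_in_wake_front_bird` and the nearest (3D) front bird's
#' relative coordinates are reported; otherwise the follower is
#' `alone_no_front` with zero coordinates. Argmax ties break by smaller 3D
#' distance, then lexicographic leader id.
#'
#' @param scores Output of [score_dyads()] on the full ordered-dyad table
#'   from [relative_positions()]; must contain `follower`, `leader`, `t`,
#'   `ew`, `ns`, `ud`, `dist3d`, `output`. Both orientations of every dyad
#'   are used: a row (follower = k, leader = j) scores k in j's wake, while
#'   the mirror row (follower = j, leader = k) locates j in k's flight frame
#'   and is what decides whether j counts as a bird in front of k.
#' @param tau In-wake decision threshold in `[0, 1)`; see [wake_config()].
#' @return A tibble with one row per (follower, t): `follower`, `t`, `state`
#'   (`in_wake`, `not_in_wake_front_bird` or `alone_no_front`), `leader`
#'   (`NA` unless in-wake), `ew`, `ns`, `ud`, `output` (winning defuzzified
#'   value). For in-wake rows the coordinates are the follower's position in
#'   the leader's frame; for `not_in_wake_front_bird` they are the nearest
#'   front bird's position in the follower's own frame (`ns > 0`); zeros
#'   when alone.
#' @export
assign_leaders <- function(scores, tau = 0) {
  stopifnot(is.data.frame(scores),
            all(c("follower", "leader", "t", "ew", "ns", "ud", "dist3d",
                  "output") %in% names(scores)),
            tau >= 0, tau < 1)
  winners <- scores |>
    dplyr::group_by(.data$follower, .data$t) |>
    dplyr::arrange(dplyr::desc(.data$output), .data$dist3d, .data$leader,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("follower", "t", win_leader = "leader", win_ew = "ew",
                  win_ns = "ns", win_ud = "ud", output = "output")
  fronts <- scores |>
    dplyr::filter(.data$ns > 0) |>
    dplyr::group_by(.data$leader, .data$t) |>
    dplyr::arrange(.data$dist3d, .data$follower, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(follower = "leader", "t", front_ew = "ew",
                  front_ns = "ns", front_ud = "ud")
  winners |>
    dplyr::left_join(fronts, by = c("follower", "t")) |>
    dplyr::mutate(
      state = dplyr::case_when(
        .data$output > tau ~ "in_wake",
        !is.na(.data$front_ns) ~ "not_in_wake_front_bird",
        TRUE ~ "alone_no_front"),
      leader = ifelse(.data$state == "in_wake",
                      as.character(.data$win_leader), NA_character_),
      ew = dplyr::case_when(.data$state == "in_wake" ~ .data$win_ew,
                            .data$state == "not_in_wake_front_bird" ~
                              .data$front_ew,
                            TRUE ~ 0),
      ns = dplyr::case_when(.data$state == "in_wake" ~ .data$win_ns,
                            .data$state == "not_in_wake_front_bird" ~
                              .data$front_ns,
                            TRUE ~ 0),
      ud = dplyr::case_when(.data$state == "in_wake" ~ .data$win_ud,
                            .data$state == "not_in_wake_front_bird" ~
                              .data$front_ud,
                            TRUE ~ 0)
    ) |>
    dplyr::arrange(.data$follower, .data$t) |>
    dplyr::select("follower", "t", "state", "leader", "ew", "ns", "ud",
                  "output")
}

#' Defuzzified output over a coordinate plane
#'
#' Evaluates the in-wake model on a dense grid with one coordinate held
#' fixed, producing the data behind the model's response heatmaps (e.g. the
#' co-planar `ud = 0` view whose maxima sit at `ew = +-1.3`, `ns = -0.1`).
#'
#' @param base A [fuzzy_rulebase()].
#' @param plane Which coordinate is held fixed: `"ud"`, `"ns"` or `"ew"`.
#' @param value Fixed value (m) of that coordinate.
#' @param ew_range,ns_range,ud_range Ranges (m) for the free axes.
#' @param res Grid resolution (m), > 0.
#' @return A tibble of class `wake_grid` with the two free coordinates and
#'   `output`.
#' @export
wake_response_grid <- function(base = wake_rulebase(),
                               plane = c("ud", "ns", "ew"), value = 0,
                               ew_range = c(-2.5, 2.5),
                               ns_range = c(-6, 0),
                               ud_range = c(-1.5, 1.5),
                               res = 0.01) {
  plane <- match.arg(plane)
  if (!is.numeric(res) || res <= 0) {
    stop("grid resolution must be positive", call. = FALSE)
  }
  axes <- list(ew = seq(ew_range[1], ew_range[2], by = res),
               ns = seq(ns_range[1], ns_range[2], by = res),
               ud = seq(ud_range[1], ud_range[2], by = res))
  free <- setdiff(c("ew", "ns", "ud"), plane)
  grid <- tidyr::expand_grid(!!free[1] := axes[[free[1]]],
                             !!free[2] := axes[[free[2]]])
  grid[[plane]] <- value
  out <- defuzzify(base, list(bird_ew = grid$ew, bird_ns = grid$ns,
                              bird_plane = grid$ud))
  grid$output <- out$output
  res_tbl <- tibble::as_tibble(grid[c(free, "output")])
  attr(res_tbl, "plane") <- plane
  attr(res_tbl, "value") <- value
  class(res_tbl) <- c("wake_grid", class(res_tbl))
  res_tbl
}
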