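#' Frontal nearest-neighbour configuration
#'
#' The conventional baseline assigns as presumed wake provider the nearest
#' bird that is (i) leading (`ns > 0`), (ii) co-planar
#' (`-coplanar_halfwidth < ud < coplanar_halfwidth`, strict) and (iii) within
#' horizontal range (`sqrt(ns^2 + ew^2) <= max_range`, inclusive).
#'
#' @param coplanar_halfwidth Vertical half-window (m); the default 0.75
#'   corresponds to half a wingspan.
#' @param max_range Maximum horizontal distance (m), default 6.
#' @param metric Distance used to rank candidates: `"horizontal"` (default,
#'   consistent with the range condition) or `"3d"`.
#' @return A list of class `fnn_config`.
#' @export
fnn_config <- function(coplanar_halfwidth = 0.75, max_range = 6,
                       metric = c("horizontal", "3d")) {
  metric <- match.arg(metric)
  stopifnot(coplanar_halfwidth > 0, max_range > 0)
  structure(list(coplanar_halfwidth = coplanar_halfwidth,
                 max_range = max_range, metric = metric),
            class = "fnn_config")
}

#' Frontal nearest-neighbour assignment
#'
#' For every (focal bird, snapshot) picks the qualifying candidate
#' minimizing the configured distance, or records no leader when none
#' qualifies. Candidacy is judged in the focal bird's own flight frame: the
#' row (follower = j, leader = k) of the dyad table locates j in k's frame,
#' so j counts as a candidate leader for k when that row has `ns > 0` and
#' meets the co-planarity and range conditions. Ties break lexicographically
#' on candidate id. The reported coordinates are the focal bird's position
#' relative to its chosen leader (the mirror row), matching the in-wake
#' model's convention so the two models can be compared axis by axis.
#'
#' @param rels Full ordered-dyad table from [relative_positions()].
#' @param cfg An [fnn_config()].
#' @return A tibble with one row per (follower, t): `state` (`fnn_leader` or
#'   `fnn_none`), `leader` (`NA` when none), `ew`, `ns`, `ud` (follower
#'   relative to the chosen leader; zeros when none) and `model = "fnn"`.
#' @export
assign_fnn <- function(rels, cfg = fnn_config()) {
  stopifnot(is.data.frame(rels), inherits(cfg, "fnn_config"),
            all(c("follower", "leader", "t", "ew", "ns", "ud", "dist3d")
                %in% names(rels)))
  picks <- rels |>
    dplyr::mutate(
      horiz = sqrt(.data$ns^2 + .data$ew^2),
      rankdist = if (cfg$metric == "horizontal") .data$horiz
                 else .data$dist3d
    ) |>
    dplyr::filter(.data$ns > 0,
                  .data$ud > -cfg$coplanar_halfwidth,
                  .data$ud < cfg$coplanar_halfwidth,
                  .data$horiz <= cfg$max_range) |>
    dplyr::group_by(.data$leader, .data$t) |>
    dplyr::arrange(.data$rankdist, .data$follower, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(follower = "leader", "t", chosen = "follower")
  mirror <- dplyr::select(rels, "follower", chosen = "leader", "t",
                          "ew", "ns", "ud")
  all_snapshots <- dplyr::distinct(rels, .data$follower, .data$t)
  all_snapshots |>
    dplyr::left_join(picks, by = c("follower", "t")) |>
    dplyr::left_join(mirror, by = c("follower", "chosen", "t")) |>
    dplyr::mutate(
      state = ifelse(is.na(.data$chosen), "fnn_none", "fnn_leader"),
      leader = as.character(.data$chosen),
      ew = ifelse(is.na(.data$leader) | is.na(.data$ew), 0, .data$ew),
      ns = ifelse(is.na(.data$leader) | is.na(.data$ns), 0, .data$ns),
      ud = ifelse(is.na(.data$leader) | is.na(.data$ud), 0, .data$ud),
      model = "fnn"
    ) |>
    dplyr::arrange(.data$follower, .data$t) |>
    dplyr::select("follower", "t", "state", "leader", "ew", "ns", "ud",
                  "model")
}
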