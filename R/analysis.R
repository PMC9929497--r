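#' Behavioural bouts from an assignment stream
#'
#' Collapses per-snapshot wake assignments into maximal runs of constant
#' state. The two non-wake states are pooled as `not_in_wake`; when
#' `split_on_leader_change` is `TRUE` (default) an in-wake run also ends
#' whenever the leader identity changes, resolving the rapid
#' (200-400 ms) leader switches typical of dense flocks. Gaps in the
#' sampling grid terminate runs. Duration is `samples x 1/rate_hz`.
#'
#' @param assignments Output of [assign_leaders()] (any number of birds).
#' @param rate_hz Sampling rate (Hz).
#' @param split_on_leader_change Split in-wake bouts at leader switches?
#' @return A tibble: `follower`, `state` (`in_wake` / `not_in_wake`),
#'   `leader` (`NA` for not-in-wake bouts), `start_t`, `end_t`, `n_samples`,
#'   `duration` (s).
#' @export
extract_bouts <- function(assignments, rate_hz = 5,
                          split_on_leader_change = TRUE) {
  stopifnot(is.data.frame(assignments),
            all(c("follower", "t", "state") %in% names(assignments)))
  dt <- 1 / rate_hz
  assignments |>
    dplyr::mutate(
      bstate = ifelse(.data$state == "in_wake", "in_wake", "not_in_wake"),
      bleader = ifelse(.data$bstate == "in_wake",
                       as.character(.data$leader), NA_character_)
    ) |>
    dplyr::group_by(.data$follower) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(
      idx = as.integer(round((.data$t - min(.data$t)) * rate_hz)),
      gap = c(TRUE, diff(.data$idx) != 1L),
      newstate = .data$gap |
        .data$bstate != dplyr::lag(.data$bstate, default = "") |
        (!is.na(.data$bleader) & split_on_leader_change &
           (is.na(dplyr::lag(.data$bleader)) |
              .data$bleader != dplyr::lag(.data$bleader, default = ""))),
      bout = cumsum(.data$newstate)
    ) |>
    dplyr::group_by(.data$follower, .data$bout) |>
    dplyr::summarise(
      state = .data$bstate[1L],
      leader = .data$bleader[1L],
      start_t = min(.data$t),
      end_t = max(.data$t),
      n_samples = dplyr::n(),
      duration = dplyr::n() * dt,
      .groups = "drop"
    ) |>
    dplyr::select(-"bout")
}

#' Alone-time proportions per bird
#'
#' A bird flies "alone" at a snapshot when it is not in-wake; this splits
#' into flying with no bird in front (`prop_no_front`) versus having a front
#' bird whose wake it is not exploiting (`prop_front_not_in_wake`). The two
#' components sum to `prop_alone`.
#'
#' @param assignments Output of [assign_leaders()].
#' @return A tibble per bird: `follower`, `n_snapshots`, `prop_alone`,
#'   `prop_no_front`, `prop_front_not_in_wake`.
#' @export
alone_stats <- function(assignments) {
  stopifnot(is.data.frame(assignments),
            all(c("follower", "state") %in% names(assignments)))
  assignments |>
    dplyr::group_by(.data$follower) |>
    dplyr::summarise(
      n_snapshots = dplyr::n(),
      prop_no_front = mean(.data$state == "alone_no_front"),
      prop_front_not_in_wake = mean(.data$state == "not_in_wake_front_bird"),
      prop_alone = .data$prop_no_front + .data$prop_front_not_in_wake,
      .groups = "drop"
    ) |>
    dplyr::select("follower", "n_snapshots", "prop_alone", "prop_no_front",
                  "prop_front_not_in_wake")
}

#' Leader preference with a bootstrap no-preference null
#'
#' For each follower, the observed proportion of in-wake snapshots spent
#' behind each other bird, together with a 95% interval for that proportion
#' under the null hypothesis of no individual preference. The null is built
#' by non-parametric bootstrap: the follower's in-wake bouts are kept (their
#' lengths carry the autocorrelation of high-rate positioning data) but each
#' bout's leader is redrawn uniformly from the other `N - 1` birds; `n_boot`
#' replicates give per-leader 2.5% and 97.5% empirical quantiles (linear
#' interpolation). The favourite leader is the argmax of the observed
#' proportions.
#'
#' @param assignments Output of [assign_leaders()] for the whole flock (the
#'   candidate-leader pool is taken as all birds appearing as follower or
#'   leader).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param rate_hz Sampling rate (Hz), used to split bouts.
#' @param birds Optional character vector fixing the candidate-leader pool.
#' @return A tibble of class `leader_preference`: `follower`, `leader`,
#'   `n_snapshots` (in-wake snapshots behind that leader), `prop`, `ci_lo`,
#'   `ci_hi`, `favourite`. Followers with zero in-wake time are dropped with
#'   a warning.
#' @export
leader_preference <- function(assignments, n_boot = 1000, seed,
                              rate_hz = 5, birds = NULL) {
  stopifnot(is.data.frame(assignments), n_boot >= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(birds)) {
    birds <- sort(unique(c(as.character(assignments$follower),
                           stats::na.omit(as.character(assignments$leader)))))
  }
  bouts <- extract_bouts(assignments, rate_hz = rate_hz,
                         split_on_leader_change = TRUE) |>
    dplyr::filter(.data$state == "in_wake")
  no_wake <- setdiff(unique(as.character(assignments$follower)),
                     unique(bouts$follower))
  if (length(no_wake) > 0L) {
    warning("dropping bird(s) with zero in-wake time: ",
            paste(no_wake, collapse = ", "), call. = FALSE)
  }
  if (nrow(bouts) == 0L) {
    return(structure(tibble::tibble(follower = character(),
                                    leader = character(),
                                    n_snapshots = integer(), prop = double(),
                                    ci_lo = double(), ci_hi = double(),
                                    favourite = logical()),
                     class = c("leader_preference",
                               class(tibble::tibble()))))
  }
  res <- withr::with_seed(seed, {
    bouts |>
      dplyr::group_by(.data$follower) |>
      dplyr::group_modify(function(df, key) {
        .preference_one(df, key$follower, birds, n_boot)
      }) |>
      dplyr::ungroup()
  })
  class(res) <- c("leader_preference", class(res))
  res
}

.preference_one <- function(bouts, follower, birds, n_boot) {
  others <- setdiff(birds, follower)
  w <- bouts$n_samples
  total <- sum(w)
  obs <- vapply(others,
                function(b) sum(w[bouts$leader == b]) / total,
                numeric(1), USE.NAMES = FALSE)
  nb <- nrow(bouts)
  draws <- matrix(sample.int(length(others), n_boot * nb, replace = TRUE),
                  nrow = n_boot)
  wmat <- matrix(w, nrow = n_boot, ncol = nb, byrow = TRUE)
  ci <- vapply(seq_along(others), function(l) {
    props <- rowSums(wmat * (draws == l)) / total
    stats::quantile(props, c(0.025, 0.975), names = FALSE, type = 7)
  }, numeric(2))
  tibble::tibble(
    leader = others,
    n_snapshots = vapply(others,
                         function(b) sum(w[bouts$leader == b]), numeric(1),
                         USE.NAMES = FALSE),
    prop = obs,
    ci_lo = ci[1, ],
    ci_hi = ci[2, ],
    favourite = seq_along(others) == which.max(obs)
  )
}

#' Per-snapshot formation graphs
#'
#' The in-wake relationships of a snapshot form a directed graph with an arc
#' from each in-wake follower to its wake provider; the single-upwash
#' constraint bounds out-degree by one. Weakly connected components of that
#' graph delimit the subgroups flying in joint formation.
#'
#' @param assignments Output of [assign_leaders()].
#' @param include_singletons Keep components of size one (birds in no wake
#'   relationship)? Default `FALSE`: the subgroup-size distribution starts at
#'   dyads.
#' @return A tibble: `t`, `component`, `size`, `members`
#'   (comma-separated bird ids), `has_cycle` (the wake relation is expected
#'   to be acyclic; directed cycles are reported, not forbidden).
#' @export
formation_components <- function(assignments, include_singletons = FALSE) {
  stopifnot(is.data.frame(assignments),
            all(c("follower", "t", "state", "leader") %in%
                  names(assignments)))
  snaps <- assignments |>
    dplyr::group_by(.data$t) |>
    dplyr::group_modify(function(df, key) {
      .components_one(df, include_singletons)
    }) |>
    dplyr::ungroup()
  n_cyclic <- sum(snaps$has_cycle)
  if (n_cyclic > 0L) {
    warning(n_cyclic, " component(s) contain a directed cycle",
            call. = FALSE)
  }
  snaps
}

.components_one <- function(df, include_singletons) {
  nodes <- sort(unique(c(as.character(df$follower),
                         stats::na.omit(as.character(df$leader)))))
  edges <- df[df$state == "in_wake", c("follower", "leader")]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$follower),
               to = as.character(edges$leader)),
    directed = TRUE,
    vertices = data.frame(name = nodes)
  )
  comp <- igraph::components(g, mode = "weak")
  out <- tibble::tibble(member = names(comp$membership),
                        component = as.integer(comp$membership)) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(size = dplyr::n(),
                     members = paste(sort(.data$member), collapse = ","),
                     .groups = "drop")
  if (!include_singletons) out <- out[out$size > 1L, , drop = FALSE]
  if (nrow(out) == 0L) {
    return(tibble::tibble(component = integer(), size = integer(),
                          members = character(), has_cycle = logical()))
  }
  cyc <- !igraph::is_dag(g)
  cyc_members <- character()
  if (cyc) {
    # out-degree <= 1, so any cycle is reachable by following unique arcs
    scc <- igraph::components(g, mode = "strong")
    cyc_members <- names(scc$membership)[
      scc$membership %in% which(scc$csize > 1L)]
  }
  out$has_cycle <- vapply(strsplit(out$members, ","),
                          function(m) any(m %in% cyc_members), logical(1))
  out
}

#' Subgroup-size distribution over a flight
#'
#' @param components Output of [formation_components()].
#' @return A tibble: `size`, `n` (component-snapshots), `prop`.
#' @export
component_size_distribution <- function(components) {
  stopifnot(is.data.frame(components), "size" %in% names(components))
  components |>
    dplyr::count(.data$size, name = "n") |>
    dplyr::mutate(prop = .data$n / sum(.data$n))
}

#' Agreement between the fuzzy and frontal-nearest-neighbour models
#'
#' Compares the leader identity chosen by the in-wake fuzzy model and the
#' FNN baseline on identical snapshots, and tabulates the positional
#' distributions (histograms of `ew`, `ns`, `ud` of the follower relative to
#' the chosen leader) for both models, overall and restricted to
#' disagreement snapshots.
#'
#' @param fis Output of [assign_leaders()].
#' @param fnn Output of [assign_fnn()] on the same relative positions.
#' @param mode Denominator for the agreement proportion: `"both"` (default;
#'   snapshots where both models name a leader), `"either"` (at least one
#'   does; a missing leader counts as disagreement) or `"all"` (every
#'   snapshot; two no-leader calls count as agreement).
#' @param binwidth Histogram bin width (m).
#' @param range Histogram range (m), symmetric about zero for `ew`/`ud` and
#'   used as `c(-range, range)`; `ns` uses `c(-range, range)` too.
#' @return A list of class `model_agreement`: `per_bird` (tibble with
#'   `follower`, `n_compared`, `agreement`), `overall` (proportion),
#'   `histograms` (tibble `axis`, `model`, `subset`, `bin_lo`, `bin_hi`,
#'   `count`), `mode`.
#' @export
model_agreement <- function(fis, fnn, mode = c("both", "either", "all"),
                            binwidth = 0.25, range = 6) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(fis), is.data.frame(fnn))
  joined <- dplyr::inner_join(
    dplyr::select(fis, "follower", "t", fis_leader = "leader",
                  fis_ew = "ew", fis_ns = "ns", fis_ud = "ud",
                  fis_state = "state"),
    dplyr::select(fnn, "follower", "t", fnn_leader = "leader",
                  fnn_ew = "ew", fnn_ns = "ns", fnn_ud = "ud"),
    by = c("follower", "t")
  )
  if (nrow(joined) != nrow(fis) || nrow(joined) != nrow(fnn)) {
    stop("the two models were not run on identical snapshots",
         call. = FALSE)
  }
  joined <- joined |>
    dplyr::mutate(
      both = !is.na(.data$fis_leader) & !is.na(.data$fnn_leader),
      either = !is.na(.data$fis_leader) | !is.na(.data$fnn_leader),
      same = (!is.na(.data$fis_leader) & !is.na(.data$fnn_leader) &
                .data$fis_leader == .data$fnn_leader) |
        (is.na(.data$fis_leader) & is.na(.data$fnn_leader)),
      compared = switch(mode, both = .data$both, either = .data$either,
                        all = TRUE)
    )
  cmp <- joined[joined$compared, , drop = FALSE]
  per_bird <- cmp |>
    dplyr::group_by(.data$follower) |>
    dplyr::summarise(n_compared = dplyr::n(),
                     agreement = mean(.data$same), .groups = "drop")
  breaks <- seq(-range, range, by = binwidth)
  hist_one <- function(df, model, subset) {
    prefix <- if (model == "fis") "fis_" else "fnn_"
    keep <- !is.na(df[[paste0(prefix, "leader")]])
    purrr::map_dfr(c("ew", "ns", "ud"), function(ax) {
      v <- df[[paste0(prefix, ax)]][keep]
      v <- v[v >= -range & v <= range]
      h <- graphics::hist(v, breaks = breaks, plot = FALSE)
      tibble::tibble(axis = ax, model = model, subset = subset,
                     bin_lo = utils::head(h$breaks, -1L),
                     bin_hi = h$breaks[-1L], count = h$counts)
    })
  }
  disag <- joined[joined$both & !joined$same, , drop = FALSE]
  histograms <- dplyr::bind_rows(
    hist_one(joined, "fis", "all"), hist_one(joined, "fnn", "all"),
    hist_one(disag, "fis", "disagreement"),
    hist_one(disag, "fnn", "disagreement")
  )
  structure(list(per_bird = per_bird,
                 overall = if (nrow(cmp)) mean(cmp$same) else NA_real_,
                 histograms = histograms, mode = mode),
            class = "model_agreement")
}

#' @export
print.model_agreement <- function(x, ...) {
  cat(sprintf("Model agreement (%s snapshots): %.1f%% overall, %d birds\n",
              x$mode, 100 * x$overall, nrow(x$per_bird)))
  invisible(x)
}
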