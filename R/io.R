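#' Read a flock position file
#'
#' Long-format CSV with header `bird_id,timestamp,x,y,z`; coordinates in
#' metres in a shared local tangent frame. Timestamps may be numeric seconds
#' or ISO-8601 date-times (normalised to seconds from the first sample).
#' Malformed rows, missing columns and duplicated (bird, timestamp) pairs
#' raise errors naming the offence; per-bird sample counts are reported via
#' `message()`.
#'
#' @param path CSV file path.
#' @param rate_hz Nominal sampling rate (Hz) for grid validation.
#' @param quiet Suppress the per-bird sample-count message?
#' @return A validated tibble `bird_id`, `t`, `x`, `y`, `z` with attribute
#'   `rate_hz`.
#' @export
read_positions <- function(path, rate_hz = 5, quiet = FALSE) {
  if (!file.exists(path)) {
    stop("position file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("bird_id", "timestamp", "x", "y", "z")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ts <- suppressWarnings(as.numeric(raw$timestamp))
  if (anyNA(ts)) {
    iso <- as.POSIXct(raw$timestamp, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                     "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(iso)) {
      bad <- which(is.na(ts) & is.na(iso))[1L]
      stop("non-numeric, non-ISO timestamp at data row ", bad, ": '",
           raw$timestamp[bad], "'", call. = FALSE)
    }
    ts <- as.numeric(iso) - as.numeric(min(iso))
  }
  pos <- tibble::tibble(bird_id = raw$bird_id, t = ts)
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    if (anyNA(v)) {
      stop("non-numeric '", cc, "' at data row ", which(is.na(v))[1L],
           call. = FALSE)
    }
    pos[[cc]] <- v
  }
  dup <- duplicated(pos[c("bird_id", "t")])
  if (any(dup)) {
    stop("duplicated (bird_id, timestamp) at data row ", which(dup)[1L],
         call. = FALSE)
  }
  pos <- .validate_positions(pos, rate_hz)
  pos$idx <- NULL
  if (!quiet) {
    counts <- dplyr::count(pos, .data$bird_id)
    message(sprintf("read %d birds, %d-%d samples each (mean %.0f)",
                    nrow(counts), min(counts$n), max(counts$n),
                    mean(counts$n)))
  }
  attr(pos, "rate_hz") <- rate_hz
  pos
}

#' Write a flock position file
#'
#' Inverse of [read_positions()]: emits `bird_id,timestamp,x,y,z`.
#'
#' @param positions Tibble `bird_id`, `t`, `x`, `y`, `z`.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_positions <- function(positions, path) {
  stopifnot(all(c("bird_id", "t", "x", "y", "z") %in% names(positions)))
  out <- tibble::tibble(bird_id = positions$bird_id,
                        timestamp = positions$t,
                        x = positions$x, y = positions$y, z = positions$z)
  readr::write_csv(out, path)
  invisible(path)
}

#' Run the full in-wake fuzzy pipeline
#'
#' Frame transform, dyad scoring and single-upwash leader assignment in one
#' call.
#'
#' @param positions Long-format positions (`bird_id`, `t`, `x`, `y`, `z`).
#' @param cfg A [wake_config()].
#' @param rate_hz Sampling rate (Hz).
#' @return An object of class `wake_fis`: list with `assignments`, `scores`,
#'   `rels`, `config`, `rate_hz`. Use [generics::tidy()] for the assignment
#'   table and [generics::glance()] for a one-row summary.
#' @examples
#' sim <- simulate_flock(sim_config(n_birds = 3, duration = 5, seed = 1))
#' fit <- run_wake_fis(sim$positions)
#' glance(fit)
#' @export
run_wake_fis <- function(positions, cfg = wake_config(), rate_hz = 5) {
  stopifnot(inherits(cfg, "wake_config"))
  rels <- relative_positions(positions, rate_hz = rate_hz)
  base <- wake_rulebase(cfg)
  scores <- score_dyads(rels, base)
  assignments <- assign_leaders(scores, tau = cfg$tau)
  structure(list(assignments = assignments, scores = scores, rels = rels,
                 config = cfg, rate_hz = rate_hz),
            class = "wake_fis")
}

#' @export
print.wake_fis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("In-wake fuzzy model: %d birds, %d snapshots; ",
                     "%.1f%% in-wake (tau = %g)\n"),
              g$n_birds, g$n_snapshots, 100 * g$prop_in_wake, x$config$tau))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-snapshot wake assignments
#'
#' @param x A `wake_fis` object.
#' @param ... Unused.
#' @return The assignment tibble (`follower`, `t`, `state`, `leader`, `ew`,
#'   `ns`, `ud`, `output`).
#' @export
tidy.wake_fis <- function(x, ...) x$assignments

#' One-row summary of a wake-model fit
#'
#' @param x A `wake_fis` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_birds`, `n_snapshots`, `prop_in_wake`,
#'   `prop_front_not_in_wake`, `prop_no_front`, `mean_output`,
#'   `prop_zero_fire`.
#' @export
glance.wake_fis <- function(x, ...) {
  a <- x$assignments
  tibble::tibble(
    n_birds = length(unique(a$follower)),
    n_snapshots = nrow(a),
    prop_in_wake = mean(a$state == "in_wake"),
    prop_front_not_in_wake = mean(a$state == "not_in_wake_front_bird"),
    prop_no_front = mean(a$state == "alone_no_front"),
    mean_output = mean(a$output),
    prop_zero_fire = mean(x$scores$zero_fire)
  )
}

#' Tidy a leader-preference table
#'
#' @param x A `leader_preference` object.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.leader_preference <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "leader_preference")
  out
}

#' One-row summary of leader preference
#'
#' @param x A `leader_preference` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_followers`, `mean_prop` (mean observed
#'   following proportion over all (follower, leader) cells), `sd_prop`,
#'   `prop_outside_ci` (cells escaping the null interval).
#' @export
glance.leader_preference <- function(x, ...) {
  tibble::tibble(
    n_followers = length(unique(x$follower)),
    mean_prop = mean(x$prop),
    sd_prop = stats::sd(x$prop),
    prop_outside_ci = mean(x$prop < x$ci_lo | x$prop > x$ci_hi)
  )
}

#' Write the standard output tables of a pipeline run
#'
#' Emits the per-follower assignment CSV
#' (`follower,timestamp,state,leader_id,ew,ns,ud,output`), the rule-strength
#' CSV (`timestamp,follower,leader,r1..r5,output,zero_fire`) and the
#' rule-base JSON into a directory.
#'
#' @param fit A `wake_fis` object.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_wake_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "wake_fis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- fit$assignments
  readr::write_csv(
    tibble::tibble(follower = a$follower, timestamp = a$t, state = a$state,
                   leader_id = a$leader, ew = a$ew, ns = a$ns, ud = a$ud,
                   output = a$output),
    file.path(dir, "assignments.csv"))
  s <- fit$scores
  readr::write_csv(
    dplyr::select(s, timestamp = "t", "follower", "leader",
                  dplyr::starts_with("r"), "output", "zero_fire"),
    file.path(dir, "strengths.csv"))
  rulebase_to_json(wake_rulebase(fit$config),
                   file.path(dir, "rulebase.json"))
  invisible(dir)
}
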