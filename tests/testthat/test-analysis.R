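mk_assign <- function(states, leaders = NULL, rate_hz = 5,
                      follower = "A") {
  n <- length(states)
  if (is.null(leaders)) leaders <- rep(NA_character_, n)
  tibble::tibble(follower = follower, t = (seq_len(n) - 1L) / rate_hz,
                 state = states, leader = leaders,
                 ew = 0, ns = 0, ud = 0, output = 0)
}

test_that("bouts are maximal runs of constant state (and leader)", {
  w <- "in_wake"; n <- "not_in_wake_front_bird"
  a <- mk_assign(c(w, w, n, w), leaders = c("B", "B", NA, "B"))
  b <- extract_bouts(a, split_on_leader_change = FALSE)
  expect_equal(b$duration, c(0.4, 0.2, 0.2))
  expect_equal(b$state, c("in_wake", "not_in_wake", "in_wake"))

  # leader change splits an in-wake run when the flag is on
  a2 <- mk_assign(c(w, w), leaders = c("B", "C"))
  expect_equal(extract_bouts(a2, split_on_leader_change = TRUE)$duration,
               c(0.2, 0.2))
  expect_equal(nrow(extract_bouts(a2, split_on_leader_change = FALSE)), 1)

  # one long not-in-wake stream is a single bout
  a3 <- mk_assign(rep("alone_no_front", 50))
  b3 <- extract_bouts(a3)
  expect_equal(nrow(b3), 1)
  expect_equal(b3$duration, 10)

  # a gap in the sampling grid terminates the run
  a4 <- mk_assign(rep(w, 6), leaders = rep("B", 6))
  a4 <- a4[-3, ]
  expect_equal(nrow(extract_bouts(a4)), 2)

  # bout durations partition the analysed flight
  sim <- simulate_flock(sim_config(n_birds = 5, duration = 20, seed = 3,
                                   leader_switch_prob = 0.05))
  fit <- run_wake_fis(sim$positions)
  bouts <- extract_bouts(fit$assignments)
  per_bird_bouts <- tapply(bouts$n_samples, bouts$follower, sum)
  per_bird_snaps <- table(fit$assignments$follower)
  expect_equal(as.integer(per_bird_bouts[names(per_bird_snaps)]),
               as.integer(per_bird_snaps))
})

test_that("alone-time proportions split into the two components", {
  w <- "in_wake"; fnb <- "not_in_wake_front_bird"; alone <- "alone_no_front"
  a <- mk_assign(c(rep(w, 7), alone, alone, fnb))
  s <- alone_stats(a)
  expect_equal(s$prop_alone, 0.3)
  expect_equal(s$prop_no_front, 0.2)
  expect_equal(s$prop_front_not_in_wake, 0.1)

  never <- alone_stats(mk_assign(rep(fnb, 10)))
  expect_equal(never$prop_alone, 1)
  expect_equal(never$prop_front_not_in_wake, 1)
  always <- alone_stats(mk_assign(rep(w, 10)))
  expect_equal(always$prop_alone, 0)
})

test_that("leader preference reports observed proportions and favourites", {
  w <- "in_wake"
  # two leaders followed for 3 and 1 bouts of one sample each
  a <- mk_assign(rep(w, 8),
                 leaders = c("B", "C", "B", "C", "B", "C", "B", "C"))
  a$leader <- c("B", "B", "B", "C", "B", "B", "B", "C")
  # insert not-in-wake separators so bouts are unambiguous
  a$state[c(4, 8)] <- "in_wake" # keep all in-wake; splits on leader change
  pref <- suppressWarnings(
    leader_preference(a, n_boot = 50, seed = 1, birds = c("A", "B", "C")))
  expect_equal(pref$prop[pref$leader == "B"], 0.75)
  expect_equal(pref$prop[pref$leader == "C"], 0.25)
  expect_true(pref$favourite[pref$leader == "B"])
  expect_false(pref$favourite[pref$leader == "C"])
  expect_true(all(pref$ci_lo <= pref$ci_hi))
  # proportions sum to one over leaders
  expect_equal(sum(pref$prop), 1)

  # single leader ever followed
  a1 <- mk_assign(rep(w, 5), leaders = rep("B", 5))
  p1 <- leader_preference(a1, n_boot = 50, seed = 1,
                          birds = c("A", "B", "C"))
  expect_equal(p1$prop[p1$leader == "B"], 1)
  expect_true(p1$favourite[p1$leader == "B"])

  # zero in-wake time warns and drops
  expect_warning(
    leader_preference(mk_assign(rep("alone_no_front", 5)),
                      n_boot = 10, seed = 1, birds = c("A", "B")),
    "zero in-wake")
})

test_that("null-calibrated data keep observed proportions inside the CI", {
  a <- simulate_null_assignments(n_birds = 6, n_focal = 12,
                                 n_samples = 400, switch_prob = 0.2,
                                 seed = 8)
  pool <- sprintf("L%02d", 1:5)
  pref <- leader_preference(a, n_boot = 400, seed = 9, birds = pool)
  cover <- mean(pref$prop >= pref$ci_lo & pref$prop <= pref$ci_hi)
  expect_gt(cover, 0.85)
  # long-run proportions approach the uniform 1/(N-1)
  expect_equal(mean(pref$prop), 1 / 5, tolerance = 1e-9)
  # bout-length weighting inflates the binomial sd by ~sqrt(1.8) for
  # geometric bouts, hence the wide multiplier
  expect_lt(max(abs(pref$prop - 0.2)), 6 * sqrt(0.2 * 0.8 / 80))
})

test_that("formation components are weakly connected wake subgroups", {
  w <- "in_wake"
  a <- dplyr::bind_rows(
    mk_assign(w, leaders = "B", follower = "A"),
    mk_assign(w, leaders = "B", follower = "C"),
    mk_assign("alone_no_front", follower = "D"),
    mk_assign("alone_no_front", follower = "B")
  )
  comp <- formation_components(a, include_singletons = TRUE)
  expect_equal(sort(comp$size), c(1, 3))
  expect_equal(comp$members[comp$size == 3], "A,B,C")
  expect_equal(sum(comp$size), 4) # sizes partition the flock
  no_single <- formation_components(a)
  expect_equal(no_single$size, 3)

  # chain A -> B -> C -> D: one component of 4 (union-find oracle)
  chain <- dplyr::bind_rows(
    mk_assign(w, leaders = "B", follower = "A"),
    mk_assign(w, leaders = "C", follower = "B"),
    mk_assign(w, leaders = "D", follower = "C"),
    mk_assign("alone_no_front", follower = "D")
  )
  got <- formation_components(chain)
  oracle <- uf_components(c("A", "B", "C", "D"),
                          from = c("A", "B", "C"), to = c("B", "C", "D"))
  expect_equal(got$size, lengths(oracle)[[1]])
  expect_equal(got$members, paste(sort(oracle[[1]]), collapse = ","))

  # no arcs at all: empty distribution without singletons
  lone <- dplyr::bind_rows(lapply(c("A", "B", "C", "D", "E"), function(b) {
    mk_assign("alone_no_front", follower = b)
  }))
  expect_equal(nrow(formation_components(lone)), 0)
  expect_equal(nrow(formation_components(lone,
                                         include_singletons = TRUE)), 5)

  # 2-cycles are reported, not forbidden
  cyc <- dplyr::bind_rows(
    mk_assign(w, leaders = "B", follower = "A"),
    mk_assign(w, leaders = "A", follower = "B")
  )
  expect_warning(cc <- formation_components(cyc), "cycle")
  expect_true(all(cc$has_cycle))
  expect_equal(cc$size, 2)

  dist <- component_size_distribution(
    formation_components(a, include_singletons = TRUE))
  expect_equal(sum(dist$prop), 1)
})

test_that("model agreement compares leader identity snapshot by snapshot", {
  offs <- tibble::tibble(bird_id = "F", ew = 1.3, ns = -0.5, ud = 0)
  rels <- relative_positions(make_straight_flock(offs))
  fis <- assign_leaders(score_dyads(rels))
  fnn <- assign_fnn(rels)
  agr <- model_agreement(fis, fnn)
  expect_equal(agr$overall, 1)
  expect_true(all(agr$per_bird$agreement >= 0 &
                    agr$per_bird$agreement <= 1))
  # symmetric in model order
  agr_rev <- model_agreement(
    dplyr::mutate(fnn, state = ifelse(state == "fnn_leader", "in_wake",
                                      state)),
    dplyr::mutate(fis, model = "fnn"))
  expect_equal(agr_rev$overall, agr$overall)

  # planted decoy: NEAR is directly ahead and close (the FNN's pick, but in
  # NEAR's downwash), FAR is ahead-left so that A sits at FAR's lateral
  # wake optimum (the FIS's pick) -- the proximity-vs-upwash disagreement
  decoy <- tibble::tibble(
    follower = c("A", "A", "NEAR", "FAR"), t = 0.2,
    leader = c("NEAR", "FAR", "A", "A"),
    ew = c(0, 1.3, 0, -1.3),
    ns = c(-0.4, -0.3, 0.4, 0.3),
    ud = 0,
    dist3d = c(0.4, sqrt(1.3^2 + 0.3^2), 0.4, sqrt(1.3^2 + 0.3^2))
  )
  scored <- score_dyads(decoy)
  fis2 <- assign_leaders(scored)
  fnn2 <- assign_fnn(decoy)
  expect_equal(fis2$leader[fis2$follower == "A"], "FAR")
  expect_equal(fnn2$leader[fnn2$follower == "A"], "NEAR")
  agr2 <- model_agreement(fis2, fnn2)
  expect_equal(agr2$overall, 0)
  # disagreement histograms carry one snapshot per model
  dis <- agr2$histograms[agr2$histograms$subset == "disagreement", ]
  expect_equal(sum(dis$count[dis$model == "fis" & dis$axis == "ew"]), 1)
  expect_equal(sum(dis$count[dis$model == "fnn" & dis$axis == "ew"]), 1)

  # snapshot mismatch errors
  expect_error(model_agreement(fis[-1, ], fnn), "identical snapshots")
})
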