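test_that("rule base encodes the published anchors and complements", {
  base <- wake_rulebase()
  expect_length(base$rules, 5)
  ew <- base$variables$bird_ew$terms
  # misaligned is fully on in the downwash corridor and far outside
  expect_equal(fuzzy_membership(ew$wingtip_misaligned, c(-0.5, 0, 0.5)),
               c(1, 1, 1))
  expect_equal(fuzzy_membership(ew$wingtip_misaligned, c(-2.5, 2.5)),
               c(1, 1))
  # complement identities hold pointwise on a dense grid
  g <- seq(-3, 3, by = 0.01)
  expect_equal(fuzzy_membership(ew$wingtip_aligned, g) +
                 fuzzy_membership(ew$wingtip_misaligned, g),
               rep(1, length(g)), tolerance = 1e-12)
  pl <- base$variables$bird_plane$terms
  gp <- seq(-2, 2, by = 0.01)
  expect_equal(fuzzy_membership(pl$same_plane, gp) +
                 fuzzy_membership(pl$different_plane, gp),
               rep(1, length(gp)), tolerance = 1e-12)
  expect_equal(fuzzy_membership(pl$different_plane, -0.75) +
                 fuzzy_membership(pl$same_plane, -0.75), 1)
  # rule 1 fires fully at the planted optimum
  expect_equal(rule_strength(base$rules[[1]],
                             list(bird_ew = 1.3, bird_ns = -0.1,
                                  bird_plane = 0), base), 1)
})

test_that("wake config validation catches inconsistent anchors", {
  expect_error(wake_config(ew_inner_zero = 1.5), "inner zero < peak")
  expect_error(wake_config(ns_peak = 0.1), "far zero < peak")
  expect_error(wake_config(too_close_peak = -0.5), "too_close apex")
  expect_error(wake_config(tau = 1), "tau")
  expect_error(wake_config(in_wake = 0), "distinct")
  # optional flat top at the alignment peak
  base <- wake_rulebase(wake_config(ew_peak_halfwidth = 0.1))
  al <- base$variables$bird_ew$terms$wingtip_aligned
  expect_equal(fuzzy_membership(al, c(1.2, 1.3, 1.4)), c(1, 1, 1))
  expect_equal(fuzzy_membership(al, 1.8), 0)
})

test_that("dyad scores match hand-derived cases", {
  base <- wake_rulebase()
  cases <- tibble::tibble(
    ew = c(1.3, 0, 1.3, -1.3),
    ns = c(-0.1, -1, 1, -0.1),
    ud = c(0, 0, 0, 0),
    expected = c(1, 0, 0, 1)
  )
  scored <- score_dyads(cases, base)
  expect_equal(scored$output, cases$expected)
  expect_named(scored, c("ew", "ns", "ud", "expected", paste0("r", 1:5),
                         "output", "zero_fire"))
  # rule 1 alone carries the in-wake optimum
  expect_equal(scored$r1[1], 1)
  expect_equal(sum(scored[1, paste0("r", 2:5)]), 0)
})

test_that("output vanishes for any follower at or ahead of the leader", {
  base <- wake_rulebase()
  withr::with_seed(31, {
    ahead <- tibble::tibble(ew = runif(500, -3, 3), ns = runif(500, 0, 6),
                            ud = runif(500, -2, 2))
  })
  expect_equal(score_dyads(ahead, base)$output, rep(0, 500))
})

test_that("response surface is symmetric and peaks at the upwash optimum", {
  base <- wake_rulebase()
  g <- wake_response_grid(base, plane = "ud", value = 0, res = 0.01)
  best <- g[which.max(g$output), ]
  expect_equal(abs(best$ew), 1.3, tolerance = 1e-8)
  expect_equal(abs(best$ns), 0.1, tolerance = 1e-8)
  expect_equal(max(g$output), 1)

  # left/right mirror symmetry on the co-planar plane
  gm <- wake_response_grid(base, plane = "ud", value = 0,
                           ew_range = c(-2, 2), ns_range = c(-3, 0),
                           res = 0.05)
  mirror <- dplyr::inner_join(
    gm, dplyr::mutate(gm, ew = -ew),
    by = c("ew", "ns"), suffix = c("", "_m"))
  expect_gt(nrow(mirror), 1000)
  expect_equal(mirror$output, mirror$output_m, tolerance = 1e-9)

  # vertical symmetry output(ew, ns, ud) = output(ew, ns, -ud)
  withr::with_seed(32, {
    pts <- tibble::tibble(ew = runif(300, -2.5, 2.5),
                          ns = runif(300, -6, 0.5),
                          ud = runif(300, -1.5, 1.5))
  })
  up <- score_dyads(pts, base)$output
  dn <- score_dyads(dplyr::mutate(pts, ud = -ud), base)$output
  expect_equal(up, dn, tolerance = 1e-12)

  # directly-behind plane is everywhere zero (rule 2 fires fully)
  g0 <- wake_response_grid(base, plane = "ew", value = 0, res = 0.05)
  expect_equal(g0$output, rep(0, nrow(g0)))

  # monotone decay behind the optimum at the lateral peak
  ns_seq <- seq(-0.1, -5, by = -0.01)
  o <- defuzzify(base, list(bird_ew = rep(1.3, length(ns_seq)),
                            bird_ns = ns_seq,
                            bird_plane = rep(0, length(ns_seq))))$output
  expect_true(all(diff(o) <= 1e-12))
  beyond <- defuzzify(base, list(bird_ew = 1.3, bird_ns = -5.5,
                                 bird_plane = 0))$output
  expect_equal(beyond, 0)

  expect_error(wake_response_grid(base, res = 0), "resolution")
})

test_that("leader assignment enforces the single-upwash constraint", {
  # A sits in the wake of both B and C (who fly ahead of it); the mirror
  # rows locate B and C in A's frame
  scores <- tibble::tibble(
    follower = c("A", "A", "B", "C"), t = 0.2,
    leader = c("B", "C", "A", "A"),
    ew = c(1.3, 1.6, -1.3, -1.6),
    ns = c(-0.5, -0.8, 0.5, 0.8),
    ud = 0,
    dist3d = c(1.39, 1.79, 1.39, 1.79),
    output = c(0.9, 0.4, 0, 0)
  )
  a <- assign_leaders(scores, tau = 0)
  aa <- a[a$follower == "A", ]
  expect_equal(aa$state, "in_wake")
  expect_equal(aa$leader, "B")
  expect_equal(aa$output, 0.9)
  expect_equal(c(aa$ew, aa$ns), c(1.3, -0.5))
  # B has nobody ahead of it -> alone with zero coordinates
  expect_equal(a$state[a$follower == "B"], "alone_no_front")
  expect_equal(a$ew[a$follower == "B"], 0)

  # no candidate above threshold but birds ahead -> nearest front bird's
  # coordinates in A's own frame, leader unset
  a95 <- assign_leaders(scores, tau = 0.95)
  aa95 <- a95[a95$follower == "A", ]
  expect_equal(aa95$state, "not_in_wake_front_bird")
  expect_true(is.na(aa95$leader))
  expect_equal(c(aa95$ew, aa95$ns), c(-1.3, 0.5)) # nearest front bird (B)

  # nobody ahead and no wake -> alone with zero coordinates
  behind_only <- tibble::tibble(
    follower = c("B", "C", "A", "A"), t = 0.2,
    leader = c("A", "A", "B", "C"),
    ew = c(0, 0, 0, 0), ns = c(-2, -3, 2, 3), ud = 0,
    dist3d = c(2, 3, 2, 3), output = 0
  )
  ab <- assign_leaders(behind_only, tau = 0)
  aa_b <- ab[ab$follower == "A", ]
  expect_equal(aa_b$state, "alone_no_front")
  expect_equal(c(aa_b$ew, aa_b$ns, aa_b$ud), c(0, 0, 0))
  # ...while B sees A in front
  expect_equal(ab$state[ab$follower == "B"], "not_in_wake_front_bird")
  expect_equal(ab$ns[ab$follower == "B"], 2)

  # argmax ties break by smaller 3D distance then id
  tie <- tibble::tibble(follower = "A", t = 0, leader = c("C", "B"),
                        ew = c(1.3, 1.3), ns = c(-0.5, -0.5), ud = c(0, 0),
                        dist3d = c(1.39, 1.39), output = c(0.8, 0.8))
  expect_equal(assign_leaders(tie)$leader, "B")

  # exactly one assignment per follower per snapshot on a real run
  sim <- simulate_flock(sim_config(n_birds = 4, duration = 10, seed = 5))
  fit <- run_wake_fis(sim$positions)
  counts <- dplyr::count(fit$assignments, follower, t)
  expect_true(all(counts$n == 1))
})
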