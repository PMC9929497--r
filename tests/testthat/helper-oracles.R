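# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementation.

# brute-force piecewise-linear membership: scan anchors, interpolate by hand
brute_membership <- function(mf, x) {
  xs <- mf$x
  ms <- mf$m
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (v < xs[1]) {
      out[i] <- mf$left
    } else if (v > xs[length(xs)]) {
      out[i] <- mf$right
    } else {
      for (k in seq_len(length(xs) - 1L)) {
        if (v >= xs[k] && v <= xs[k + 1L]) {
          w <- (v - xs[k]) / (xs[k + 1L] - xs[k])
          out[i] <- (1 - w) * ms[k] + w * ms[k + 1L]
          break
        }
      }
      if (v == xs[length(xs)]) out[i] <- ms[length(ms)]
    }
  }
  out
}

# brute-force 0-order Takagi-Sugeno: explicit loop over rules and clauses
brute_defuzzify <- function(base, inputs) {
  num <- 0
  den <- 0
  for (rule in base$rules) {
    s <- 1
    for (cl in rule$antecedent) {
      m <- brute_membership(base$variables[[cl[1]]]$terms[[cl[2]]],
                            inputs[[cl[1]]])
      s <- if (base$tnorm == "min") min(s, m) else s * m
    }
    num <- num + s * rule$consequent_value
    den <- den + s
  }
  if (den == 0) base$zero_strength_output else num / den
}

# union-find connected components over undirected edge list
uf_components <- function(nodes, from, to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(a) {
    while (parent[[a]] != a) a <- parent[[a]]
    a
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# straight northward flock: one bird per column of `offsets` (ew, ns, ud)
# relative to a lead bird flying due north at `speed`
make_straight_flock <- function(offsets, n_steps = 10, rate_hz = 5,
                                speed = 10, lead_id = "L") {
  dt <- 1 / rate_hz
  tvec <- (seq_len(n_steps) - 1L) * dt
  lead <- tibble::tibble(bird_id = lead_id, t = tvec, x = 0,
                         y = speed * tvec, z = 100)
  rows <- lapply(seq_len(nrow(offsets)), function(i) {
    # heading north: ew -> +x, ns -> +y, ud = z_lead - z => z = 100 - ud
    tibble::tibble(bird_id = offsets$bird_id[i], t = tvec,
                   x = offsets$ew[i], y = speed * tvec + offsets$ns[i],
                   z = 100 - offsets$ud[i])
  })
  dplyr::bind_rows(c(list(lead), rows))
}

ts_reference_outputs <- function(base, inputs_df) {
  script <- system.file("validation", "ts_reference.py",
                        package = "flockwake")
  stopifnot(nzchar(script))
  tmp_base <- tempfile(fileext = ".json")
  tmp_in <- tempfile(fileext = ".csv")
  tmp_out <- tempfile(fileext = ".csv")
  rulebase_to_json(base, tmp_base)
  readr::write_csv(inputs_df, tmp_in)
  status <- system2("python", c(script, tmp_base, tmp_in, tmp_out))
  stopifnot(status == 0)
  readr::read_csv(tmp_out, show_col_types = FALSE)$output
}
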