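#' Piecewise-linear membership function
#'
#' Builds a fuzzy membership function defined by interpolation anchors.
#' Between anchors the membership is linearly interpolated; outside the
#' anchored range it is held at a constant plateau (by default the membership
#' of the nearest anchor), so the function returns a value for every real
#' input.
#'
#' @param x Numeric vector of anchor positions, strictly increasing, in the
#'   units of the universe of discourse (metres for all wake-model variables).
#' @param m Numeric vector of membership degrees in `[0, 1]`, same length as
#'   `x`.
#' @param left,right Plateau membership held for inputs below the first /
#'   above the last anchor. Defaults to the boundary anchor's membership.
#' @return An object of class `fuzzy_mf`.
#' @examples
#' aligned <- fuzzy_mf(c(-1.8, -1.3, -0.8, 0.8, 1.3, 1.8),
#'                     c(0, 1, 0, 0, 1, 0))
#' fuzzy_membership(aligned, c(0, 1.3, 1.55, 3))
#' @export
fuzzy_mf <- function(x, m, left = m[1], right = m[length(m)]) {
  stopifnot(is.numeric(x), is.numeric(m), length(x) == length(m),
            length(x) >= 1L, all(is.finite(x)), all(is.finite(m)))
  if (any(diff(x) <= 0)) {
    stop("membership anchors must be strictly increasing", call. = FALSE)
  }
  if (any(m < 0 | m > 1) || left < 0 || left > 1 || right < 0 || right > 1) {
    stop("membership degrees must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(x = as.numeric(x), m = as.numeric(m),
         left = as.numeric(left), right = as.numeric(right)),
    class = "fuzzy_mf"
  )
}

#' Evaluate a membership function
#'
#' @param mf A [fuzzy_mf()].
#' @param x Numeric vector of (finite) universe values.
#' @return Numeric vector of membership degrees in `[0, 1]`.
#' @export
fuzzy_membership <- function(mf, x) {
  stopifnot(inherits(mf, "fuzzy_mf"))
  if (any(!is.finite(x))) {
    stop("membership input must be finite", call. = FALSE)
  }
  if (length(mf$x) == 1L) {
    out <- ifelse(x < mf$x, mf$left, ifelse(x > mf$x, mf$right, mf$m))
    return(as.numeric(out))
  }
  out <- stats::approx(mf$x, mf$m, xout = x, method = "linear",
                       yleft = mf$left, yright = mf$right, ties = "ordered")$y
  as.numeric(out)
}

#' Complement of a membership function
#'
#' Pointwise `1 - m(x)`; exact for piecewise-linear functions because the
#' complement shares the same knots.
#' @param mf A [fuzzy_mf()].
#' @return A [fuzzy_mf()].
#' @export
fuzzy_complement <- function(mf) {
  fuzzy_mf(mf$x, 1 - mf$m, left = 1 - mf$left, right = 1 - mf$right)
}

#' Fuzzy logic connectors on membership degrees
#'
#' Conjunction, disjunction and negation of membership degrees. `fz_and()`
#' uses the configured t-norm (`"min"` or `"prod"`), `fz_or()` the max s-norm
#' and `fz_not()` the standard complement.
#'
#' @param ... Numeric vectors of membership degrees (recycled elementwise).
#' @param m Numeric vector of membership degrees.
#' @param tnorm `"min"` (default) or `"prod"`.
#' @return Numeric vector of degrees in `[0, 1]`.
#' @export
fz_and <- function(..., tnorm = c("min", "prod")) {
  tnorm <- match.arg(tnorm)
  vals <- list(...)
  if (tnorm == "min") Reduce(pmin, vals) else Reduce(`*`, vals)
}

#' @rdname fz_and
#' @export
fz_or <- function(...) Reduce(pmax, list(...))

#' @rdname fz_and
#' @export
fz_not <- function(m) 1 - m

#' Linguistic variable
#'
#' A named input dimension together with its fuzzy terms.
#'
#' @param name Variable label (e.g. `"bird_ew"`).
#' @param terms Named list of [fuzzy_mf()], one per linguistic term.
#' @param universe Optional numeric length-2 range documenting the modelled
#'   universe of discourse.
#' @return An object of class `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, terms, universe = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.list(terms),
            length(terms) >= 1L)
  if (is.null(names(terms)) || anyDuplicated(names(terms)) ||
      any(!nzchar(names(terms)))) {
    stop("terms must be uniquely named", call. = FALSE)
  }
  ok <- vapply(terms, inherits, logical(1), "fuzzy_mf")
  if (!all(ok)) stop("every term must be a fuzzy_mf", call. = FALSE)
  structure(list(name = name, terms = terms, universe = universe),
            class = "fuzzy_variable")
}

#' Fuzzy rule with a crisp (zero-order Takagi-Sugeno) consequent
#'
#' @param antecedent List of clauses, each a character vector
#'   `c(variable, term)`; clauses are combined with the rule base's t-norm
#'   (logical AND).
#' @param consequent_label Output term label (e.g. `"in_wake"`).
#' @param consequent_value Crisp output value.
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedent, consequent_label, consequent_value) {
  stopifnot(is.list(antecedent), length(antecedent) >= 1L,
            is.character(consequent_label), length(consequent_label) == 1L,
            is.numeric(consequent_value), length(consequent_value) == 1L,
            is.finite(consequent_value))
  ok <- vapply(antecedent, function(cl) is.character(cl) && length(cl) == 2L,
               logical(1))
  if (!all(ok)) {
    stop("each antecedent clause must be c(variable, term)", call. = FALSE)
  }
  structure(list(antecedent = antecedent,
                 consequent_label = consequent_label,
                 consequent_value = as.numeric(consequent_value)),
            class = "fuzzy_rule")
}

#' Zero-order Takagi-Sugeno rule base
#'
#' Collects linguistic variables and rules. Inference computes each rule's
#' firing strength from clause memberships (min t-norm by default) and
#' defuzzifies as the strength-weighted mean of the crisp consequents.
#'
#' @param variables List of [fuzzy_variable()].
#' @param rules List of [fuzzy_rule()]; every referenced variable/term must
#'   exist.
#' @param zero_strength_output Crisp value returned when no rule fires at all.
#' @param tnorm Conjunction operator for antecedents: `"min"` (default) or
#'   `"prod"`.
#' @return An object of class `fuzzy_rulebase`.
#' @export
fuzzy_rulebase <- function(variables, rules, zero_strength_output = 0,
                           tnorm = c("min", "prod")) {
  tnorm <- match.arg(tnorm)
  stopifnot(is.list(variables), is.list(rules), length(rules) >= 1L,
            is.numeric(zero_strength_output),
            is.finite(zero_strength_output))
  ok <- vapply(variables, inherits, logical(1), "fuzzy_variable")
  if (!all(ok)) stop("variables must be fuzzy_variable objects", call. = FALSE)
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(names(variables))) {
    stop("variable names must be unique", call. = FALSE)
  }
  for (r in rules) {
    if (!inherits(r, "fuzzy_rule")) {
      stop("rules must be fuzzy_rule objects", call. = FALSE)
    }
    for (cl in r$antecedent) {
      if (!cl[1] %in% names(variables)) {
        stop("rule references unknown variable '", cl[1], "'", call. = FALSE)
      }
      if (!cl[2] %in% names(variables[[cl[1]]]$terms)) {
        stop("rule references unknown term '", cl[2], "' of variable '",
             cl[1], "'", call. = FALSE)
      }
    }
  }
  structure(list(variables = variables, rules = rules,
                 zero_strength_output = as.numeric(zero_strength_output),
                 tnorm = tnorm),
            class = "fuzzy_rulebase")
}

#' @export
print.fuzzy_rulebase <- function(x, ...) {
  cat("Zero-order Takagi-Sugeno rule base\n")
  cat("  variables:", paste(names(x$variables), collapse = ", "), "\n")
  cat("  rules:", length(x$rules), " (t-norm:", x$tnorm, ")\n")
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    ant <- paste(vapply(r$antecedent,
                        function(cl) paste(cl[1], "IS", cl[2]),
                        character(1)),
                 collapse = " AND ")
    cat(sprintf("  %d: IF %s THEN %s (%g)\n", i, ant,
                r$consequent_label, r$consequent_value))
  }
  invisible(x)
}

#' Firing strength of one rule
#'
#' @param rule A [fuzzy_rule()].
#' @param inputs Named numeric vector or list mapping variable names to crisp
#'   input values.
#' @param base The [fuzzy_rulebase()] providing variables and the t-norm.
#' @return Firing strength in `[0, 1]` (vectorised over input values).
#' @export
rule_strength <- function(rule, inputs, base) {
  stopifnot(inherits(rule, "fuzzy_rule"), inherits(base, "fuzzy_rulebase"))
  inputs <- as.list(inputs)
  degrees <- lapply(rule$antecedent, function(cl) {
    if (is.null(inputs[[cl[1]]])) {
      stop("missing input for variable '", cl[1], "'", call. = FALSE)
    }
    fuzzy_membership(base$variables[[cl[1]]]$terms[[cl[2]]],
                     inputs[[cl[1]]])
  })
  if (base$tnorm == "min") Reduce(pmin, degrees) else Reduce(`*`, degrees)
}

#' Defuzzify a rule base at crisp inputs
#'
#' Zero-order Takagi-Sugeno inference: the output is
#' `sum(strength_i * value_i) / sum(strength_i)`. When no rule fires at all
#' the configured `zero_strength_output` is returned and `zero_fire` is set,
#' so callers can distinguish "no rule fired" from a genuine zero consequent.
#'
#' @inheritParams rule_strength
#' @param inputs Named list/vector of crisp inputs; values may be equal-length
#'   numeric vectors for vectorised evaluation.
#' @return A list with `output` (numeric), `strengths` (matrix, one column per
#'   rule) and `zero_fire` (logical).
#' @examples
#' base <- wake_rulebase()
#' defuzzify(base, list(bird_ew = 1.3, bird_ns = -0.1, bird_plane = 0))$output
#' @export
defuzzify <- function(base, inputs) {
  stopifnot(inherits(base, "fuzzy_rulebase"))
  strengths <- vapply(base$rules, rule_strength,
                      numeric(length(inputs[[1]])),
                      inputs = inputs, base = base)
  if (is.null(dim(strengths))) {
    strengths <- matrix(strengths, nrow = 1L)
  }
  values <- vapply(base$rules, `[[`, numeric(1), "consequent_value")
  total <- rowSums(strengths)
  zero_fire <- total == 0
  output <- ifelse(zero_fire, base$zero_strength_output,
                   as.numeric(strengths %*% values) /
                     ifelse(zero_fire, 1, total))
  list(output = as.numeric(output), strengths = strengths,
       zero_fire = zero_fire)
}

#' Serialize a rule base to JSON
#'
#' Writes anchors, plateaus, rules and inference settings so that
#' [rulebase_from_json()] reconstructs a bit-identical rule base.
#'
#' @param base A [fuzzy_rulebase()].
#' @param path File path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
rulebase_to_json <- function(base, path = NULL) {
  stopifnot(inherits(base, "fuzzy_rulebase"))
  obj <- list(
    inference = "takagi-sugeno-0",
    tnorm = base$tnorm,
    zero_strength_output = base$zero_strength_output,
    variables = lapply(base$variables, function(v) {
      list(universe = v$universe,
           terms = lapply(v$terms, function(mf) {
             list(x = I(mf$x), m = I(mf$m), left = mf$left, right = mf$right)
           }))
    }),
    rules = lapply(base$rules, function(r) {
      list(antecedent = lapply(r$antecedent,
                               function(cl) list(variable = cl[1],
                                                 term = cl[2])),
           consequent_label = r$consequent_label,
           consequent_value = r$consequent_value)
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Deserialize a rule base from JSON
#'
#' @param path File path or a JSON string produced by [rulebase_to_json()].
#' @return A [fuzzy_rulebase()].
#' @export
rulebase_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  variables <- lapply(names(obj$variables), function(nm) {
    v <- obj$variables[[nm]]
    terms <- lapply(v$terms, function(tm) {
      fuzzy_mf(unlist(tm$x), unlist(tm$m), left = tm$left, right = tm$right)
    })
    fuzzy_variable(nm, terms,
                   universe = if (!is.null(v$universe)) unlist(v$universe))
  })
  rules <- lapply(obj$rules, function(r) {
    fuzzy_rule(lapply(r$antecedent, function(cl) c(cl$variable, cl$term)),
               r$consequent_label, r$consequent_value)
  })
  fuzzy_rulebase(variables, rules,
                 zero_strength_output = obj$zero_strength_output,
                 tnorm = obj$tnorm)
}
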