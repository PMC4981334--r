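#' Left-hand side of the multiplayer sigma rule
#'
#' The expected gains from flipping `E[f(J)] = sum_j sigma_j f_j`, where `f`
#' is [gains_from_flipping()] and `J` is distributed according to the
#' normalized structure coefficients. Strategy `A` is favored over `B` under
#' weak selection (fixation probability of a single `A` mutant exceeds that
#' of a single `B` mutant) exactly when this quantity is positive.
#'
#' @param sc A `structure_coefficients` object.
#' @param game A [multiplayer_game()] with the same `d`.
#' @return A single number.
#' @export
sigma_rule_lhs <- function(sc, game) {
  stopifnot(is_structure_coefficients(sc), is_multiplayer_game(game))
  if (sc$d != game$d)
    stop(sprintf("dimension mismatch: coefficients have d = %d, game has d = %d",
                 sc$d, game$d))
  sum(sc$sigma * gains_from_flipping(game))
}

#' Decide whether strategy A is favored over B
#'
#' Applies the sigma rule: `A` is favored when the expected gains from
#' flipping are strictly positive. An exact zero lies on the selection
#' boundary and is reported as not favored with `boundary = TRUE`.
#'
#' @inheritParams sigma_rule_lhs
#' @return An object of class `selection_verdict` with fields `lhs`,
#'   `favored`, `boundary` and `coefficients_source`.
#' @examples
#' sc <- cycle_coefficients(Inf)
#' is_favored(sc, volunteers_dilemma(B = 3, C = 1, d = 3))
#' @export
is_favored <- function(sc, game) {
  lhs <- sigma_rule_lhs(sc, game)
  structure(list(lhs = lhs, favored = lhs > 0, boundary = lhs == 0,
                 coefficients_source = sc$source),
            class = "selection_verdict")
}

#' @export
print.selection_verdict <- function(x, ...) {
  cat(sprintf("sigma rule [%s]: E f(J) = %g -> %s%s\n",
              x$coefficients_source, x$lhs,
              if (x$favored) "A favored over B" else "A not favored over B",
              if (x$boundary) " (selection boundary)" else ""))
  invisible(x)
}

#' @param x A `selection_verdict`.
#' @param ... Unused.
#' @return `glance()`: a one-row tibble with `lhs`, `favored`, `boundary`,
#'   `coefficients_source`.
#' @rdname is_favored
#' @exportS3Method generics::glance
glance.selection_verdict <- function(x, ...) {
  tibble::tibble(lhs = x$lhs, favored = x$favored, boundary = x$boundary,
                 coefficients_source = x$coefficients_source)
}

#' Critical benefit-to-cost ratio for the volunteer's dilemma
#'
#' For the volunteer's dilemma the sigma rule reduces to
#' `B/C > 1 / sigma_{d-1}`, so the critical ratio depends on the population
#' structure only through its last structure coefficient. On the cycle this
#' gives `2(N-2)/(N-3)` (tending to 2), and in a large well-mixed population
#' `d = k + 1`.
#'
#' @param sc A `structure_coefficients` object.
#' @param exact If `TRUE` and `sc` carries an exact rational representation,
#'   return the threshold as an exact fraction (class `rat`) instead of a
#'   double.
#' @return The critical `B/C` (a number, or a `rat` when `exact = TRUE`);
#'   `Inf` when `sigma_{d-1} = 0` (cooperation is never favored).
#' @export
critical_bc_vd <- function(sc, exact = FALSE) {
  stopifnot(is_structure_coefficients(sc))
  if (exact) {
    if (is.null(sc$num)) stop("no exact representation available for these coefficients")
    if (sc$num[sc$d] == 0) return(Inf)
    return(rat(sc$den, sc$num[sc$d]))
  }
  last <- sc$sigma[sc$d]
  if (last == 0) return(Inf)
  1 / last
}

#' Critical benefit-to-cost ratio for the cost-sharing volunteer's dilemma
#'
#' When the cost of the public good is shared among cooperators the sigma
#' rule becomes `B/C > (1 / sigma_{d-1}) * sum_j sigma_j / (j + 1)`. On a
#' large cycle the threshold is `5/6` — below 1, so cooperation is favored
#' even when the shared cost exceeds the benefit margin of a lone volunteer.
#'
#' @inheritParams critical_bc_vd
#' @return The critical `B/C` (a number, or a `rat` when `exact = TRUE`);
#'   `Inf` when `sigma_{d-1} = 0`.
#' @export
critical_bc_vd_cs <- function(sc, exact = FALSE) {
  stopifnot(is_structure_coefficients(sc))
  j <- seq_len(sc$d) - 1
  if (exact) {
    if (is.null(sc$num)) stop("no exact representation available for these coefficients")
    if (sc$num[sc$d] == 0) return(Inf)
    acc <- rat(0)
    for (i in seq_len(sc$d))
      acc <- rat_add(acc, rat(sc$num[i], sc$den * i))
    return(rat_mul(rat(sc$den, sc$num[sc$d]), acc))
  }
  last <- sc$sigma[sc$d]
  if (last == 0) return(Inf)
  sum(sc$sigma / (j + 1)) / last
}

#' Pairwise sigma condition on a regular graph
#'
#' For a collection of two-player games with payoff matrix
#' `(alpha, beta; gamma, delta)` summed over `k` neighbors, the multiplayer
#' sigma rule on a large regular graph reduces (via the mean identity
#' `E[J] = (k+1)/2`) to the classical pairwise condition
#' `(k+1) alpha + (k-1) beta - (k-1) gamma - (k+1) delta > 0`. For the
#' donation game this is the well-known `B/C > k` rule.
#'
#' @inheritParams game_from_pairwise
#' @return `TRUE` if the condition holds strictly.
#' @export
pairwise_condition <- function(alpha, beta, gamma, delta, k) {
  if (k < 2) stop("degree k must be at least 2")
  (k + 1) * alpha + (k - 1) * beta - (k - 1) * gamma - (k + 1) * delta > 0
}

#' Sigma condition for linear games on a regular graph
#'
#' For [linear_game()] payoffs the sigma rule on a large regular graph of
#' degree `k` simplifies to `2B + D(k+1) > 2Ck`. With `D = 0` this recovers
#' `B/C > k`; for large `k` with a bonus it tends to `D > 2C`.
#'
#' @inheritParams linear_game
#' @return `TRUE` if the condition holds strictly.
#' @export
linear_condition <- function(B, C, D, k) {
  if (k < 2) stop("degree k must be at least 2")
  2 * B + D * (k + 1) > 2 * C * k
}

#' Count sign changes of a sequence
#'
#' Counts strict sign alternations in sequence order, skipping zeros (a zero
#' entry neither creates nor breaks a run of like signs). Used for the
#' containment-order test between population structures, where a single
#' `-` to `+` change in a coefficient difference is sufficient for one
#' structure to favor cooperation in every cooperation game the other does.
#'
#' @param x Numeric vector of length at least 2.
#' @return A list with `count` (number of alternations) and `pattern` (the
#'   run signs as a string of `-` and `+`).
#' @examples
#' sign_changes(c(-1, -2, 3, 4))   # one change, "-+"
#' @export
sign_changes <- function(x) {
  if (length(x) < 2) stop("need at least 2 entries")
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) == 0) stop("undefined pattern: all entries are zero")
  runs <- rle(s)$values
  list(count = length(runs) - 1L,
       pattern = paste(ifelse(runs > 0, "+", "-"), collapse = ""))
}

#' Compare two structures in the containment order
#'
#' A population structure is greater than another in the containment order
#' when its set of cooperation games favoring `A` contains the other's. A
#' sufficient condition is that the difference of normalized structure
#' coefficients has exactly one sign change from `-` to `+`. The test is
#' sufficient but not necessary, so the third outcome is
#' `"incomparable_by_this_test"` rather than a definite incomparability.
#'
#' @param sc_a,sc_b `structure_coefficients` objects with equal `d`.
#' @return One of `"a_contains_b"`, `"b_contains_a"`,
#'   `"incomparable_by_this_test"`.
#' @examples
#' containment_compare(regular_graph_coefficients(5),
#'                     wellmixed_coefficients(Inf, 6))
#' @export
containment_compare <- function(sc_a, sc_b) {
  stopifnot(is_structure_coefficients(sc_a), is_structure_coefficients(sc_b))
  if (sc_a$d != sc_b$d) stop("dimension mismatch: unequal d")
  diff <- sc_a$sigma - sc_b$sigma
  if (all(diff == 0)) return("incomparable_by_this_test")
  sc <- sign_changes(diff)
  if (sc$count == 1 && sc$pattern == "-+") return("a_contains_b")
  if (sc$count == 1 && sc$pattern == "+-") return("b_contains_a")
  "incomparable_by_this_test"
}

#' Containment scan of regular graphs against the well-mixed baseline
#'
#' For each degree `k` in the requested range, compares the regular-graph
#' coefficient vector with the large well-mixed population playing
#' `d = k + 1`-player games and records the sign-change pattern of their
#' difference. A single `-+` change for every `k` means large regular graphs
#' favor cooperation in every cooperation game the well-mixed population
#' does.
#'
#' @param kmin,kmax Degree range (both at least 3).
#' @return A tibble with columns `k`, `sign_change_count`, `pattern`,
#'   `verdict`.
#' @export
containment_scan <- function(kmin = 3, kmax = 100) {
  stopifnot(kmin >= 3, kmax >= kmin)
  ks <- kmin:kmax
  rows <- lapply(ks, function(k) {
    diff <- regular_graph_coefficients(k)$sigma -
      wellmixed_coefficients(Inf, k + 1)$sigma
    sc <- sign_changes(diff)
    tibble::tibble(k = k, sign_change_count = sc$count, pattern = sc$pattern)
  })
  out <- do.call(rbind, rows)
  out$verdict <- ifelse(out$sign_change_count == 1 & out$pattern == "-+",
                        "a_contains_b", "incomparable_by_this_test")
  out
}
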