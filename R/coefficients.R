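#' Structure coefficients of a population structure
#'
#' Normalized structure coefficients are a vector of `d` nonnegative numbers
#' summing to one that encode, for a given population structure and update
#' rule and independently of any payoffs, how a focal player's group
#' compositions are weighted under weak selection. They define a probability
#' distribution over the number `J` of co-players using the focal strategy;
#' strategy `A` is favored over `B` exactly when the expected gains from
#' flipping under this distribution are positive (the sigma rule).
#'
#' Objects of class `structure_coefficients` carry the numeric vector
#' `sigma`, the group size `d`, a `source` tag recording which structure and
#' formula produced them, a `params` list (`N` and/or `k`), and — when the
#' defining formula is a closed-form ratio of small integers — an exact
#' rational representation (`num` integer numerators over the common
#' denominator `den`) used by exact threshold computations.
#'
#' @param sigma Numeric vector of nonnegative coefficients.
#' @param source Provenance tag, one of `"well_mixed"`, `"cycle_exact"`,
#'   `"regular_approx"`, `"cycle_overlapping"`, `"custom"`.
#' @param params Named list of structural parameters (`N`, `k`).
#' @param num,den Optional exact representation: integer numerators and a
#'   common denominator with `sigma == num / den`.
#'
#' @return An object of class `structure_coefficients`.
#' @keywords internal
new_structure_coefficients <- function(sigma, source, params = list(),
                                       num = NULL, den = NULL) {
  sigma <- as.numeric(sigma)
  if (any(sigma < 0)) stop("structure coefficients must be nonnegative")
  s <- sum(sigma)
  if (abs(s - 1) > 1e-12) stop("structure coefficients must sum to 1")
  structure(list(d = length(sigma), sigma = sigma, source = source,
                 params = params, num = num, den = den),
            class = "structure_coefficients")
}

is_structure_coefficients <- function(x) inherits(x, "structure_coefficients")

#' @export
print.structure_coefficients <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("structure coefficients [%s%s], d = %d\n", x$source,
              if (nzchar(p)) paste0("; ", p) else "", x$d))
  v <- x$sigma
  names(v) <- paste0("sigma_", seq_along(v) - 1)
  print(v)
  invisible(x)
}

#' @param x A `structure_coefficients` object.
#' @param ... Unused.
#' @return A tibble with columns `j` and `sigma`.
#' @rdname new_structure_coefficients
#' @exportS3Method generics::tidy
tidy.structure_coefficients <- function(x, ...) {
  tibble::tibble(j = seq_len(x$d) - 1L, sigma = x$sigma)
}

#' Structure coefficients of a well-mixed population
#'
#' For a well-mixed population of size `N` in which groups of `d` players are
#' formed at random (Moran or Wright-Fisher updating), the normalized
#' structure coefficients are `N / (d (N - 1))` for `j <= d - 2` and
#' `(N - d) / (d (N - 1))` for `j = d - 1`. In the large-population limit
#' (`N = Inf`) they are uniform, `1/d`.
#'
#' @param N Population size (`> d`), or `Inf` for the large-population limit.
#' @param d Group size, at least 2.
#' @return A `structure_coefficients` object with source `"well_mixed"`.
#' @examples
#' wellmixed_coefficients(100, 6)
#' wellmixed_coefficients(Inf, 4)
#' @export
wellmixed_coefficients <- function(N, d) {
  if (d < 2) stop("group size d must be at least 2")
  if (is.infinite(N)) {
    return(new_structure_coefficients(rep(1 / d, d), "well_mixed",
                                      list(N = Inf, d = d),
                                      num = rep(1, d), den = d))
  }
  if (N <= d) stop("population too small: need N > d")
  num <- c(rep(N, d - 1), N - d)
  den <- d * (N - 1)
  new_structure_coefficients(num / den, "well_mixed", list(N = N, d = d),
                             num = num, den = den)
}

#' Exact structure coefficients of the cycle
#'
#' On the cycle (regular graph of degree `k = 2`, so three-player games)
#' updated with a Moran death-Birth process the structure coefficients are
#' known exactly: `sigma_0 = 1/(2(N-2))`, `sigma_1 = 1/2`,
#' `sigma_2 = (N-3)/(2(N-2))`. As `N -> Inf` they tend to `(0, 1/2, 1/2)`,
#' under which the sigma rule reduces to `a_1 + a_2 > b_1 + b_0` — the
#' condition for a cluster boundary of `A`-players to advance.
#'
#' @param N Number of vertices (`>= 4`), or `Inf` for the large-cycle limit.
#' @return A `structure_coefficients` object with source `"cycle_exact"` and
#'   `d = 3`.
#' @examples
#' cycle_coefficients(5)      # (1/6, 1/2, 1/3)
#' cycle_coefficients(Inf)    # (0, 1/2, 1/2)
#' @export
cycle_coefficients <- function(N) {
  if (is.infinite(N)) {
    return(new_structure_coefficients(c(0, 0.5, 0.5), "cycle_exact",
                                      list(N = Inf, k = 2),
                                      num = c(0, 1, 1), den = 2))
  }
  if (N < 4) stop("graph too small: the cycle formulas need N >= 4")
  num <- c(1, N - 2, N - 3)
  den <- 2 * (N - 2)
  new_structure_coefficients(num / den, "cycle_exact", list(N = N, k = 2),
                             num = num, den = den)
}

# Auxiliary terms of the large-N pair/diffusion approximation for regular
# graphs of degree k >= 3. choose() already returns 0 outside 0 <= r <= n,
# which is exactly the convention the sums require.
upsilon_term <- function(l, j, k) {
  choose(k - 1 - l, k - 1 - j) / (k - 1)^(k - 1 - l) +
    choose(l, k - j) * (k - 2) / (k - 1)^l
}

tau_term <- function(l, j, k) {
  choose(k - 1 - l, k - j) * (k - 2) / (k - 1)^(k - 1 - l) +
    choose(l, k - 1 - j) / (k - 1)^l
}

#' Approximate structure coefficients of a large regular graph
#'
#' For regular graphs of degree `k >= 3` under Moran death-Birth updating,
#' the structure coefficients are approximated by a combination of pair
#' approximation and diffusion approximation, valid for large graphs
#' (`N >> k`) that are locally tree-like and for weak selection
#' (`w k << 1`). For `k = 3` the resulting normalized vector is
#' `(7, 31, 61, 45) / 144`. The approximation treats the graph as a Bethe
#' lattice, so it is systematically biased for graphs with many short loops
#' (rings with `k >= 4`, lattices).
#'
#' The vector satisfies the mean identity `sum(j * sigma_j) = (k + 1) / 2`,
#' which is what reduces the multiplayer sigma rule to the classical pairwise
#' condition on regular graphs when the game is a sum of two-player games.
#'
#' @param k Degree of the graph, at least 3 (for `k = 2` use
#'   [cycle_coefficients()], which is exact).
#' @return A `structure_coefficients` object with source `"regular_approx"`
#'   and `d = k + 1`.
#' @examples
#' regular_graph_coefficients(3)$sigma * 144
#' @export
regular_graph_coefficients <- function(k) {
  if (k < 3) stop("for k = 2 use cycle_coefficients(); the approximation needs k >= 3")
  j <- 0:k
  raw <- vapply(j, function(jj) {
    l <- 0:(k - 1)
    inner <- sum((k - l) * ((k^2 - (k - 2) * l) * upsilon_term(l, jj, k) +
                              (2 * k + (k - 2) * l) * tau_term(l, jj, k)))
    (k - 2)^(k - 1 - jj) * inner
  }, numeric(1))
  sigma <- raw / ((k + 2) * (k + 1) * k^2)
  # the prefactor already normalizes; renormalize to absorb rounding
  new_structure_coefficients(sigma / sum(sigma), "regular_approx",
                             list(k = k))
}

#' Cycle structure coefficients under overlapping (neighbor-centered) games
#'
#' When a focal player's payoff is the sum over `k + 1` games — one centered
#' on itself and one on each neighbor — rather than the single self-centered
#' game used elsewhere in this package, the structure coefficients of the
#' cycle become `((N+1), (2N-1), 3(N-3)) / (3(2N-3))`. For `N > 4` the
#' single-game coefficients dominate these in the containment order, i.e.
#' payoffs from a single game make cooperation strictly easier to favor.
#'
#' @param N Number of vertices, at least 4.
#' @return A `structure_coefficients` object with source
#'   `"cycle_overlapping"` and `d = 3`.
#' @export
cycle_overlapping_coefficients <- function(N) {
  if (N < 4) stop("graph too small: need N >= 4")
  num <- c(N + 1, 2 * N - 1, 3 * (N - 3))
  den <- 3 * (2 * N - 3)
  new_structure_coefficients(num / den, "cycle_overlapping",
                             list(N = N, k = 2), num = num, den = den)
}

#' Pairwise structure coefficient of a transitive graph
#'
#' Under delta-weak selection between two nearby mixed strategies, a single
#' structure coefficient suffices for any number of players. For transitive
#' graphs of size `N` and degree `k` under death-Birth updating it equals
#' `((k+1)N - 4k) / ((k-1)N)`, tending to `(k+1)/(k-1)` as `N -> Inf`.
#'
#' @param N Population size (`> k`), or `Inf`.
#' @param k Degree, at least 2.
#' @return A single number.
#' @seealso [scaled_relatedness()] for the inclusive-fitness transform.
#' @export
pairwise_sigma_transitive <- function(N, k) {
  if (k < 2) stop("degree k must be at least 2")
  if (is.infinite(N)) return((k + 1) / (k - 1))
  if (N <= k) stop("need N > k")
  ((k + 1) * N - 4 * k) / ((k - 1) * N)
}

#' Scaled relatedness coefficient of a transitive graph
#'
#' The inclusive-fitness transform `kappa = (sigma - 1) / (sigma + 1)` of the
#' pairwise structure coefficient; for transitive graphs under death-Birth
#' updating `kappa = (N - 2k) / (k (N - 2))`, tending to `1/k` for large `N`
#' and vanishing at `N = 2k`.
#'
#' @param N Population size (`> 2`), or `Inf`.
#' @param k Degree, at least 2.
#' @return A single number.
#' @export
scaled_relatedness <- function(N, k) {
  if (k < 2) stop("degree k must be at least 2")
  if (is.infinite(N)) return(1 / k)
  if (N <= 2) stop("need N > 2")
  (N - 2 * k) / (k * (N - 2))
}

#' Normalize a raw coefficient vector
#'
#' Divides a vector of nonnegative weights by its sum, yielding normalized
#' structure coefficients with source `"custom"`. Structure coefficients are
#' only determined up to a positive constant, so this normalization does not
#' affect which games satisfy the sigma rule.
#'
#' @param raw Numeric vector with nonnegative entries, at least one positive.
#' @return A `structure_coefficients` object.
#' @examples
#' normalize_coefficients(c(7, 31, 61, 45))
#' @export
normalize_coefficients <- function(raw) {
  raw <- as.numeric(raw)
  if (any(raw < 0)) stop("cannot normalize: negative entry")
  s <- sum(raw)
  if (s <= 0) stop("cannot normalize: all entries are zero")
  new_structure_coefficients(raw / s, "custom")
}

#' Expected number of co-players using the focal strategy
#'
#' Normalized structure coefficients define a probability distribution over
#' the number `J` of co-players playing the focal strategy; this returns its
#' mean `sum(j * sigma_j)`. For the regular-graph approximation the mean is
#' `(k + 1) / 2` for every degree `k`.
#'
#' @param sc A `structure_coefficients` object.
#' @return A single number, `E[J]`.
#' @export
mean_coplayers <- function(sc) {
  stopifnot(is_structure_coefficients(sc))
  sum(sc$sigma * (seq_len(sc$d) - 1))
}
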