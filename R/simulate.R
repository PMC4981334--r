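#' Payoff of a focal individual in a population state
#'
#' Each individual plays a single `d = k + 1`-player game with its `k`
#' neighbors: the focal payoff is `a[j]` for an `A`-player and `b[j]` for a
#' `B`-player, where `j` is the number of `A`-strategists among its
#' neighbors.
#'
#' @param vertex Vertex index (1-based).
#' @param state Integer vector of length `N`, 1 for strategy `A`, 0 for `B`.
#' @param game A [multiplayer_game()] with `d = k + 1`.
#' @param g A `regular_graph`.
#' @return The focal payoff, a single number.
#' @export
focal_payoff <- function(vertex, state, game, g) {
  check_group_size(game, g)
  j <- sum(state[g$adj[vertex, ]])
  if (state[vertex] == 1) game$a[j + 1] else game$b[j + 1]
}

check_group_size <- function(game, g) {
  if (game$d != g$k + 1)
    stop(sprintf("group-size mismatch: game has d = %d but graph degree k = %d needs d = %d",
                 game$d, g$k, g$k + 1))
  invisible(TRUE)
}

check_fitness_positivity <- function(game, w) {
  if (w < 0) stop("selection intensity w must be nonnegative")
  fmin <- 1 - w + w * min(c(game$a, game$b))
  if (fmin <= 0)
    stop(sprintf("fitness positivity violated: 1 - w + w * payoff reaches %g; reduce w", fmin))
  invisible(TRUE)
}

#' One step of the Moran death-Birth process
#'
#' A uniformly chosen individual dies; its `k` neighbors compete to place a
#' copy of themselves on the vacated vertex with probability proportional to
#' fitness `1 - w + w * payoff`. Neighbor payoffs are evaluated on the state
#' before the death, so the dying individual still counts in its neighbors'
#' groups. This is the R reference implementation; [fixation_probability()]
#' runs the same dynamics in compiled code.
#'
#' @param state Integer vector of strategies (1 = `A`, 0 = `B`).
#' @param game A [multiplayer_game()] with `d = k + 1`.
#' @param g A `regular_graph`.
#' @param w Selection intensity (`1 - w + w * payoff` must stay positive
#'   over the whole payoff table).
#' @return The updated state vector.
#' @export
db_step <- function(state, game, g, w) {
  check_group_size(game, g)
  check_fitness_positivity(game, w)
  die <- sample.int(g$N, 1)
  nb <- g$adj[die, ]
  j <- vapply(nb, function(v) sum(state[g$adj[v, ]]), numeric(1))
  pay <- ifelse(state[nb] == 1, game$a[j + 1], game$b[j + 1])
  fit <- 1 - w + w * pay
  chosen <- nb[sample.int(g$k, 1, prob = fit)]
  state[die] <- state[chosen]
  state
}

#' Estimate a fixation probability by Monte Carlo
#'
#' Runs independent realizations of the Moran death-Birth process, each
#' started from a single mutant placed at a uniformly random vertex, until
#' one of the two monomorphic absorbing states is reached, and estimates the
#' mutant's fixation probability as the fraction of runs in which it took
#' over. Under neutrality (`w = 0`) this probability is `1/N` on any graph.
#'
#' @param g A `regular_graph`.
#' @param game A [multiplayer_game()] with `d = k + 1`.
#' @param w Selection intensity.
#' @param runs Number of realizations.
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param mutant `"A"` (single `A` in a `B` population) or `"B"`.
#' @return A `fixation_estimate` with fields `rho`, `runs`, `fixations`,
#'   `stderr` (binomial standard error `sqrt(rho (1 - rho) / runs)`),
#'   `mutant`, and `mean_steps`, the mean number of effective updates per
#'   run (the compiled core skips deaths at vertices whose neighbors all
#'   share their strategy, which provably cannot change the state and so
#'   leave fixation probabilities untouched).
#' @examples
#' g <- make_ring(10, 2)
#' vd <- volunteers_dilemma(B = 3, C = 1, d = 3)
#' fixation_probability(g, vd, w = 0.01, runs = 2000, seed = 1)
#' @export
fixation_probability <- function(g, game, w, runs = 1e5, seed = NULL,
                                 mutant = c("A", "B")) {
  mutant <- match.arg(mutant)
  stopifnot(is_regular_graph(g), runs >= 1)
  check_group_size(game, g)
  check_fitness_positivity(game, w)
  if (!is.null(seed)) set.seed(seed)
  res <- run_fixation_cpp(g$adj, game$a, game$b, w, as.integer(runs),
                          mutant == "A")
  rho <- res$fixations / runs
  structure(list(rho = rho, runs = as.integer(runs),
                 fixations = as.integer(res$fixations),
                 stderr = sqrt(rho * (1 - rho) / runs),
                 mutant = mutant, mean_steps = res$mean_steps),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("fixation of a single %s mutant: rho = %.6g (+/- %.2g SE, %d/%d runs)\n",
              x$mutant, x$rho, x$stderr, x$fixations, x$runs))
  invisible(x)
}

#' @param x A `fixation_estimate`.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `mutant`, `rho`, `stderr`,
#'   `fixations`, `runs`.
#' @rdname fixation_probability
#' @exportS3Method generics::tidy
tidy.fixation_estimate <- function(x, ...) {
  tibble::tibble(mutant = x$mutant, rho = x$rho, stderr = x$stderr,
                 fixations = x$fixations, runs = x$runs)
}

#' Exact fixation probabilities from the full Markov chain
#'
#' For small graphs (`N <= 14`) the death-Birth process is a Markov chain on
#' the `2^N` strategy configurations with two absorbing states (all-`A`,
#' all-`B`). This builds the full transition matrix and solves the absorption
#' linear system exactly, providing an oracle against which both the Monte
#' Carlo simulator and the weak-selection theory can be tested.
#'
#' @param g A `regular_graph` with `N <= 14`.
#' @param game A [multiplayer_game()] with `d = k + 1`.
#' @param w Selection intensity.
#' @param mutant Which single-mutant average to report in
#'   `rho_single_mutant` (`"A"` or `"B"`); both are always returned.
#' @return An `exact_chain_result` with `prob_A_fixation` (per-state
#'   probability of absorption in all-`A`, indexed by the state bitmask + 1),
#'   `rho_A`, `rho_B` (averages over the `N` single-mutant states) and
#'   `rho_single_mutant`.
#' @examples
#' g <- make_ring(6, 2)
#' vd <- volunteers_dilemma(B = 3, C = 1, d = 3)
#' exact_fixation(g, vd, w = 0)$rho_A   # neutral: exactly 1/6
#' @export
exact_fixation <- function(g, game, w, mutant = c("A", "B")) {
  mutant <- match.arg(mutant)
  stopifnot(is_regular_graph(g))
  check_group_size(game, g)
  check_fitness_positivity(game, w)
  N <- g$N
  if (N > 14) stop("state space too large: exact chain supports N <= 14")
  nstates <- 2^N
  bits <- 2^(0:(N - 1))
  all_a <- nstates - 1L
  transient <- 1:(nstates - 2)          # state bitmasks 1 .. 2^N - 2

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  ri <- integer(0); rx <- numeric(0)    # direct jumps to all-A
  idx <- rep(NA_integer_, nstates)      # bitmask -> transient row
  idx[transient + 1L] <- seq_along(transient)

  for (s in transient) {
    st <- as.integer(bitwAnd(s, bits) > 0)
    row <- idx[s + 1L]
    for (die in seq_len(N)) {
      nb <- g$adj[die, ]
      j <- vapply(nb, function(v) sum(st[g$adj[v, ]]), numeric(1))
      pay <- ifelse(st[nb] == 1, game$a[j + 1], game$b[j + 1])
      fit <- 1 - w + w * pay
      p <- fit / sum(fit) / N
      snew <- ifelse(st[nb] == 1, bitwOr(s, bits[die]),
                     bitwAnd(s, bitwNot(bits[die])))
      for (e in seq_len(g$k)) {
        if (snew[e] == all_a) {
          ri <- c(ri, row); rx <- c(rx, p[e])
        } else if (snew[e] != 0) {
          ti <- c(ti, row); tj <- c(tj, idx[snew[e] + 1L]); tx <- c(tx, p[e])
        }
      }
    }
  }

  nt <- length(transient)
  Q <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(nt, nt))
  r <- as.vector(Matrix::sparseMatrix(i = ri, j = rep(1L, length(ri)), x = rx,
                                      dims = c(nt, 1)))
  x <- as.vector(Matrix::solve(Matrix::Diagonal(nt) - Q, r))

  prob <- numeric(nstates)
  prob[all_a + 1L] <- 1
  prob[transient + 1L] <- x
  single_a <- prob[bits + 1L]
  single_b <- 1 - prob[all_a - bits + 1L]
  rho_a <- mean(single_a)
  rho_b <- mean(single_b)
  structure(list(prob_A_fixation = prob, rho_A = rho_a, rho_B = rho_b,
                 rho_single_mutant = if (mutant == "A") rho_a else rho_b,
                 mutant = mutant, N = N, w = w),
            class = "exact_chain_result")
}

#' @export
print.exact_chain_result <- function(x, ...) {
  cat(sprintf("exact death-Birth chain (N = %d, w = %g): rho_A = %.8g, rho_B = %.8g\n",
              x$N, x$w, x$rho_A, x$rho_B))
  invisible(x)
}

#' Sweep fixation probabilities over a benefit-to-cost grid
#'
#' For each benefit-to-cost ratio on the grid, builds the requested
#' volunteer's dilemma (with or without cost sharing, cost fixed at `C`),
#' estimates the fixation probabilities of a single `A` mutant and a single
#' `B` mutant by Monte Carlo, and tabulates their difference. The sign of
#' `rho_A - rho_B` changes near the weak-selection critical ratio predicted
#' by [critical_bc_vd()] / [critical_bc_vd_cs()].
#'
#' @param g A `regular_graph`.
#' @param game_family `"vd"` or `"vd_cs"`.
#' @param bc_grid Numeric vector of benefit-to-cost ratios.
#' @param C Cost of cooperation (benefit is `bc * C`).
#' @param w Selection intensity.
#' @param runs Monte Carlo runs per grid point and mutant type.
#' @param seed Integer seed for the whole sweep.
#' @return A tibble of class `bc_sweep` with columns `bc`, `rho_A`,
#'   `stderr_A`, `rho_B`, `stderr_B`, `diff`.
#' @export
sweep_bc <- function(g, game_family = c("vd", "vd_cs"), bc_grid, C = 1,
                     w = 0.01, runs = 1e5, seed = 1) {
  game_family <- match.arg(game_family)
  stopifnot(is_regular_graph(g), all(bc_grid > 0), C > 0)
  maker <- if (game_family == "vd") volunteers_dilemma else vd_cost_sharing
  set.seed(seed)
  rows <- lapply(bc_grid, function(bc) {
    game <- maker(B = bc * C, C = C, d = g$k + 1)
    ea <- fixation_probability(g, game, w, runs, seed = NULL, mutant = "A")
    eb <- fixation_probability(g, game, w, runs, seed = NULL, mutant = "B")
    tibble::tibble(bc = bc, rho_A = ea$rho, stderr_A = ea$stderr,
                   rho_B = eb$rho, stderr_B = eb$stderr,
                   diff = ea$rho - eb$rho)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bc_sweep", class(out))
  attr(out, "game_family") <- game_family
  attr(out, "graph_family") <- g$family
  attr(out, "N") <- g$N
  attr(out, "k") <- g$k
  attr(out, "w") <- w
  attr(out, "runs") <- runs
  out
}

#' Plot a benefit-to-cost sweep
#'
#' Plots `rho_A - rho_B` against `B/C` with 3-standard-error bars and a
#' horizontal zero line; the empirical crossing marks the critical
#' benefit-to-cost ratio.
#'
#' @param object A `bc_sweep` from [sweep_bc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bc_sweep <- function(object, ...) {
  se <- sqrt(object$stderr_A^2 + object$stderr_B^2)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bc, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$diff - 3 * se,
                                          ymax = .data$diff + 3 * se)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "benefit-to-cost ratio B/C",
      y = expression(rho[A] - rho[B]),
      title = sprintf("%s on %s (N = %d, k = %d, w = %g)",
                      attr(object, "game_family"),
                      attr(object, "graph_family"),
                      attr(object, "N"), attr(object, "k"),
                      attr(object, "w")))
}

#' @importFrom ggplot2 .data
NULL
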