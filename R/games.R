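#' Construct a d-player two-strategy symmetric game
#'
#' A multiplayer game between two strategies, conventionally labelled `A`
#' (cooperate) and `B` (defect), is specified by two payoff vectors indexed
#' by the number of `A` co-players `j = 0, ..., d - 1` among the `d - 1`
#' opponents: an `A`-player facing `j` co-players who play `A` receives
#' `a[j + 1]`, a `B`-player in the same situation receives `b[j + 1]`.
#'
#' @param a Numeric vector of length `d`: payoffs to an `A`-player with
#'   `0, ..., d - 1` co-players playing `A`.
#' @param b Numeric vector of length `d`: payoffs to a `B`-player, indexed
#'   the same way.
#'
#' @return An object of class `multiplayer_game` with fields `d`, `a`, `b`.
#'
#' @examples
#' # volunteer's dilemma with benefit 3, cost 1, three players
#' g <- multiplayer_game(a = c(2, 2, 2), b = c(0, 3, 3))
#' gains_from_flipping(g)
#' @export
multiplayer_game <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b))
    stop("payoff vectors `a` and `b` must have the same length")
  d <- length(a)
  if (d < 2) stop("a multiplayer game needs d >= 2 players")
  if (anyNA(a) || anyNA(b)) stop("payoffs must not contain NA")
  structure(list(d = d, a = a, b = b), class = "multiplayer_game")
}

is_multiplayer_game <- function(x) inherits(x, "multiplayer_game")

#' @export
print.multiplayer_game <- function(x, ...) {
  cat(sprintf("%d-player symmetric game (two strategies)\n", x$d))
  m <- rbind(`payoff to A` = x$a, `payoff to B` = x$b)
  colnames(m) <- paste0("j=", seq_len(x$d) - 1)
  print(m)
  invisible(x)
}

#' Gains from flipping
#'
#' The payoff differences `f[j] = a[j] - b[d-1-j]`: the change in payoff
#' experienced by a focal `B`-player with `j` co-players playing `A` if every
#' player in the group simultaneously switched strategy. Under weak selection
#' the payoffs of the game enter the condition for `A` to be favored only
#' through this vector.
#'
#' @param game A [multiplayer_game()].
#' @return Numeric vector of length `d` with entries `f_0, ..., f_{d-1}`.
#' @export
gains_from_flipping <- function(game) {
  stopifnot(is_multiplayer_game(game))
  game$a - rev(game$b)
}

#' Test whether a game is a cooperation game
#'
#' A cooperation game is one in which the payoff of a focal player never
#' decreases with the number of co-players playing `A`, irrespective of the
#' focal player's own strategy: `a` and `b` are both nondecreasing in `j`
#' (ties allowed). Volunteer's dilemmas, snowdrift games and stag hunts all
#' belong to this class.
#'
#' @param game A [multiplayer_game()].
#' @return `TRUE` or `FALSE`.
#' @export
is_cooperation_game <- function(game) {
  stopifnot(is_multiplayer_game(game))
  all(diff(game$a) >= 0) && all(diff(game$b) >= 0)
}

#' Swap the roles of the two strategies
#'
#' Relabels `A` as `B` and vice versa: the payoff to the new `A`-player with
#' `j` new-`A` co-players is the payoff the old `B`-player got with
#' `d - 1 - j` old-`A` co-players. Useful for antisymmetry checks: the gains
#' from flipping of the swapped game are the entrywise negation of the
#' original's.
#'
#' @param game A [multiplayer_game()].
#' @return A [multiplayer_game()] with strategies exchanged.
#' @export
swap_strategies <- function(game) {
  stopifnot(is_multiplayer_game(game))
  multiplayer_game(a = rev(game$b), b = rev(game$a))
}

#' Multiplayer game from summed pairwise games
#'
#' Each individual plays the two-player matrix game
#' \deqn{\begin{pmatrix} \alpha & \beta \\ \gamma & \delta \end{pmatrix}}
#' with each of its `k` neighbors and collects the payoff sum, producing a
#' `(k+1)`-player game with `a[j] = j*alpha + (k-j)*beta` and
#' `b[j] = j*gamma + (k-j)*delta`.
#'
#' @param alpha,beta,gamma,delta Entries of the pairwise payoff matrix
#'   (`alpha`: A vs A, `beta`: A vs B, `gamma`: B vs A, `delta`: B vs B).
#' @param k Number of neighbors (group size is `d = k + 1`).
#' @return A [multiplayer_game()].
#' @export
game_from_pairwise <- function(alpha, beta, gamma, delta, k) {
  if (k < 1) stop("invalid degree: k must be at least 1")
  j <- 0:k
  multiplayer_game(a = j * alpha + (k - j) * beta,
                   b = j * gamma + (k - j) * delta)
}

#' Linear public-goods game
#'
#' Payoffs linear in the number of cooperating co-players: cooperators pay a
#' cost `C` to give a benefit `B/k` to each co-player and receive an extra
#' bonus `D/k` per other cooperator in the group;
#' `a[j] = -C + (B + D) j / k`, `b[j] = B j / k`. With `D = 0` this is the
#' additive prisoner's dilemma (the donation game summed over neighbors).
#'
#' @param B,C,D Benefit, cost and synergy/discount bonus.
#' @param k Number of neighbors (group size `d = k + 1`).
#' @return A [multiplayer_game()].
#' @export
linear_game <- function(B, C, D, k) {
  if (k < 1) stop("invalid degree: k must be at least 1")
  j <- 0:k
  multiplayer_game(a = -C + (B + D) * j / k, b = B * j / k)
}

#' Volunteer's dilemma
#'
#' A single cooperator suffices to produce a public good of value `B`; each
#' cooperator pays the full cost `C`. Payoffs: `a[j] = B - C` for all `j`,
#' `b[0] = 0`, `b[j] = B` for `j >= 1`.
#'
#' @param B Benefit of the public good.
#' @param C Cost of volunteering.
#' @param d Group size (at least 2).
#' @return A [multiplayer_game()].
#' @export
volunteers_dilemma <- function(B, C, d) {
  if (d < 2) stop("group size d must be at least 2")
  multiplayer_game(a = rep(B - C, d), b = c(0, rep(B, d - 1)))
}

#' Volunteer's dilemma with cost sharing
#'
#' As [volunteers_dilemma()], but the cost of producing the public good is
#' shared equally among the cooperators present: `a[j] = B - C/(j + 1)`.
#'
#' @inheritParams volunteers_dilemma
#' @return A [multiplayer_game()].
#' @export
vd_cost_sharing <- function(B, C, d) {
  if (d < 2) stop("group size d must be at least 2")
  j <- 0:(d - 1)
  multiplayer_game(a = B - C / (j + 1), b = c(0, rep(B, d - 1)))
}

#' Tidy a multiplayer game into a payoff table
#'
#' @param x A [multiplayer_game()].
#' @param ... Unused.
#' @return A tibble with columns `j`, `payoff_A`, `payoff_B`.
#' @exportS3Method generics::tidy
tidy.multiplayer_game <- function(x, ...) {
  tibble::tibble(j = seq_len(x$d) - 1L, payoff_A = x$a, payoff_B = x$b)
}

# --- serialization ---------------------------------------------------------

#' Read and write games as JSON or TSV
#'
#' Games serialize to a small JSON object `{d, a, b}` or to a two-row TSV
#' payoff table (rows `A` and `B`, one column per co-player count).
#'
#' @param game A [multiplayer_game()].
#' @param path File path; for the writers, omit to return the text.
#' @return Writers return `path` (or the serialized text) invisibly; readers
#'   return a [multiplayer_game()].
#' @name game-io
NULL

#' @rdname game-io
#' @export
game_to_json <- function(game, path = NULL) {
  stopifnot(is_multiplayer_game(game))
  txt <- jsonlite::toJSON(list(d = game$d, a = game$a, b = game$b),
                          auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname game-io
#' @export
game_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  g <- multiplayer_game(a = x$a, b = x$b)
  if (!is.null(x$d) && x$d != g$d) stop("inconsistent `d` in JSON game")
  g
}

#' @rdname game-io
#' @export
game_to_tsv <- function(game, path) {
  stopifnot(is_multiplayer_game(game))
  m <- data.frame(strategy = c("A", "B"), rbind(game$a, game$b))
  names(m)[-1] <- paste0("j", seq_len(game$d) - 1)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname game-io
#' @export
game_from_tsv <- function(path) {
  m <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  a <- as.numeric(m[m$strategy == "A", -1])
  b <- as.numeric(m[m$strategy == "B", -1])
  multiplayer_game(a = a, b = b)
}
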