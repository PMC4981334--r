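# Minimal exact rational arithmetic on machine integers (stored as doubles).
# Used for the closed-form structure coefficients and thresholds, whose
# numerators and denominators stay far below 2^53 for every supported N.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

lcm2 <- function(a, b) a / gcd2(a, b) * b

rat <- function(num, den = 1) {
  stopifnot(length(num) == 1, length(den) == 1, den != 0)
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- gcd2(num, den)
  if (g > 0) {
    num <- num / g
    den <- den / g
  }
  structure(list(num = num, den = den), class = "rat")
}

rat_add <- function(x, y) rat(x$num * y$den + y$num * x$den, x$den * y$den)
rat_mul <- function(x, y) rat(x$num * y$num, x$den * y$den)
rat_div <- function(x, y) {
  if (y$num == 0) stop("division by zero rational")
  rat(x$num * y$den, x$den * y$num)
}
rat_eq <- function(x, y) x$num == y$num && x$den == y$den

#' @export
as.numeric.rat <- function(x, ...) x$num / x$den

#' @export
format.rat <- function(x, ...) {
  if (x$den == 1) sprintf("%g", x$num) else sprintf("%g/%g", x$num, x$den)
}

#' @export
print.rat <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
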