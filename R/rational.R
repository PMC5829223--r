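#' Exact rational numbers
#'
#' A small vectorised rational-number class used for transmission-share
#' accounting, where results such as 1/4 or 1/(L_offspring * L_parent) must be
#' exact rather than floating point. Numerators and denominators are stored as
#' integer-valued doubles (exact up to 2^53, far beyond any ploidy product that
#' arises here) and kept in lowest terms with a positive denominator.
#'
#' @param num integer-valued numerators.
#' @param den integer-valued denominators (recycled if scalar); must be nonzero.
#' @return An object of class `rational`.
#' @examples
#' rational(1, 4) + rational(1, 4)  # 1/2
#' as.numeric(rational(3, 2))
#' @export
rational <- function(num, den = 1) {
  if (length(den) == 1L) den <- rep(den, length(num))
  stopifnot(length(num) == length(den))
  if (any(den == 0)) stop("zero denominator in rational()")
  if (any(num != round(num)) || any(den != round(den)))
    stop("rational() requires integer-valued numerators and denominators")
  .rat(round(num), round(den))
}

.gcd_vec <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b == 0, 0, a %% ifelse(b == 0, 1, b))
    a <- t
  }
  a
}

.rat <- function(num, den) {
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- .gcd_vec(num, den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

#' @export
is_rational <- function(x) inherits(x, "rational")

as_rational <- function(x) {
  if (is_rational(x)) return(x)
  if (is.character(x)) return(parse_rational(x))
  rational(x)
}

#' Parse rational strings
#'
#' Accepts strings such as `"1/4"`, `"-3/2"` or `"2"`.
#' @param x character vector.
#' @return A `rational` vector.
#' @export
parse_rational <- function(x) {
  parts <- strsplit(as.character(x), "/", fixed = TRUE)
  num <- vapply(parts, function(p) as.numeric(p[[1]]), 0)
  den <- vapply(parts, function(p) if (length(p) > 1) as.numeric(p[[2]]) else 1, 0)
  rational(num, den)
}

#' @export
Ops.rational <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(.rat(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not supported for rational")
  }
  e1 <- as_rational(e1); e2 <- as_rational(e2)
  switch(.Generic,
    "+" = .rat(e1$num * e2$den + e2$num * e1$den, e1$den * e2$den),
    "-" = .rat(e1$num * e2$den - e2$num * e1$den, e1$den * e2$den),
    "*" = .rat(e1$num * e2$num, e1$den * e2$den),
    "/" = {
      if (any(e2$num == 0)) stop("division by zero rational")
      .rat(e1$num * e2$den, e1$den * e2$num)
    },
    "==" = e1$num * e2$den == e2$num * e1$den,
    "!=" = e1$num * e2$den != e2$num * e1$den,
    "<"  = e1$num * e2$den <  e2$num * e1$den,
    "<=" = e1$num * e2$den <= e2$num * e1$den,
    ">"  = e1$num * e2$den >  e2$num * e1$den,
    ">=" = e1$num * e2$den >= e2$num * e1$den,
    stop(.Generic, " not supported for rational")
  )
}

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) .rat(x$num[i], x$den[i])

#' @export
as.double.rational <- function(x, ...) x$num / x$den

# as.numeric() dispatches through as.double(); keep an alias for direct calls
as.numeric.rational <- function(x, ...) x$num / x$den

#' @export
as.character.rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num), sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
format.rational <- function(x, ...) as.character(x)

#' @export
print.rational <- function(x, ...) {
  cat("<rational> ", paste(as.character(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
sum.rational <- function(..., na.rm = FALSE) {
  xs <- list(...)
  out <- rational(0)
  for (x in xs) {
    x <- as_rational(x)
    for (i in seq_len(length(x))) out <- out + x[i]
  }
  out
}
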