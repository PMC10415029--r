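#' Exact portion amounts
#'
#' Annotators record portion amounts either as decimals ("0.75") or as simple
#' fractions ("1/3", "2 1/2"). Amounts are held as exact rationals so that
#' subtracting a leftover from an initial amount introduces no floating-point
#' error: one cup minus one third of a cup is exactly two thirds of a cup.
#'
#' @param x a numeric vector, or a character vector of decimals, fractions
#'   ("n/d") or mixed numbers ("w n/d").
#' @return an `nc_amount` object: an exact rational with `numerator` and
#'   `denominator` attributes, convertible with [as.numeric()] and printable
#'   with [format()].
#' @examples
#' parse_amount("1/3")
#' as.numeric(parse_amount("1") - parse_amount("1/3")) # exactly 2/3
#' @export
parse_amount <- function(x) {
  if (inherits(x, "nc_amount")) return(x)
  if (is.numeric(x)) {
    bad <- !is.finite(x)
    if (any(bad)) stop("amounts must be finite numbers", call. = FALSE)
    return(decimal_to_amount(x))
  }
  x <- stringr::str_trim(as.character(x))
  num <- den <- numeric(length(x))
  for (i in seq_along(x)) {
    nd <- parse_one_amount(x[i])
    num[i] <- nd[1]
    den[i] <- nd[2]
  }
  new_amount(num, den)
}

# "2 1/2" -> 5/2; "1/3" -> 1/3; "0.75" -> 3/4; "1,000" -> 1000
parse_one_amount <- function(s) {
  s <- gsub(",", "", s, fixed = TRUE)
  if (grepl("^[+-]?[0-9]+\\s+[0-9]+\\s*/\\s*[0-9]+$", s)) {
    parts <- strsplit(s, "\\s+")[[1]]
    whole <- as.numeric(parts[1])
    frac <- strsplit(paste(parts[-1], collapse = ""), "/", fixed = TRUE)[[1]]
    n <- as.numeric(frac[1]); d <- as.numeric(frac[2])
    if (d == 0) stop("zero denominator in amount '", s, "'", call. = FALSE)
    sgn <- if (whole < 0) -1 else 1
    return(c(sgn * (abs(whole) * d + n), d))
  }
  if (grepl("^[+-]?[0-9]+\\s*/\\s*[0-9]+$", s)) {
    frac <- strsplit(gsub("\\s", "", s), "/", fixed = TRUE)[[1]]
    n <- as.numeric(frac[1]); d <- as.numeric(frac[2])
    if (d == 0) stop("zero denominator in amount '", s, "'", call. = FALSE)
    return(c(n, d))
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("cannot parse amount '", s, "'", call. = FALSE)
  a <- decimal_to_amount(v)
  c(attr(a, "numerator"), attr(a, "denominator"))
}

# exact: a finite decimal string/double with <= 9 decimal places maps to n/10^k
decimal_to_amount <- function(v) {
  den <- vapply(v, function(x) {
    for (k in 0:9) if (x * 10^k == round(x * 10^k)) return(10^k)
    NA_real_
  }, numeric(1))
  if (anyNA(den)) {
    # irregular doubles (no short decimal expansion) are kept as-is over 1;
    # arithmetic on them degrades gracefully to double precision
    den[is.na(den)] <- 1
  }
  new_amount(ifelse(den > 1, round(v * den), v), den)
}

new_amount <- function(num, den) {
  stopifnot(all(den > 0))
  g <- mapply(gcd2, abs(num), den)
  g[g == 0] <- 1
  # underlying data is the numeric value; exact num/den ride as attributes
  structure(num / den,
    numerator = num / g, denominator = den / g,
    class = "nc_amount"
  )
}

gcd2 <- function(a, b) {
  if (a != floor(a) || b != floor(b)) return(1)
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

amount_num <- function(a) attr(a, "numerator")
amount_den <- function(a) attr(a, "denominator")

#' @export
as.double.nc_amount <- function(x, ...) amount_num(x) / amount_den(x)

#' @export
format.nc_amount <- function(x, ...) {
  n <- amount_num(x)
  d <- amount_den(x)
  ifelse(d == 1, format(n, trim = TRUE),
    paste0(format(n, trim = TRUE), "/", format(d, trim = TRUE))
  )
}

#' @export
print.nc_amount <- function(x, ...) {
  cat("<amount>", format(x), "\n")
  invisible(x)
}

#' @export
Ops.nc_amount <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(new_amount(-amount_num(e1), amount_den(e1)))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for amounts", call. = FALSE)
  }
  a <- parse_amount(e1)
  b <- parse_amount(e2)
  n1 <- amount_num(a); d1 <- amount_den(a)
  n2 <- amount_num(b); d2 <- amount_den(b)
  switch(.Generic,
    "+" = new_amount(n1 * d2 + n2 * d1, d1 * d2),
    "-" = new_amount(n1 * d2 - n2 * d1, d1 * d2),
    "*" = new_amount(n1 * n2, d1 * d2),
    "/" = {
      if (any(n2 == 0)) stop("division by zero amount", call. = FALSE)
      new_amount(n1 * d2 * sign(n2), d1 * abs(n2))
    },
    "==" = n1 * d2 == n2 * d1,
    "!=" = n1 * d2 != n2 * d1,
    "<" = n1 * d2 < n2 * d1,
    "<=" = n1 * d2 <= n2 * d1,
    ">" = n1 * d2 > n2 * d1,
    ">=" = n1 * d2 >= n2 * d1,
    stop(.Generic, " not defined for amounts", call. = FALSE)
  )
}
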