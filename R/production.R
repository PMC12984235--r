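#' Production-curve shape
#'
#' Constructs the shape of the surplus production curve. The generalized
#' (Pella-Tomlinson) family is indexed by a dimensionless exponent `n`:
#' `n = 2` gives the symmetric Schaefer curve, the analytic limit `n -> 1`
#' gives the left-skewed Fox curve, and any other positive `n` a free
#' Pella-Tomlinson curve.
#'
#' @param mode One of `"schaefer"`, `"fox"`, `"pella_tomlinson"`.
#' @param n Shape exponent; ignored for `"schaefer"` (forced to 2) and
#'   `"fox"` (the limit is used analytically); required, positive and
#'   different from 1 for `"pella_tomlinson"`.
#' @return An object of class `production_shape`.
#' @examples
#' production_shape("schaefer")
#' production_shape("pella_tomlinson", n = 1.5)
#' @export
production_shape <- function(mode = c("schaefer", "fox", "pella_tomlinson"),
                             n = NULL) {
  mode <- match.arg(mode)
  if (mode == "schaefer") {
    n <- 2
  } else if (mode == "fox") {
    n <- NA_real_
  } else {
    if (is.null(n) || !is.finite(n) || n <= 0 || n == 1)
      stop("pella_tomlinson requires a shape exponent n > 0 and n != 1")
  }
  structure(list(mode = mode, n = n), class = "production_shape")
}

#' @export
print.production_shape <- function(x, ...) {
  cat("production shape:", x$mode,
      if (x$mode != "fox") sprintf("(n = %g)", x$n) else "(n -> 1 limit)", "\n")
  invisible(x)
}

is_fox <- function(shape) shape$mode == "fox"

check_shape <- function(shape) {
  if (!inherits(shape, "production_shape"))
    stop("'shape' must be a production_shape object")
  shape
}

check_pos <- function(..., .what = NULL) {
  args <- list(...)
  nm <- if (is.null(.what)) names(args) else .what
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("'%s' must be strictly positive and finite", nm[i]))
  }
  invisible(TRUE)
}

#' Shape constant of the generalized production curve
#'
#' Returns `gamma(n) = n^(n/(n-1)) / (n-1)`, the normalizing constant that
#' makes the peak of the production curve equal the maximum net productivity
#' `m`. It diverges as `n -> 1`; the Fox curve therefore never evaluates it
#' and uses the analytic limit inside [surplus_production()].
#'
#' @param shape A [production_shape()].
#' @return The positive scalar gamma.
#' @examples
#' production_gamma(production_shape("schaefer")) # 4
#' @export
production_gamma <- function(shape) {
  check_shape(shape)
  if (is_fox(shape) || isTRUE(shape$n == 1))
    stop("gamma undefined at the Fox limit")
  n <- shape$n
  n^(n / (n - 1)) / (n - 1)
}

#' Surplus production
#'
#' Net biomass production rate at biomass `B` for a population with maximum
#' net productivity `m` and carrying capacity `K`:
#' `gamma * m * (B/K) - gamma * m * (B/K)^n`, or the Fox limit
#' `e * m * (B/K) * log(K/B)`. The curve vanishes at `B = K`, is positive on
#' `(0, K)` and attains its maximum, exactly `m`, at `B = bmsy(K, shape)`.
#'
#' @param B Biomass (tonnes); vectorized.
#' @param m Maximum net productivity (tonnes / yr).
#' @param K Carrying capacity (tonnes).
#' @param shape A [production_shape()].
#' @return Production rate (tonnes / yr), same length as `B`.
#' @examples
#' surplus_production(1, m = 1, K = 4, production_shape("schaefer")) # 0.75
#' @export
surplus_production <- function(B, m, K, shape) {
  check_shape(shape)
  check_pos(B = B, m = m, K = K)
  x <- B / K
  if (is_fox(shape)) {
    exp(1) * m * x * log(1 / x)
  } else {
    g <- production_gamma(shape)
    g * m * x - g * m * x^shape$n
  }
}

#' Map intrinsic growth rate to maximum net productivity
#'
#' `m = r * K * n^(-n/(n-1))`; Schaefer: `rK/4`; Fox limit: `rK/e`.
#'
#' @param r Intrinsic growth rate (1 / yr).
#' @param K Carrying capacity (tonnes).
#' @param shape A [production_shape()].
#' @return Maximum net productivity (tonnes / yr).
#' @export
m_from_r <- function(r, K, shape) {
  check_shape(shape)
  check_pos(r = r, K = K)
  if (is_fox(shape)) return(r * K / exp(1))
  n <- shape$n
  r * K * n^(-n / (n - 1))
}

#' Map maximum net productivity to intrinsic growth rate
#'
#' Inverse of [m_from_r()]: returns `m * n^(n/(n-1)) / K`, i.e. Schaefer `4m/K`;
#' Fox limit `e m / K`.
#'
#' @param m Maximum net productivity (tonnes / yr).
#' @param K Carrying capacity (tonnes).
#' @param shape A [production_shape()].
#' @return Intrinsic growth rate (1 / yr).
#' @export
r_from_m <- function(m, K, shape) {
  check_shape(shape)
  check_pos(m = m, K = K)
  if (is_fox(shape)) return(exp(1) * m / K)
  n <- shape$n
  m * n^(n / (n - 1)) / K
}

#' Biomass at maximum sustainable yield
#'
#' `B_MSY = K * (1/n)^(1/(n-1))`; Schaefer `K/2`; Fox limit `K/e`.
#'
#' @param K Carrying capacity (tonnes).
#' @param shape A [production_shape()].
#' @return B_MSY (tonnes), always in (0, K).
#' @export
bmsy <- function(K, shape) {
  check_shape(shape)
  check_pos(K = K)
  if (is_fox(shape)) return(K / exp(1))
  n <- shape$n
  K * (1 / n)^(1 / (n - 1))
}

#' Fishing mortality at maximum sustainable yield
#'
#' `F_MSY = MSY / B_MSY = m / bmsy(K, shape)`. Under Schaefer this reduces
#' to `r/2`; at the Fox limit it equals `r` itself.
#'
#' @param m Maximum net productivity (tonnes / yr).
#' @param K Carrying capacity (tonnes).
#' @param shape A [production_shape()].
#' @return F_MSY (1 / yr).
#' @export
fmsy <- function(m, K, shape) {
  check_shape(shape)
  check_pos(m = m, K = K)
  msy(m) / bmsy(K, shape)
}

#' Maximum sustainable yield
#'
#' In the maximum-net-productivity parameterization MSY is `m` itself.
#'
#' @param m Maximum net productivity (tonnes / yr).
#' @return MSY (tonnes / yr).
#' @export
msy <- function(m) {
  check_pos(m = m)
  m
}
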