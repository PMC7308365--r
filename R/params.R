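#' Model parameters
#'
#' Bundles the reaction rates and neighborhood ranges of the niche-construction
#' particle system and checks their domains.
#'
#' The reactions, per site and in continuous time, are:
#' \itemize{
#'   \item extinction: an occupied site (NC or exploiter) becomes vacant at
#'     rate `delta`;
#'   \item destruction: every non-destroyed site becomes destroyed at rate `e`
#'     (patch lifetime `tau = 1/e`);
#'   \item colonization: a vacant site is colonized by NC at rate
#'     `(1-c)^alpha * n_NC(Z*) / |Z*|` and by the exploiter at rate
#'     `n_EX(Z*) / |Z*|`, where `Z*` is the Hamming ball of range `r_col`;
#'   \item construction: a destroyed site is renewed to vacant at rate
#'     `c * n_NC(Z) / |Z|`, `Z` the Hamming ball of range `r_con`
#'     (only NC constructs).
#' }
#'
#' The allocation `c` to construction is paid as a colonization discount
#' `(1-c)^alpha`; `alpha` sets the severity of the trade-off (with `alpha = 0`
#' construction is free). The exploiter is the plain contact process (`c = 0`),
#' sharing `delta`, `e` and the colonization range with NC.
#'
#' @param delta Extinction rate per occupied site (>= 0).
#' @param e Destruction rate per non-destroyed site (>= 0).
#' @param c Construction allocation in `[0, 1]`.
#' @param alpha Trade-off exponent (>= 0).
#' @param r_col Colonization range `r*` (integer >= 1; default 1, i.e. the
#'   four nearest neighbors).
#' @param r_con Construction range `r` (integer >= 1, or `Inf` for global
#'   construction over the whole lattice); defaults to `r_col`.
#' @param competition Enable the exploiter strategy (two-strategy model).
#' @return An object of class `model_params`.
#' @examples
#' model_params(delta = 0.1, e = 0.01, c = 0.4, alpha = 1)
#' @export
model_params <- function(delta = 0.1, e = 0, c = 0, alpha = 1,
                         r_col = 1, r_con = r_col, competition = FALSE) {
  stopifnot(
    "'delta' must be a single rate >= 0" =
      length(delta) == 1 && is.finite(delta) && delta >= 0,
    "'e' must be a single rate >= 0" =
      length(e) == 1 && is.finite(e) && e >= 0,
    "'c' must be a single value in [0, 1]" =
      length(c) == 1 && is.finite(c) && c >= 0 && c <= 1,
    "'alpha' must be a single value >= 0" =
      length(alpha) == 1 && is.finite(alpha) && alpha >= 0,
    "'r_col' must be an integer >= 1" =
      length(r_col) == 1 && is.finite(r_col) && r_col >= 1 && r_col == round(r_col),
    "'r_con' must be an integer >= 1 or Inf" =
      length(r_con) == 1 && !is.na(r_con) &&
        (is.infinite(r_con) || (r_con >= 1 && r_con == round(r_con))),
    "'competition' must be TRUE or FALSE" =
      isTRUE(competition) || isFALSE(competition)
  )
  structure(
    list(
      delta = as.numeric(delta), e = as.numeric(e), c = as.numeric(c),
      alpha = as.numeric(alpha), r_col = as.integer(r_col),
      r_con = if (is.infinite(r_con)) Inf else as.integer(r_con),
      competition = competition
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  con <- if (is.infinite(x$r_con)) "global" else sprintf("r=%d", x$r_con)
  cat(sprintf(
    "<model_params> delta=%g  e=%g  c=%g  alpha=%g  colonization r*=%d  construction %s%s\n",
    x$delta, x$e, x$c, x$alpha, x$r_col, con,
    if (x$competition) "  [+ exploiter]" else ""
  ))
  invisible(x)
}

# Colonization discount (1-c)^alpha with the 0^0 = 1 convention.
.beta_col <- function(params) (1 - params$c)^params$alpha
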