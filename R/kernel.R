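#' Negative-exponential dispersal kernel
#'
#' The probability that an individual disperses across a gap of `d` km is
#' modelled as a negative exponential, `p(d) = exp(-k d)`, anchored so that
#' `p(half_distance) = 0.5`, i.e. `k = ln(2) / half_distance`. The natural
#' anchor is the species' *median* dispersal distance: half of dispersal
#' events go further, half shorter.
#'
#' @param half_distance_km Distance (km) at which the dispersal probability
#'   is 0.5; must be > 0.
#' @return An object of class `dispersal_kernel`.
#' @examples
#' k <- dispersal_kernel(44)
#' dispersal_prob(k, c(0, 44, 88))  # 1, 0.5, 0.25
#' @export
dispersal_kernel <- function(half_distance_km) {
  stopifnot(is.numeric(half_distance_km), length(half_distance_km) == 1,
            is.finite(half_distance_km), half_distance_km > 0)
  structure(
    list(form = "neg_exponential",
         half_distance_km = half_distance_km,
         rate = log(2) / half_distance_km),
    class = "dispersal_kernel")
}

#' @rdname dispersal_kernel
#' @param kernel A `dispersal_kernel`.
#' @param d Distances in km (vector or matrix).
#' @export
dispersal_prob <- function(kernel, d) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  exp(-kernel$rate * d)
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat(sprintf("Negative-exponential dispersal kernel: p(d) = exp(-%.6g d),",
              x$rate),
      sprintf("p = 0.5 at %g km\n", x$half_distance_km))
  invisible(x)
}
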