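#' Response conventions
#'
#' Dose-response readouts arrive in four conventions: viability or inhibition,
#' each as a ratio (0-1) or a percentage (0-100). All analysis in this package
#' is carried out in a single canonical unit, percent inhibition; ingest
#' converts every response on the way in and the synthetic generator converts
#' on the way out, so the conversion path is exercised in both directions.
#'
#' @param quantity `"viability"` or `"inhibition"` - what the readout measures.
#' @param scale `"ratio"` (around 0-1) or `"percent"` (around 0-100).
#'
#' @return An object of class `response_convention`.
#' @examples
#' response_convention("viability", "ratio")
#' @export
response_convention <- function(quantity = c("inhibition", "viability"),
                                scale = c("percent", "ratio")) {
  quantity <- match.arg(quantity)
  scale <- match.arg(scale)
  structure(list(quantity = quantity, scale = scale),
            class = "response_convention")
}

#' @export
print.response_convention <- function(x, ...) {
  cat(sprintf("<response convention: %s, %s>\n", x$quantity, x$scale))
  invisible(x)
}

#' Convert responses to percent inhibition
#'
#' The canonical internal unit. Viability `v` (as a ratio) maps to
#' `(1 - v) * 100`; viability in percent to `100 - p`; an inhibition ratio is
#' scaled by 100; inhibition in percent is the identity. The map is total and
#' exactly invertible (see [from_percent_inhibition()]).
#'
#' @param value numeric vector of responses in the stated convention.
#' @param convention a [response_convention()].
#' @return numeric vector in percent inhibition. `NA` passes through (a blank
#'   replicate cell); any other non-finite value is an error.
#' @examples
#' to_percent_inhibition(0.25, response_convention("viability", "ratio"))  # 75
#' @export
to_percent_inhibition <- function(value, convention) {
  stopifnot(inherits(convention, "response_convention"))
  if (any(is.nan(value) | (!is.na(value) & !is.finite(value)))) {
    stop("non-finite response value (Inf/NaN) cannot be converted", call. = FALSE)
  }
  out <- if (convention$scale == "ratio") value * 100 else value
  if (convention$quantity == "viability") out <- 100 - out
  out
}

#' Convert percent inhibition back to a stated convention
#'
#' Exact inverse of [to_percent_inhibition()]; used by the synthetic-data
#' generator so fixtures land on disk in the requested convention.
#'
#' @inheritParams to_percent_inhibition
#' @param value numeric vector in percent inhibition.
#' @return numeric vector in the target convention.
#' @export
from_percent_inhibition <- function(value, convention) {
  stopifnot(inherits(convention, "response_convention"))
  if (any(is.nan(value) | (!is.na(value) & !is.finite(value)))) {
    stop("non-finite response value (Inf/NaN) cannot be converted", call. = FALSE)
  }
  out <- if (convention$quantity == "viability") 100 - value else value
  if (convention$scale == "ratio") out <- out / 100
  out
}
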