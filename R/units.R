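# Unit handling for configuration files.
#
# The package computes in SI base units (m, kg, s, N, Pa, F) throughout.
# Configuration files use the mixed micro-scale units that are conventional
# for surface-micromachined devices (um, uN um rad^-1, kg um^2, ...), each
# field tagged explicitly.  Conversion to SI happens exactly once, at load
# time, and back-conversion exactly once, at save time; nothing downstream
# ever sees a non-SI number.

# multiplicative factor unit -> SI
.unit_table <- c(
  m            = 1,
  mm           = 1e-3,
  um           = 1e-6,
  nm           = 1e-9,
  m2           = 1,
  um2          = 1e-12,
  rad          = 1,
  deg          = pi / 180,
  V            = 1,
  Hz           = 1,
  rad_s        = 1,
  Pa           = 1,
  kPa          = 1e3,
  MPa          = 1e6,
  GPa          = 1e9,
  Pa_s         = 1,
  kg_m3        = 1,
  kg_m2        = 1,
  kg_um2       = 1e-12,
  N_m_per_rad  = 1,
  uN_um_per_rad = 1e-12,
  N_per_m      = 1,
  uN_per_um    = 1,        # uN/um = 1e-6 N / 1e-6 m
  N            = 1,
  uN           = 1e-6,
  dimensionless = 1
)

#' Convert a tagged quantity to SI
#'
#' @param x either a bare number (assumed already in `default_unit`) or a
#'   list with elements `value` and `unit`.
#' @param default_unit unit assumed when `x` is untagged.
#' @param field field name used in error messages.
#' @return numeric scalar (or vector) in SI base units.
#' @keywords internal
to_si <- function(x, default_unit, field = deparse(substitute(x))) {
  if (is.list(x)) {
    if (is.null(x$value) || is.null(x$unit)) {
      stop("configuration field '", field,
           "' must be a number or a {value, unit} pair", call. = FALSE)
    }
    unit <- as.character(x$unit)
    val <- x$value
  } else {
    unit <- default_unit
    val <- x
  }
  if (!unit %in% names(.unit_table)) {
    stop("configuration field '", field, "' has unknown unit '", unit, "'",
         call. = FALSE)
  }
  if (!is.numeric(val)) {
    stop("configuration field '", field, "' is not numeric", call. = FALSE)
  }
  as.numeric(val) * .unit_table[[unit]]
}

#' Convert an SI value back to a tagged configuration unit
#' @keywords internal
from_si <- function(value, unit) {
  if (!unit %in% names(.unit_table)) {
    stop("unknown unit '", unit, "'", call. = FALSE)
  }
  list(value = value / .unit_table[[unit]], unit = unit)
}

.check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("field '", field, "' must be a positive finite number", call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("field '", field, "' must be non-negative and finite", call. = FALSE)
  }
  invisible(x)
}
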