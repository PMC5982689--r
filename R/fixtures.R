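# Synthetic fixtures: cell populations drawn from published reference
# distributions and noisy synthetic frequency-response "measurements" for
# exercising the inference stage.

# published reference moduli (Pa, mean and sd) and radii (m) of prostate
# cell lines measured by AFM
.cell_references <- data.frame(
  label = c("BHP", "PC-3", "LNCaP"),
  type = c("benign prostate cell", "malignant prostate cell",
           "malignant prostate cell"),
  E_mean = c(2797, 1401, 287),
  E_sd = c(491, 162, 52),
  R = c(10e-6, 10e-6, 10e-6),
  stringsAsFactors = FALSE
)

#' Reference cell table
#'
#' Mean and standard deviation of the elastic modulus, and radius, of the
#' reference prostate cell lines (benign BHP and malignant PC-3 / LNCaP)
#' used for population generation and classification.
#'
#' @return data.frame with columns `label`, `type`, `E_mean` (Pa),
#'   `E_sd` (Pa), `R` (m).
#' @export
cell_reference_table <- function() .cell_references

#' Generate a synthetic cell population
#'
#' Draws `n_cells` cells of the given type with elastic moduli from a
#' normal distribution with the reference mean and standard deviation,
#' truncated at zero (redrawing non-positive values), and the reference
#' radius.
#'
#' @param n_cells number of cells (>= 1).
#' @param type one of `"BHP"`, `"PC-3"`, `"LNCaP"`.
#' @param seed integer seed; the draw is reproducible.
#' @return list of [cell_model()] objects.
#' @export
make_cell_population <- function(n_cells, type, seed = 1L) {
  ref <- .cell_references[.cell_references$label == type, ]
  if (!nrow(ref)) {
    stop("unknown cell type '", type, "'; known: ",
         paste(.cell_references$label, collapse = ", "), call. = FALSE)
  }
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  E <- stats::rnorm(n_cells, ref$E_mean, ref$E_sd)
  while (any(E <= 0)) {
    E[E <= 0] <- stats::rnorm(sum(E <= 0), ref$E_mean, ref$E_sd)
  }
  lapply(E, function(e) cell_model(E_c = e, v = 0.5, R = ref$R,
                                   label = type))
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic noisy frequency-response measurement
#'
#' The ideal amplitude curve a capacitive read-out would report — the upper
#' stable branch of the Ritz steady-state response on the scenario's solver
#' grid — with multiplicative Gaussian amplitude noise of relative standard
#' deviation `noise_sd`.
#'
#' @param scn a `grip_scenario`.
#' @param noise_sd relative amplitude noise standard deviation (0 = ideal).
#' @param seed integer seed; the noise draw is reproducible.
#' @return data.frame with columns `frequency_hz`, `amplitude_rad`.
#' @export
make_synthetic_measurement <- function(scn, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(scn, "grip_scenario"))
  .check_nonneg(noise_sd, "noise_sd")
  resp <- sweep_response(scn)
  up <- .upper_stable(resp)
  amp <- up$c1
  if (noise_sd > 0) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
    amp <- amp * (1 + stats::rnorm(length(amp), 0, noise_sd))
  }
  data.frame(frequency_hz = up$frequency_hz, amplitude_rad = amp)
}
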