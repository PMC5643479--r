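# Physical model of DNA buoyant density in a CsCl gradient.

#' Buoyant-density model constants
#'
#' The equilibrium buoyant density (BD) of unlabeled DNA is modeled as a
#' linear function of GC content, `BD0 = intercept + gc_slope * GC`, the
#' classic CsCl relationship. Full heavy-isotope labeling adds an
#' isotope-specific maximal shift: 0.036 g/ml for \eqn{^{13}}C and
#' 0.016 g/ml for \eqn{^{15}}N (values standard in SIP methodology).
#' Partial labeling scales the shift by the atom fraction excess.
#'
#' @param intercept BD of GC = 0 DNA, g/ml.
#' @param gc_slope Increase in BD per unit GC fraction, g/ml.
#' @param shift_13c,shift_15n Maximal density shift at atom fraction
#'   excess 1, g/ml.
#' @return A named list of the four constants.
#' @export
bd_constants <- function(intercept = 1.660, gc_slope = 0.098,
                         shift_13c = 0.036, shift_15n = 0.016) {
  list(intercept = intercept, gc_slope = gc_slope,
       shift_13c = shift_13c, shift_15n = shift_15n)
}

#' Mean buoyant density of (partially) labeled DNA
#'
#' @param gc_content GC fraction in (0, 1); vectorized.
#' @param isotope `"none"`, `"13C"` or `"15N"`.
#' @param atom_excess Heavy-isotope atom fraction excess in \[0, 1\];
#'   vectorized (recycled against `gc_content`).
#' @param constants See [bd_constants()].
#' @return Mean buoyant density in g/ml, strictly increasing in both
#'   `gc_content` and (for a labeling isotope) `atom_excess`.
#' @examples
#' mean_buoyant_density(0.5, "none")        # 1.709
#' mean_buoyant_density(0.5, "13C", 1)      # 1.745
#' @export
mean_buoyant_density <- function(gc_content, isotope = c("none", "13C", "15N"),
                                 atom_excess = 0, constants = bd_constants()) {
  isotope <- match.arg(isotope)
  if (any(gc_content <= 0 | gc_content >= 1)) {
    abort("`gc_content` must lie strictly inside (0, 1).")
  }
  if (any(atom_excess < 0 | atom_excess > 1)) {
    abort("`atom_excess` must lie in [0, 1].")
  }
  shift_max <- switch(isotope,
    none = 0,
    `13C` = constants$shift_13c,
    `15N` = constants$shift_15n
  )
  constants$intercept + constants$gc_slope * gc_content + atom_excess * shift_max
}

# Validate a density-window table: columns low/high, densest-first,
# contiguous (each window's low is the next lighter window's high),
# non-overlapping.
assert_windows <- function(windows, require_contiguous = TRUE) {
  if (!is.data.frame(windows) || nrow(windows) == 0L) {
    abort("`windows` must be a non-empty data frame with `low` and `high` columns.")
  }
  if (!all(c("low", "high") %in% names(windows))) {
    abort("`windows` must have `low` and `high` columns (g/ml).")
  }
  if (any(windows$high <= windows$low)) {
    abort("Each window must have `high` > `low`.")
  }
  if (is.unsorted(rev(windows$high), strictly = TRUE)) {
    abort("Windows must be ordered densest-first (decreasing `high`).")
  }
  if (require_contiguous && nrow(windows) > 1L) {
    gaps <- windows$low[-nrow(windows)] - windows$high[-1L]
    if (any(abs(gaps) > 1e-9)) {
      abort("Windows must be contiguous: each `low` must equal the next lighter window's `high`.")
    }
  }
  invisible(windows)
}

#' Distribute a DNA band over density windows
#'
#' A taxon's DNA band is modeled as a Gaussian in density, centered on its
#' mean buoyant density with spread `sigma`. The mass collected in each
#' window is the Gaussian integral over that window, renormalized so the
#' proportions over the collected windows sum to 1 (DNA banding outside
#' the collected range is re-attributed proportionally, mirroring the fact
#' that all recovered DNA is in some fraction).
#'
#' @param mean_bd Mean buoyant density of the band, g/ml.
#' @param sigma Band spread (standard deviation), g/ml, > 0.
#' @param windows Data frame of contiguous density windows with `low` and
#'   `high` columns, ordered densest-first.
#' @return Numeric vector of mass proportions, one per window, summing to 1.
#' @export
band_fraction_masses <- function(mean_bd, sigma, windows) {
  stopifnot(length(mean_bd) == 1L, length(sigma) == 1L)
  if (sigma <= 0) abort("`sigma` must be > 0.")
  assert_windows(windows)
  mass <- pnorm(windows$high, mean_bd, sigma) - pnorm(windows$low, mean_bd, sigma)
  total <- sum(mass)
  if (total <= 0) {
    # band entirely outside the collected range at double precision: put all
    # mass in the nearest window
    nearest <- which.min(pmin(abs(windows$low - mean_bd), abs(windows$high - mean_bd)))
    mass <- rep(0, nrow(windows))
    mass[nearest] <- 1
    return(mass)
  }
  mass / total
}
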