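# Isotope algebra: delta-notation conversions, enrichment, trophic position.
# All delta values are in permil; ratios and atom fractions are dimensionless.

# Community reference ratios of the international scales.
.R_VPDB <- 0.0111802 # 13C/12C of Vienna Pee Dee Belemnite
.R_AIR <- 0.0036765 # 15N/14N of atmospheric N2

#' Isotope reference standard
#'
#' Defines the heavy/light isotope ratio of the reference scale used by
#' delta-notation: VPDB for carbon (13C/12C = 0.0111802) and atmospheric
#' N2 ("AIR") for nitrogen (15N/14N = 0.0036765).  The ratio can be
#' overridden, e.g. to use an updated consensus value.
#'
#' @param element "C" or "N".
#' @param r_std optional reference ratio; defaults to the community value
#'   for the element.
#' @return An object of class `iso_standard` with fields `element` and
#'   `r_std`.
#' @examples
#' iso_standard("C")$r_std
#' @export
iso_standard <- function(element = c("C", "N"), r_std = NULL) {
  element <- match.arg(element)
  if (is.null(r_std)) r_std <- switch(element, C = .R_VPDB, N = .R_AIR)
  if (!is.numeric(r_std) || length(r_std) != 1L || !is.finite(r_std) ||
      r_std <= 0) {
    stop("'r_std' must be a single positive finite number")
  }
  structure(list(element = element, r_std = r_std), class = "iso_standard")
}

.as_standard <- function(std) {
  if (inherits(std, "iso_standard")) return(std)
  if (is.character(std) && length(std) == 1L) return(iso_standard(std))
  stop("'std' must be an iso_standard or \"C\"/\"N\"")
}

#' Convert delta values to isotope ratios
#'
#' R = R_std * (1 + delta/1000).  Strictly increasing in delta; defined for
#' delta > -1000 permil (the ratio must stay positive).
#'
#' @param delta delta value(s) in permil.
#' @param std an [iso_standard()] or "C"/"N".
#' @return Heavy/light isotope ratio(s).
#' @export
delta_to_ratio <- function(delta, std = iso_standard("C")) {
  std <- .as_standard(std)
  if (any(delta <= -1000, na.rm = TRUE)) {
    stop("delta values must be greater than -1000 permil")
  }
  std$r_std * (1 + delta / 1000)
}

#' @rdname delta_to_ratio
#' @param ratio heavy/light isotope ratio(s), > 0.
#' @export
ratio_to_delta <- function(ratio, std = iso_standard("C")) {
  std <- .as_standard(std)
  if (any(ratio <= 0, na.rm = TRUE)) stop("ratios must be positive")
  1000 * (ratio / std$r_std - 1)
}

#' Convert delta values to fractional isotopic abundance
#'
#' The atom fraction F = R/(1+R) of the heavy isotope is the linear mixing
#' space for mass-balance calculations on pooled samples.
#'
#' @inheritParams delta_to_ratio
#' @return Atom fraction(s) in (0, 1).
#' @export
delta_to_atom_fraction <- function(delta, std = iso_standard("C")) {
  r <- delta_to_ratio(delta, std)
  r / (1 + r)
}

#' @rdname delta_to_atom_fraction
#' @param f atom fraction(s) in (0, 1).
#' @export
atom_fraction_to_delta <- function(f, std = iso_standard("C")) {
  if (any(f <= 0 | f >= 1, na.rm = TRUE)) {
    stop("atom fractions must lie strictly between 0 and 1")
  }
  ratio_to_delta(f / (1 - f), std)
}

#' Trophic 15N enrichment
#'
#' Delta-15N of a consumer relative to its diet (consumer minus diet).
#'
#' @param consumer_d15n,diet_d15n absolute delta-15N values in permil.
#' @return Enrichment in permil.
#' @export
enrichment <- function(consumer_d15n, diet_d15n) {
  consumer_d15n - diet_d15n
}

#' Trophic position from 15N enrichment
#'
#' TP = enrichment / tef_n, using the canonical 3.4 permil enrichment per
#' trophic transfer.
#'
#' @param enrichment delta-15N enrichment over the baseline, permil.
#' @param tef_n enrichment factor per trophic level, permil (> 0).
#' @return Dimensionless trophic position (0 = baseline resource).
#' @examples
#' trophic_position(16.7) # about 4.91
#' @export
trophic_position <- function(enrichment, tef_n = 3.4) {
  if (!is.numeric(tef_n) || length(tef_n) != 1L || !is.finite(tef_n) ||
      tef_n <= 0) {
    stop("'tef_n' must be a single positive number")
  }
  enrichment / tef_n
}

#' Span of a set of isotope values
#'
#' @param values numeric vector (at least one finite value), permil.
#' @return max - min, permil.
#' @export
mean_span <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop("'values' must contain at least one finite value")
  max(values) - min(values)
}

#' Approximate number of trophic levels covered by an enrichment span
#'
#' Divides the delta-15N span by the per-level enrichment factor and rounds
#' half up (span 16 at 3.4 permil per level gives 5 levels).
#'
#' @param span delta-15N span, permil (>= 0).
#' @param tef_n enrichment factor per trophic level, permil (> 0).
#' @return Integer number of levels.
#' @export
n_trophic_levels <- function(span, tef_n = 3.4) {
  if (!is.numeric(span) || any(span < 0)) stop("'span' must be >= 0")
  if (!is.numeric(tef_n) || length(tef_n) != 1L || tef_n <= 0) {
    stop("'tef_n' must be a single positive number")
  }
  as.integer(floor(span / tef_n + 0.5))
}
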