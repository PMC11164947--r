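# Biomass-weighted mass-balance deconvolution of pooled isotope samples.
#
# A pooled measurement of several components obeys, in atom-fraction space,
#   m_pool * F_pool = sum_i m_i * F_i,    m_pool = sum_i m_i,
# where m_i are component dry masses and F_i fractional isotopic
# abundances.  When every F_i but one is known, the unknown component's
# signal can be recovered exactly (e.g. fungal-feeding nematodes pooled
# with bacterial feeders of known signature).

#' Pooled-sample observation
#'
#' @param biomass dry masses of the components, micrograms (> 0, length
#'   >= 2).
#' @param f fractional isotopic abundances of the components; exactly one
#'   entry must be `NA` (the unknown component), all others in (0, 1).
#' @param f_pool fractional abundance measured on the pooled sample, in
#'   (0, 1).
#' @param element "C" or "N".
#' @param labels optional component labels.
#' @return An object of class `pool_observation`.
#' @export
pool_observation <- function(biomass, f, f_pool, element = c("C", "N"),
                             labels = NULL) {
  element <- match.arg(element)
  if (length(biomass) < 2L) stop("need at least two pooled components")
  if (length(f) != length(biomass)) {
    stop("'biomass' and 'f' must have the same length")
  }
  if (any(!is.finite(biomass)) || any(biomass <= 0)) {
    stop("degenerate pool: every component biomass must be > 0")
  }
  unknown <- which(is.na(f))
  if (length(unknown) != 1L) {
    stop("exactly one component must have unknown f (one NA)")
  }
  known <- f[-unknown]
  if (any(known <= 0 | known >= 1)) {
    stop("known atom fractions must lie strictly in (0, 1)")
  }
  if (!is.finite(f_pool) || f_pool <= 0 || f_pool >= 1) {
    stop("'f_pool' must lie strictly in (0, 1)")
  }
  if (is.null(labels)) labels <- paste0("component_", seq_along(biomass))
  structure(
    list(biomass = as.numeric(biomass), f = as.numeric(f),
         f_pool = as.numeric(f_pool), element = element,
         labels = as.character(labels), unknown = unknown),
    class = "pool_observation"
  )
}

#' Forward biomass-weighted mixing of component signals
#'
#' @param biomass component dry masses (> 0).
#' @param f component atom fractions (all known).
#' @return Pooled atom fraction, sum(m * f) / sum(m).
#' @export
mix_pool <- function(biomass, f) {
  if (length(biomass) != length(f)) stop("length mismatch")
  if (any(biomass <= 0)) stop("biomasses must be > 0")
  sum(biomass * f) / sum(biomass)
}

.unmix_raw <- function(obs) {
  u <- obs$unknown
  m_pool <- sum(obs$biomass)
  (m_pool * obs$f_pool - sum(obs$biomass[-u] * obs$f[-u])) / obs$biomass[u]
}

#' Recover the unknown component's atom fraction from a pooled measurement
#'
#' Inverts the two-(or more-)pool mass-balance equation.  A result outside
#' (0, 1) signals measurement incompatibility and raises a classed error
#' (`isoweb_unmix_inconsistency`) carrying the raw value in its `value`
#' field rather than silently clamping.
#'
#' @param obs a [pool_observation()].
#' @return The unknown component's atom fraction, in (0, 1).
#' @export
unmix_pool <- function(obs) {
  stopifnot(inherits(obs, "pool_observation"))
  f_u <- .unmix_raw(obs)
  if (f_u <= 0 || f_u >= 1) {
    cond <- structure(
      class = c("isoweb_unmix_inconsistency", "error", "condition"),
      list(
        message = sprintf(
          "deconvolved atom fraction %.6g lies outside (0, 1); pooled measurement is inconsistent with the known components",
          f_u
        ),
        call = sys.call(-1), value = f_u
      )
    )
    stop(cond)
  }
  f_u
}

#' Mass-balance deconvolution in delta space
#'
#' Convenience wrapper: converts known component deltas and the pooled
#' delta to atom fractions, applies [unmix_pool()], and converts the result
#' back.  Mixing is always performed in atom-fraction space, never as a
#' linear combination of delta values.
#'
#' @param biomass component dry masses, micrograms.
#' @param delta component delta values, permil; exactly one `NA` marks the
#'   unknown component.
#' @param delta_pool delta value measured on the pooled sample, permil.
#' @param element "C" or "N".
#' @param labels optional component labels.
#' @return Delta value of the unknown component, permil.
#' @examples
#' # equal signals are invariant under pooling
#' unmix_pool_delta(c(48.5, 105.8), c(-20, NA), -20, "C") # -20
#' @export
unmix_pool_delta <- function(biomass, delta, delta_pool,
                             element = c("C", "N"), labels = NULL) {
  element <- match.arg(element)
  std <- iso_standard(element)
  f <- ifelse(is.na(delta), NA_real_, delta_to_atom_fraction(delta, std))
  obs <- pool_observation(biomass, f, delta_to_atom_fraction(delta_pool, std),
                          element = element, labels = labels)
  atom_fraction_to_delta(unmix_pool(obs), std)
}

#' First-order uncertainty of a pool deconvolution
#'
#' Delta-method SD of the unknown component's atom fraction given SDs on
#' the pooled measurement, the known component signals, and the component
#' biomasses.  With F_u = (m_pool F_pool - sum m_i F_i) / m_u the
#' sensitivities are m_pool/m_u (pooled signal), -m_i/m_u (known signals),
#' (F_pool - F_i)/m_u (known biomasses) and (F_pool - F_u)/m_u (unknown
#' biomass).
#'
#' @param obs a [pool_observation()].
#' @param sd_f_pool SD of the pooled atom fraction (>= 0).
#' @param sd_f SDs of the component atom fractions (recycled; the entry
#'   for the unknown component is ignored).
#' @param sd_biomass SDs of the component biomasses (recycled).
#' @return SD of the deconvolved atom fraction; zero when all inputs are
#'   exact.
#' @export
propagate_unmix_sd <- function(obs, sd_f_pool = 0, sd_f = 0,
                               sd_biomass = 0) {
  stopifnot(inherits(obs, "pool_observation"))
  k <- length(obs$biomass)
  sd_f <- rep_len(sd_f, k)
  sd_biomass <- rep_len(sd_biomass, k)
  if (sd_f_pool < 0 || any(sd_f < 0) || any(sd_biomass < 0)) {
    stop("SDs must be >= 0")
  }
  u <- obs$unknown
  m_u <- obs$biomass[u]
  m_pool <- sum(obs$biomass)
  f_u <- .unmix_raw(obs)
  g_pool <- m_pool / m_u
  g_f <- -obs$biomass / m_u # known signals
  g_m <- (obs$f_pool - obs$f) / m_u # known biomasses
  g_m[u] <- (obs$f_pool - f_u) / m_u
  var_out <- (g_pool * sd_f_pool)^2 +
    sum((g_f[-u] * sd_f[-u])^2) +
    sum((g_m * sd_biomass)^2)
  sqrt(var_out)
}
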