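# Unit contract: 1 MPa == 1 pN/nm^2 exactly, so with E in MPa and all
# lengths converted to nm, k = (3/4) pi E r^4 / L^3 comes out in pN/nm
# with no extra factor.
NM_PER_UM <- 1000

#' @describeIn springConstant spring constant from a PillarGeometry.
#'
#' The pilus is a clamped elastic cylinder loaded laterally at its tip;
#' beam bending gives k = (3/4) * pi * E * r^4 / L^3. With the modulus in
#' MPa (= pN/nm^2) and r, L in micrometres the result is returned in
#' pN/nm.
#' @export
setMethod("springConstant", "PillarGeometry", function(geom, ...) {
  validObject(geom)
  r_nm <- geom@r * NM_PER_UM
  L_nm <- geom@L * NM_PER_UM
  0.75 * pi * geom@E * r_nm^4 / L_nm^3
})

#' @describeIn springConstant numeric convenience: E (MPa), r and L (um).
#' @param r,L pilus radius and length, micrometres.
#' @export
setMethod("springConstant", "numeric", function(geom, r, L, ...) {
  springConstant(PillarGeometry(E = geom, r = r, L = L))
})

#' Convert pilus deflections to restoring forces via Hooke's law
#'
#' F = k d for a linear spring; the restoring force is reported as a
#' positive magnitude (the sign only encodes that the force opposes the
#' deflection).
#'
#' @param d deflection magnitude(s), nm. A [measureDeflection()] result
#'   (or any list/data.frame with a \code{d_magnitude} element) is also
#'   accepted.
#' @param spring a [PillarGeometry-class], or the spring constant k in
#'   pN/nm directly.
#' @param unit "nN" (default) or "pN".
#' @return force magnitude(s) in the requested unit.
#' @examples
#' k <- springConstant(PillarGeometry())   # ~251 pN/nm
#' deflectionToForce(252, k)               # ~63 nN
#' @export
deflectionToForce <- function(d, spring, unit = c("nN", "pN")) {
  unit <- match.arg(unit)
  if (is.list(d) && !is.null(d$d_magnitude)) d <- d$d_magnitude
  d <- as.numeric(d)
  if (any(d < 0, na.rm = TRUE)) stop("deflection magnitudes must be >= 0")
  k <- if (is(spring, "PillarGeometry")) springConstant(spring) else as.numeric(spring)
  if (k <= 0) stop("spring constant must be > 0")
  f_pN <- abs(k * d)
  if (unit == "nN") f_pN / 1000 else f_pN
}
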