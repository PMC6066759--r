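# Tip-apex distance (TAD) and predicted cut-out rate (COR).
#
# TAD is the clinical predictor of sliding-screw cut-out: the sum over
# the AP and lateral radiographs of the tip-to-apex distance, each
# corrected for radiographic magnification. The standard correction uses
# the known true guide-wire diameter: distances measured in pixels are
# scaled by d_true_mm / d_apparent_px in that plane. When the apparent
# diameter is not measured, a plane's mm-per-pixel scale is used instead.

#' Compute the tip-apex distance (TAD)
#'
#' `TAD = X_ap * (D_true / D_ap) + X_lat * (D_true / D_lat)` where `X` is
#' the Euclidean tip-to-apex pixel distance in a plane and `D` the
#' apparent wire diameter in pixels there. Either `d_app_*` (with
#' `d_true_mm`) or `mm_per_px_*` must be supplied per plane; the
#' diameter-based correction takes precedence.
#'
#' @param tip_ap,apex_ap wire tip and femoral-head apex in the AP
#'   radiograph, `c(x, y)` pixels.
#' @param tip_lat,apex_lat the same in the cross-table lateral plane.
#' @param d_app_ap,d_app_lat apparent wire diameter in pixels (> 0).
#' @param d_true_mm true wire diameter in mm (> 0); required with the
#'   diameter-based correction.
#' @param mm_per_px_ap,mm_per_px_lat fallback plane scales (> 0).
#' @return A list with `tad_mm`, `ap_component_mm`, `lat_component_mm`
#'   (`tad_mm` is their sum).
#' @examples
#' # 40 px at 4 px apparent / 2.5 mm true, plus 30 px at 3 px apparent
#' compute_tad(c(0, 0), c(40, 0), c(0, 0), c(0, 30),
#'             d_app_ap = 4, d_app_lat = 3, d_true_mm = 2.5)$tad_mm  # 50
#' @export
compute_tad <- function(tip_ap, apex_ap, tip_lat, apex_lat,
                        d_app_ap = NULL, d_app_lat = NULL,
                        d_true_mm = NULL,
                        mm_per_px_ap = NULL, mm_per_px_lat = NULL) {
  ap <- plane_mm(tip_ap, apex_ap, d_app_ap, d_true_mm, mm_per_px_ap, "AP")
  lat <- plane_mm(tip_lat, apex_lat, d_app_lat, d_true_mm, mm_per_px_lat,
                  "lateral")
  list(tad_mm = ap + lat, ap_component_mm = ap, lat_component_mm = lat)
}

plane_mm <- function(tip, apex, d_app, d_true_mm, mm_per_px, plane) {
  ft_assert_finite(tip, "tip"); ft_assert_finite(apex, "apex")
  px <- sqrt(sum((as.numeric(tip) - as.numeric(apex))^2))
  if (!is.null(d_app)) {
    if (d_app <= 0)
      ft_stop(sprintf("apparent wire diameter in %s plane must be > 0", plane),
              "fluorotrack_nonpositive_diameter")
    if (is.null(d_true_mm) || d_true_mm <= 0)
      ft_stop("d_true_mm must be > 0 with the diameter-based correction",
              "fluorotrack_nonpositive_diameter")
    return(px * d_true_mm / d_app)
  }
  if (is.null(mm_per_px) || mm_per_px <= 0)
    ft_stop(sprintf("%s plane needs d_app (+ d_true_mm) or mm_per_px > 0",
                    plane), "fluorotrack_invalid_input")
  px * mm_per_px
}

#' Calibrate the logistic TAD-to-cut-out-risk curve
#'
#' The cut-out risk curve is modeled as a two-parameter logistic on the
#' logit scale, `COR(t) = 100 * plogis(a + b t)`, pinned exactly through
#' two (TAD mm, COR %) anchor pairs. With distinct anchors the two logit
#' equations have a unique solution; risk must increase with TAD
#' (`b > 0`), otherwise (or with equal TADs or probabilities) a
#' `fluorotrack_degenerate_anchors` condition is raised.
#'
#' @param anchor_lo,anchor_hi `c(tad_mm, cor_pct)` pairs with
#'   `cor_pct` strictly inside `(0, 100)`.
#' @return A `cutout_curve` list with logit-scale intercept `a` and slope
#'   `b` (per mm).
#' @export
calibrate_cutout_curve <- function(anchor_lo, anchor_hi) {
  ft_assert_finite(anchor_lo, "anchor_lo")
  ft_assert_finite(anchor_hi, "anchor_hi")
  t <- c(anchor_lo[1], anchor_hi[1]); p <- c(anchor_lo[2], anchor_hi[2])
  if (any(p <= 0 | p >= 100))
    ft_stop("anchor probabilities must lie strictly in (0, 100)%",
            "fluorotrack_degenerate_anchors")
  if (t[1] == t[2] || p[1] == p[2])
    ft_stop("anchors must have distinct TADs and distinct probabilities",
            "fluorotrack_degenerate_anchors")
  b <- (qlogis(p[2] / 100) - qlogis(p[1] / 100)) / (t[2] - t[1])
  if (b <= 0)
    ft_stop("cut-out risk must increase with TAD (slope <= 0)",
            "fluorotrack_degenerate_anchors")
  a <- qlogis(p[1] / 100) - b * t[1]
  structure(list(a = a, b = b), class = "cutout_curve")
}

#' Default cut-out curve
#'
#' Calibrated to the two extreme published cohort-median anchor pairs,
#' (24 mm, 2.6%) and (47 mm, 55%). The resulting curve evaluates at
#' 28 mm to about 4.9%, consistent with the published intermediate pair.
#'
#' @return A `cutout_curve`.
#' @export
default_cutout_curve <- function() {
  calibrate_cutout_curve(c(24, 2.6), c(47, 55))
}

#' Predicted cut-out rate from TAD
#'
#' @param curve a [calibrate_cutout_curve()] result.
#' @param tad_mm tip-apex distance in mm (vectorized, >= 0).
#' @return Cut-out rate in percent, strictly increasing in `tad_mm`,
#'   bounded in (0, 100).
#' @export
cor_from_tad <- function(curve, tad_mm) {
  ft_assert_finite(tad_mm, "tad_mm")
  if (any(tad_mm < 0))
    ft_stop("tad_mm must be >= 0", "fluorotrack_invalid_input")
  100 * plogis(curve$a + curve$b * tad_mm)
}

#' Score a standalone annotation file
#'
#' Reads a JSON annotation `{AP: {tip, apex, d_app_px?, mm_per_px?},
#' CTL: {...}, d_true_mm?}` and returns the TAD/COR report. COR is
#' rounded to 1 decimal place, matching the reporting precision of the
#' published cohort tables.
#'
#' @param path annotation JSON file.
#' @param curve cut-out curve (default [default_cutout_curve()]).
#' @return A list with `tad_mm`, `ap_component_mm`, `lat_component_mm`,
#'   `cor_pct`.
#' @export
score_annotation <- function(path, curve = default_cutout_curve()) {
  obj <- jsonlite::fromJSON(path)
  tad <- compute_tad(
    tip_ap = obj$AP$tip, apex_ap = obj$AP$apex,
    tip_lat = obj$CTL$tip, apex_lat = obj$CTL$apex,
    d_app_ap = obj$AP$d_app_px, d_app_lat = obj$CTL$d_app_px,
    d_true_mm = obj$d_true_mm,
    mm_per_px_ap = obj$AP$mm_per_px, mm_per_px_lat = obj$CTL$mm_per_px)
  c(tad, list(cor_pct = round(cor_from_tad(curve, tad$tad_mm), 1)))
}
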