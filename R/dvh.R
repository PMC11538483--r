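#' Cumulative dose-volume histogram for one ROI
#'
#' Stores the ROI's per-voxel dose sample and voxel volume; metrics are
#' read off the cumulative curve with linear interpolation between
#' sorted voxel doses (midpoint plotting positions `(i - 1/2) / n`,
#' clamped to min/max dose at the ends).
#'
#' @param doses numeric vector of per-voxel dose (Gy).
#' @param voxel_cc volume of one voxel in cc.
#' @param roi ROI name (metadata).
#' @return a `dvh_curve`.
#' @export
dvh_curve <- function(doses, voxel_cc, roi = "") {
  doses <- as.numeric(doses)
  if (!length(doses)) stop("empty dose sample")
  if (any(!is.finite(doses)) || any(doses < -1e-9)) stop("doses must be finite and >= 0")
  structure(list(doses = sort(doses), voxel_cc = voxel_cc, roi = roi),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat("<dvh_curve> ", x$roi, ": ", length(x$doses), " voxels (",
      signif(length(x$doses) * x$voxel_cc, 4), " cc), Dmean ",
      signif(mean(x$doses), 4), " Gy\n", sep = "")
  invisible(x)
}

#' Evaluate the cumulative DVH: volume fraction receiving >= dose
#' @param curve a `dvh_curve`.
#' @param dose_gy dose values (Gy).
#' @return percent of ROI volume receiving at least each dose.
#' @export
dvh_volume_at <- function(curve, dose_gy) {
  n <- length(curve$doses)
  vapply(dose_gy, function(d) 100 * sum(curve$doses >= d) / n, numeric(1))
}

#' DVH metrics
#'
#' Supported queries: `Dx%` (dose to the hottest x% of the volume),
#' `Dycc` (dose to the hottest y cc), `VxGy` (percent volume receiving
#' at least x Gy), and `Dmean`.  `D100%` is the minimum and `D0%` the
#' maximum dose.
#'
#' @param curve a `dvh_curve`.
#' @param query a string such as `"D98%"`, `"D0.04cc"`, `"V30Gy"`,
#'   `"Dmean"` (or a vector for `dvh_metrics`).
#' @return metric value (Gy for D-metrics, percent for V-metrics).
#' @export
dvh_metric <- function(curve, query) {
  d <- curve$doses; n <- length(d)
  if (query == "Dmean") return(mean(d))
  if (grepl("^D[0-9.]+%$", query)) {
    x <- as.numeric(sub("^D([0-9.]+)%$", "\\1", query))
    if (x < 0 || x > 100) stop("Dx% requires x in [0, 100]")
    return(dose_at_fraction(d, x / 100))
  }
  if (grepl("^D[0-9.]+cc$", query)) {
    y <- as.numeric(sub("^D([0-9.]+)cc$", "\\1", query))
    vol <- n * curve$voxel_cc
    if (y > vol) stop("query volume ", y, " cc exceeds ROI volume ",
                      signif(vol, 4), " cc")
    return(dose_at_fraction(d, y / vol))
  }
  if (grepl("^V[0-9.]+Gy$", query)) {
    x <- as.numeric(sub("^V([0-9.]+)Gy$", "\\1", query))
    return(dvh_volume_at(curve, x))
  }
  stop("unknown DVH query: ", query)
}

#' @rdname dvh_metric
#' @export
dvh_metrics <- function(curve, query) {
  vapply(query, dvh_metric, numeric(1), curve = curve)
}

# dose received by at least fraction p of the volume: interpolate the
# descending-sorted doses at plotting positions (i - 1/2) / n
dose_at_fraction <- function(sorted_asc, p) {
  n <- length(sorted_asc)
  desc <- rev(sorted_asc)
  if (n == 1) return(desc[1])
  pos <- (seq_len(n) - 0.5) / n
  stats::approx(pos, desc, xout = p, rule = 2)$y
}

#' Homogeneity index, conformity index and integral dose
#'
#' HI (default) is `(D2% - D98%) / D50%` on the CTV; CI (default) is the
#' Paddick conformity index `TV_PIV^2 / (TV * PIV)` at the
#' `isodose_frac` of the prescription; ID is the body integral dose
#' `sum(dose) * voxel volume` in Gy cc.  Both index definitions are
#' configuration choices (the RTOG ratio `PIV / TV` is available) and
#' are echoed in the output.
#'
#' @param dose a dose `voxel_volume`.
#' @param structures a `structure_set` with `CTV` and `Body`.
#' @param prescription_gy prescription dose (> 0).
#' @param isodose_frac prescription fraction defining the PIV, default
#'   0.95.
#' @param ci `"paddick"` or `"rtog"`.
#' @return list with `HI`, `CI`, `ID_gycc`, and the definitions used.
#' @export
conformity_homogeneity_id <- function(dose, structures, prescription_gy,
                                      isodose_frac = 0.95,
                                      ci = c("paddick", "rtog")) {
  ci <- match.arg(ci)
  if (prescription_gy <= 0) stop("prescription must be > 0")
  ctv <- roi_mask(structures, "CTV")
  body <- roi_mask(structures, "Body")
  if (!any(ctv)) stop("CTV is empty")
  vcc <- voxel_cc(structures$grid)
  crv <- dvh_curve(dose$values[ctv], vcc, "CTV")
  hi <- (dvh_metric(crv, "D2%") - dvh_metric(crv, "D98%")) /
    dvh_metric(crv, "D50%")
  piv <- dose$values >= isodose_frac * prescription_gy
  tv <- sum(ctv); pv <- sum(piv); ov <- sum(ctv & piv)
  ci_val <- if (pv == 0) 0
  else if (ci == "paddick") ov^2 / (tv * pv) else pv / tv
  list(HI = hi, CI = ci_val,
       ID_gycc = sum(dose$values[body]) * vcc,
       hi_def = "(D2%-D98%)/D50%",
       ci_def = paste0(ci, "@", isodose_frac * 100, "%"))
}
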