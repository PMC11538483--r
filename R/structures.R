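#' Directional margin specification
#'
#' Margins are stored as a length-6 nonnegative vector in the order
#' `(-x, +x, -y, +y, -z, +z)`, mm.  A scalar gives an isotropic margin.
#'
#' @param m scalar, length-3 (symmetric per axis) or length-6 margins, mm.
#' @return a `margin_spec` numeric vector of length 6.
#' @export
margin_spec <- function(m) {
  m <- as.numeric(m)
  m <- switch(as.character(length(m)),
              "1" = rep(m, 6), "3" = rep(m, each = 2), "6" = m,
              stop("margins must have length 1, 3 or 6"))
  if (any(m < 0)) stop("margins must be >= 0")
  names(m) <- c("-x", "+x", "-y", "+y", "-z", "+z")
  structure(m, class = "margin_spec")
}

#' Split a setup margin between optimizer and geometric expansion
#'
#' The total directional setup margin is divided into an isotropic part
#' handed to the robust optimizer as its setup-error parameter and the
#' remainder applied as a geometric CTV expansion; the two reconstruct
#' the total exactly.
#'
#' @param total a `margin_spec` (or coercible) of total margins, mm.
#' @param optimizer_part_mm isotropic optimizer setup error, mm; must not
#'   exceed any directional total margin.
#' @return list with `geometric` (a `margin_spec`) and
#'   `optimizer_setup_error_mm`.
#' @export
split_margin <- function(total, optimizer_part_mm) {
  total <- margin_spec(unclass(total))
  if (optimizer_part_mm < 0) stop("optimizer part must be >= 0")
  if (optimizer_part_mm > min(total) + 1e-12)
    stop("optimizer setup error exceeds a directional margin (min ",
         min(total), " mm)")
  list(geometric = margin_spec(pmax(unclass(total) - optimizer_part_mm, 0)),
       optimizer_setup_error_mm = optimizer_part_mm)
}

# voxel offsets of the structuring element for a directional margin:
# offset d (mm) is included iff sum_i (d_i / m_i(sign d_i))^2 <= 1,
# i.e. the axis-aligned (possibly asymmetric) ellipsoid with the six
# directional margins as semi-axes.  Equal margins give the Euclidean
# ball, so isotropic expansion matches distance-transform thresholding
# between voxel centers.
margin_offsets <- function(margins, spacing) {
  m <- unclass(margins)
  reach <- floor(max(m) / spacing + 1e-9)
  ax <- lapply(1:3, function(a) seq(-reach[a], reach[a]))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  d <- sweep(g, 2, spacing, `*`)
  q <- matrix(0, nrow(d), 3)
  for (a in 1:3) {
    r <- ifelse(d[, a] < 0, m[2 * a - 1], m[2 * a])
    ok <- r > 0
    q[, a] <- ifelse(d[, a] == 0, 0, ifelse(ok, (d[, a] / r)^2, Inf))
  }
  g[rowSums(q) <= 1 + 1e-12, , drop = FALSE]
}

check_fit <- function(mask, offsets, dims) {
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min) + apply(offsets, 2, min)
  hi <- apply(idx, 2, max) + apply(offsets, 2, max)
  bad <- which(lo < 1 | hi > dims)
  if (length(bad))
    stop("margin expansion exceeds the grid along axis ",
         paste(c("x", "y", "z")[bad], collapse = ", "))
}

#' Isotropic margin expansion of an ROI mask
#'
#' Minkowski dilation by a Euclidean ball of radius `margin_mm`: a voxel
#' joins the expansion iff its center lies within the margin of any
#' source voxel center.
#'
#' @param mask logical 3-D array.
#' @param margin_mm nonnegative margin, mm.
#' @param grid a `voxel_volume` (for spacing), or a length-3 spacing.
#' @return logical array of the same dimensions, containing `mask`.
#' @export
expand_isotropic <- function(mask, margin_mm, grid) {
  if (margin_mm < 0) stop("margin must be >= 0")
  expand_anisotropic(mask, margin_spec(margin_mm), grid)
}

#' Anisotropic margin expansion of an ROI mask
#'
#' Dilation by the axis-aligned, possibly asymmetric ellipsoidal
#' structuring element whose six semi-axes are the directional margins.
#' Equal margins reduce to [expand_isotropic()].
#'
#' @inheritParams expand_isotropic
#' @param margins a `margin_spec` (or coercible).
#' @export
expand_anisotropic <- function(mask, margins, grid) {
  if (!any(mask)) stop("mask is empty")
  spacing <- if (inherits(grid, "voxel_volume")) grid$spacing else rep_len(grid, 3)
  margins <- margin_spec(unclass(margins))
  offs <- margin_offsets(margins, spacing)
  check_fit(mask, offs, dim(mask))
  out <- cpp_dilate_mask(as.logical(mask), dim(mask), offs)
  array(out, dim(mask))
}

#' Structure set: named ROI masks on the planning (MidP) grid
#'
#' @param rois named list of logical arrays with identical dimensions.
#' @param grid the `voxel_volume` the masks live on.
#' @param margins optional margin bookkeeping (total / split).
#' @return a `structure_set`.
#' @export
structure_set <- function(rois, grid, margins = NULL) {
  stopifnot(is.list(rois), length(names(rois)) == length(rois))
  d <- dim(grid$values)
  for (nm in names(rois))
    if (!identical(dim(rois[[nm]]), d))
      stop("ROI '", nm, "' does not match the grid dimensions")
  chk <- function(a, b)
    if (all(c(a, b) %in% names(rois)) && any(rois[[a]] & !rois[[b]]))
      stop("ROI containment violated: ", a, " not within ", b)
  chk("GTV", "CTV"); chk("CTV", "CTVexp"); chk("CTVexp", "Body")
  if (all(c("Lungs", "GTV", "Lungs-GTV") %in% names(rois)) &&
      !identical(rois[["Lungs-GTV"]], rois[["Lungs"]] & !rois[["GTV"]]))
    stop("Lungs-GTV must equal Lungs minus GTV")
  structure(list(rois = rois, grid = grid, margins = margins),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cc <- voxel_cc(x$grid)
  v <- vapply(x$rois, function(m) sum(m) * cc, numeric(1))
  cat("<structure_set> on ", paste(dim(x$grid$values), collapse = "x"),
      " grid\n", sep = "")
  for (nm in names(v)) cat(sprintf("  %-10s %8.1f cc\n", nm, v[nm]))
  invisible(x)
}

#' Fetch one ROI mask by name
#' @param structures a `structure_set`.
#' @param name ROI name.
#' @return logical array.
#' @export
roi_mask <- function(structures, name) {
  m <- structures$rois[[name]]
  if (is.null(m)) stop("unknown ROI: ", name)
  m
}
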