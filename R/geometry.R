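#' Six-parameter rigid transformation
#'
#' The chromosome of the registration problem: translations in mm along x, y,
#' z followed by rotations in degrees about x, y, z. Rotations are intrinsic
#' with composition order `Rz %*% Ry %*% Rx`, applied about a stated centre.
#'
#' @param tx,ty,tz Translations, mm.
#' @param rx,ry,rz Rotations, degrees.
#' @return A `rigid_params` object (named numeric of length 6).
#' @examples
#' rigid_params(tx = 5, rz = 10)
#' @export
rigid_params <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz)
  p <- vapply(p, as.numeric, numeric(1))
  if (any(!is.finite(p))) stop("all six parameters must be finite", call. = FALSE)
  structure(p, class = "rigid_params")
}

#' @export
print.rigid_params <- function(x, ...) {
  cat("<rigid_params> t = (", paste(format(x[1:3], digits = 4), collapse = ", "),
      ") mm, r = (", paste(format(x[4:6], digits = 4), collapse = ", "),
      ") deg\n", sep = "")
  invisible(x)
}

as_rigid_params <- function(x) {
  if (inherits(x, "rigid_params")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6L) stop("need 6 values (tx, ty, tz, rx, ry, rz)", call. = FALSE)
  rigid_params(x[1], x[2], x[3], x[4], x[5], x[6])
}

param_names <- c("tx", "ty", "tz", "rx", "ry", "rz")

#' Per-parameter search ranges
#'
#' @param lower,upper Length-6 numeric bounds in parameter order
#'   (tx, ty, tz in mm; rx, ry, rz in degrees), `lower < upper` per entry.
#'   Defaults are the +/-40 mm / +/-20 degree misalignment envelope of
#'   clinical cardiac PET/CT acquisitions.
#' @return A `param_ranges` object.
#' @export
param_ranges <- function(lower = c(-40, -40, -40, -20, -20, -20),
                         upper = c(40, 40, 40, 20, 20, 20)) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 6L || length(upper) != 6L)
    stop("bounds must have length 6", call. = FALSE)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("need finite lower <= upper for every parameter", call. = FALSE)
  structure(list(lower = stats::setNames(lower, param_names),
                 upper = stats::setNames(upper, param_names)),
            class = "param_ranges")
}

#' Homogeneous matrix of a rigid transformation
#'
#' Builds the 4 x 4 world-coordinate matrix `T(x) = R (x - c) + c + t` with
#' `R = Rz Ry Rx` (angles in degrees) about centre `c`.
#'
#' @param p A [rigid_params()] (or 6 numbers).
#' @param center Rotation centre, world mm. Default the origin.
#' @return 4 x 4 numeric matrix.
#' @examples
#' compose_matrix(rigid_params(tx = 5))[1, 4]
#' @export
compose_matrix <- function(p, center = c(0, 0, 0)) {
  p <- as_rigid_params(p)
  a <- p[4:6] * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  center <- as.numeric(center)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- p[1:3] + center - R %*% center
  M
}

#' Rigid parameters of a homogeneous matrix
#'
#' Inverse of [compose_matrix()] for the same Euler convention
#' (`Rz Ry Rx`, degrees, rotation about `center`). Used to express residual
#' transforms — e.g. estimated composed with applied — as signed parameter
#' errors.
#'
#' @param M 4 x 4 rigid homogeneous matrix.
#' @param center Rotation centre used in the parameterization.
#' @return A [rigid_params()].
#' @export
decompose_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-10) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock: fold rz into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  center <- as.numeric(center)
  t <- M[1:3, 4] - center + R %*% center
  rigid_params(t[1], t[2], t[3], rx * 180 / pi, ry * 180 / pi, rz * 180 / pi)
}

#' Apply a rigid transformation to a volume
#'
#' Resamples `vol` under the transform `T` (floating-to-reference contract)
#' on its own grid: output voxel at world position `x` takes the value of the
#' input at `T^-1 x`. Voxels mapping outside the input field of view are
#' filled with the volume's minimum intensity, which acts as background for
#' mutual information.
#'
#' @param vol A [volume_grid()].
#' @param p A [rigid_params()].
#' @param interp `"trilinear"` (default) or `"nearest"`.
#' @param center Rotation centre; default the volume's physical centre.
#' @param pad Fill value for out-of-field voxels; default `min(vol)`.
#' @return A [volume_grid()] on the same grid as `vol`.
#' @export
apply_rigid <- function(vol, p, interp = c("trilinear", "nearest"),
                        center = NULL, pad = NULL) {
  assert_volume(vol)
  interp <- match.arg(interp)
  if (is.null(center)) center <- volume_center(vol)
  if (is.null(pad)) pad <- min(vol$intensities)
  M <- compose_matrix(as_rigid_params(p), center)
  Minv <- solve(M)
  icode <- if (interp == "nearest") 0L else 1L
  out <- resample_grid(as.numeric(vol$intensities), as.integer(vol$dims),
                       vol$spacing, vol$origin,
                       as.integer(vol$dims), vol$spacing, vol$origin,
                       as.numeric(t(Minv)), icode, pad)
  # validity travels with the data: voxels sampled outside the input field of
  # view (or touching its invalid voxels) become invalid in the output
  src_mask <- if (is.null(vol$mask)) array(1, vol$dims) else vol$mask * 1
  mk <- resample_grid(as.numeric(src_mask), as.integer(vol$dims),
                      vol$spacing, vol$origin,
                      as.integer(vol$dims), vol$spacing, vol$origin,
                      as.numeric(t(Minv)), icode, 0)
  volume_grid(array(out, vol$dims), spacing = vol$spacing, origin = vol$origin,
              mask = array(mk > 0.999, vol$dims))
}

#' Misalign a volume without losing content
#'
#' Applies the rigid transform `p` to `vol` and resamples it onto an
#' axis-aligned canvas grid just large enough to enclose the transformed
#' field of view, at the volume's own spacing. Unlike [apply_rigid()], which
#' clips to the input grid, no content is lost: the output carries a validity
#' mask marking canvas voxels not covered by the input. This emulates a
#' second acquisition of the same anatomy with a differently placed field of
#' view, the situation a registration benchmark needs.
#'
#' @param vol A [volume_grid()].
#' @param p A [rigid_params()] misalignment.
#' @param center Rotation centre; default the volume's physical centre.
#' @return A [volume_grid()] with expanded dims, shifted origin, and a mask.
#' @export
misalign_volume <- function(vol, p, center = NULL) {
  assert_volume(vol)
  if (is.null(center)) center <- volume_center(vol)
  M <- compose_matrix(as_rigid_params(p), center)
  # transformed positions of the 8 grid corners (voxel-centre convention)
  lo <- vol$origin
  hi <- vol$origin + (vol$dims - 1) * vol$spacing
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  tc <- t(M[1:3, 1:3] %*% t(corners) + M[1:3, 4])
  new_lo <- floor(apply(tc, 2, min) / vol$spacing) * vol$spacing
  new_hi <- ceiling(apply(tc, 2, max) / vol$spacing) * vol$spacing
  ndims <- as.integer(round((new_hi - new_lo) / vol$spacing)) + 1L
  Minv <- solve(M)
  pad <- min(vol$intensities)
  out <- resample_grid(as.numeric(vol$intensities), as.integer(vol$dims),
                       vol$spacing, vol$origin,
                       ndims, vol$spacing, new_lo,
                       as.numeric(t(Minv)), 1L, pad)
  src_mask <- if (is.null(vol$mask)) array(1, vol$dims) else vol$mask * 1
  mk <- resample_grid(as.numeric(src_mask), as.integer(vol$dims),
                      vol$spacing, vol$origin,
                      ndims, vol$spacing, new_lo,
                      as.numeric(t(Minv)), 1L, 0)
  volume_grid(array(out, ndims), spacing = vol$spacing, origin = new_lo,
              mask = array(mk > 0.999, ndims))
}

#' Crop a volume to a box around its signal content
#'
#' Finds the bounding box of voxels whose intensity exceeds a threshold
#' fraction of the (valid) intensity range, expands it by a margin, and
#' returns the cropped volume (mask included). For a floating PET volume this
#' isolates the region around the heart — the only structure carrying
#' registration information — so that mutual information is not diluted or
#' gamed by large empty backgrounds; the clinical counterpart is the manual
#' region-of-interest drawn around the heart before registration.
#'
#' @param vol A [volume_grid()].
#' @param threshold_frac Content threshold as a fraction of the intensity
#'   range above the minimum (default 0.25).
#' @param margin Context margin in mm added on every side (default 15).
#' @return A cropped [volume_grid()].
#' @export
crop_to_content <- function(vol, threshold_frac = 0.25, margin = 15) {
  assert_volume(vol)
  # threshold a lightly smoothed copy: isolated noise excursions above the
  # threshold must not inflate the bounding box
  vals <- array(gauss_blur3(as.numeric(vol$intensities),
                            as.integer(vol$dims), rep(2, 3)), vol$dims)
  valid <- if (is.null(vol$mask)) array(TRUE, vol$dims) else vol$mask
  rng <- range(vals[valid])
  thr <- rng[1] + threshold_frac * diff(rng)
  hit <- which(vals > thr & valid, arr.ind = TRUE)
  if (nrow(hit) == 0L) stop("no voxel exceeds the content threshold", call. = FALSE)
  mvox <- ceiling(margin / vol$spacing)
  lo <- pmax(1L, apply(hit, 2, min) - mvox)
  hi <- pmin(vol$dims, apply(hit, 2, max) + mvox)
  sub <- vol$intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msub <- if (is.null(vol$mask)) NULL else
    vol$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  volume_grid(sub, spacing = vol$spacing,
              origin = vol$origin + (lo - 1) * vol$spacing, mask = msub)
}

#' Resample a volume to a target voxel volume (downsampling factor)
#'
#' The downsampling factor DF is the target voxel volume in cubic mm; the
#' output grid is isotropic with edge `df^(1/3)` mm, trilinearly resampled
#' and centred on the input's physical field of view (preserved to within one
#' output voxel). `df` larger than the input voxel volume downsamples;
#' `df < 1` on a 1 mm grid upsamples; `df` equal to the input voxel volume
#' leaves the grid unchanged.
#'
#' @param vol A [volume_grid()].
#' @param df Target voxel volume, cubic mm (> 0).
#' @return A [volume_grid()].
#' @examples
#' v <- volume_grid(array(rnorm(8^3), c(8, 8, 8)))
#' resample_by_df(v, 8)$spacing   # 2 mm edges
#' @export
resample_by_df <- function(vol, df) {
  assert_volume(vol)
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df <= 0)
    stop("`df` must be a positive voxel volume in mm^3", call. = FALSE)
  if (isTRUE(all.equal(df, prod(vol$spacing)))) return(vol)
  edge <- df^(1 / 3)
  extent <- vol$dims * vol$spacing
  ndims <- pmax(1L, as.integer(round(extent / edge)))
  norigin <- vol$origin - vol$spacing / 2 + edge / 2 + (extent - ndims * edge) / 2
  out <- resample_grid(as.numeric(vol$intensities), as.integer(vol$dims),
                       vol$spacing, vol$origin,
                       ndims, rep(edge, 3), norigin,
                       as.numeric(t(diag(4))), 1L, min(vol$intensities))
  mask <- NULL
  if (!is.null(vol$mask)) {
    mk <- resample_grid(as.numeric(vol$mask * 1), as.integer(vol$dims),
                        vol$spacing, vol$origin,
                        ndims, rep(edge, 3), norigin,
                        as.numeric(t(diag(4))), 1L, 0)
    mask <- array(mk > 0.999, ndims)
  }
  volume_grid(array(out, ndims), spacing = rep(edge, 3), origin = norigin,
              mask = mask)
}

#' Envelope of inverse transforms of a parameter box
#'
#' Registration recovers the inverse of an applied misalignment, and the
#' inverse of a rotation-plus-translation drawn from a box is not confined
#' to that box: the inverse translation is `-R^-1 t`, whose components can
#' exceed the per-axis translation bound when rotations are present. This
#' helper sweeps the corners of the translation box against a grid of
#' rotations and returns the componentwise envelope of the inverse
#' parameters (padded by 2%), the search box that provably contains every
#' recoverable truth.
#'
#' @param ranges A [param_ranges()] describing the misalignment box.
#' @param grid_step Rotation grid step in degrees for the sweep (default 5).
#' @return A [param_ranges()] enclosing all inverse transforms.
#' @export
inverse_envelope <- function(ranges, grid_step = 5) {
  stopifnot(inherits(ranges, "param_ranges"))
  gr <- function(j) {
    g <- unique(c(seq(ranges$lower[j], ranges$upper[j], by = grid_step),
                  ranges$upper[j]))
    g
  }
  tcorners <- as.matrix(expand.grid(c(ranges$lower[1], ranges$upper[1]),
                                    c(ranges$lower[2], ranges$upper[2]),
                                    c(ranges$lower[3], ranges$upper[3])))
  lo <- rep(Inf, 6); hi <- rep(-Inf, 6)
  for (rx in gr(4)) for (ry in gr(5)) for (rz in gr(6)) {
    R <- compose_matrix(rigid_params(0, 0, 0, rx, ry, rz))[1:3, 1:3]
    ang <- as.numeric(decompose_matrix(solve(compose_matrix(
      rigid_params(0, 0, 0, rx, ry, rz)))))[4:6]
    tinv <- -t(R) %*% t(tcorners)
    lo[1:3] <- pmin(lo[1:3], apply(tinv, 1, min))
    hi[1:3] <- pmax(hi[1:3], apply(tinv, 1, max))
    lo[4:6] <- pmin(lo[4:6], ang)
    hi[4:6] <- pmax(hi[4:6], ang)
  }
  pad <- 0.02 * (hi - lo)
  param_ranges(lower = lo - pad, upper = hi + pad)
}

#' Write rigid parameters to a plain-text file
#'
#' Six named values plus the rotation centre and a conventions tag, one
#' `key = value` per line.
#'
#' @param p A [rigid_params()].
#' @param path Output file.
#' @param center Rotation centre recorded alongside the parameters.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path, center = c(0, 0, 0)) {
  p <- as_rigid_params(p)
  lines <- c(
    sprintf("%s = %.10g", param_names, as.numeric(p)),
    sprintf("center = %.10g %.10g %.10g", center[1], center[2], center[3]),
    "conventions = intrinsic ZYX, degrees, translations mm"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read rigid parameters written by [write_params()]
#'
#' @param path File path.
#' @return A list with `params` ([rigid_params()]) and `center`.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  p <- as.numeric(vals[match(param_names, keys)])
  if (any(is.na(p))) stop("malformed parameter file: ", path, call. = FALSE)
  center <- as.numeric(strsplit(vals[match("center", keys)], "\\s+")[[1]])
  list(params = as_rigid_params(p), center = center)
}
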