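#' Specification of a synthetic cardiac phantom
#'
#' Describes the geometry, tissue intensities, blur, and noise of a synthetic
#' short-axis cardiac volume. The left ventricle is modelled as a myocardial
#' shell between two concentric ellipsoids (epicardial and endocardial
#' surfaces) with a blood pool inside, flanked by a right-ventricular
#' crescent (shell plus blood pool) on the septal side — the structure that
#' anchors in-plane orientation in real short-axis images; the CT phantom
#' adds an ellipsoidal soft-tissue thorax with two lung ellipsoids against
#' an air background.
#'
#' The image model is piecewise-constant tissue intensities convolved with an
#' isotropic Gaussian kernel (partial-volume effect) plus zero-mean Gaussian
#' noise. The default blur standard deviations are 0.8 voxels for CT and 2.4
#' voxels for PET, reflecting PET's coarser intrinsic resolution.
#'
#' @param modality `"ct"` or `"pet"`.
#' @param dims Voxel counts per axis. Default `c(256, 256, 55)`.
#' @param spacing Voxel size in mm. Default 1 mm isotropic.
#' @param epi_axes,endo_axes Semi-axes (mm) of the epicardial and endocardial
#'   ellipsoids; `endo_axes` must be strictly inside `epi_axes`.
#' @param center World position (mm) of the ventricle centre; default the
#'   grid's physical centre.
#' @param tissues Named intensity table over labels air, lung, soft, blood,
#'   myocardium, rv_myocardium. CT defaults (HU, contrast-enhanced): air
#'   -1000, lung -750, soft tissue 40, blood 300, myocardium and RV wall
#'   110. PET defaults: LV myocardium 200, RV wall 80 (physiologic relative
#'   uptake), 0 background.
#' @param blur_sd Gaussian blur SD in voxels; defaults 0.8 (CT) / 2.4 (PET).
#' @param noise_sd Additive Gaussian noise SD in intensity units; defaults
#'   10 HU (CT) / 15 units (PET).
#' @param seed Integer seed making the noise (hence the volume) reproducible.
#' @return A `phantom_spec` object.
#' @examples
#' spec <- phantom_spec("ct", dims = c(64, 64, 16))
#' spec$tissues
#' @export
phantom_spec <- function(modality = c("ct", "pet"),
                         dims = c(256, 256, 55),
                         spacing = c(1, 1, 1),
                         epi_axes = NULL, endo_axes = NULL,
                         center = NULL,
                         tissues = NULL,
                         blur_sd = NULL,
                         noise_sd = NULL,
                         seed = 1L) {
  modality <- match.arg(modality)
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be 3 positive voxel counts", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)

  extent <- dims * spacing
  # default ventricle scaled to the field of view; on the canonical
  # 256 x 256 x 55 grid this gives semi-axes 50 x 40 mm in-plane and 25 mm
  # axially. The in-plane anisotropy matters: a circular cross-section would
  # leave the in-plane rotation unidentifiable from the PET shell alone.
  if (is.null(epi_axes))
    epi_axes <- pmin(c(50, 40, 25), 0.46 * extent)
  if (is.null(endo_axes))
    endo_axes <- epi_axes * c(42, 33, 20) / c(50, 40, 25)
  epi_axes <- as.numeric(epi_axes); endo_axes <- as.numeric(endo_axes)
  if (any(endo_axes >= epi_axes))
    stop("`endo_axes` must be strictly inside `epi_axes`", call. = FALSE)
  if (any(endo_axes <= 0))
    stop("semi-axes must be positive", call. = FALSE)
  if (is.null(center)) center <- (dims - 1) * spacing / 2

  if (is.null(tissues)) {
    # CT defaults follow a contrast-enhanced cardiac acquisition, the
    # standard protocol for PET/CT CAD workups: the iodinated blood pool and
    # the enhanced myocardium must be separated by more than the histogram
    # bin width, otherwise the heart is featureless to mutual information
    # and in-plane orientation is unidentifiable.
    tissues <- if (modality == "ct") {
      c(air = -1000, lung = -750, soft = 40, blood = 300, myocardium = 110,
        rv_myocardium = 110)
    } else {
      c(air = 0, lung = 0, soft = 0, blood = 0, myocardium = 200,
        rv_myocardium = 80)
    }
  }
  needed <- c("air", "lung", "soft", "blood", "myocardium", "rv_myocardium")
  if (!all(needed %in% names(tissues)))
    stop("`tissues` must name: ", paste(needed, collapse = ", "), call. = FALSE)

  if (is.null(blur_sd)) blur_sd <- if (modality == "ct") 0.8 else 2.4
  if (is.null(noise_sd)) noise_sd <- if (modality == "ct") 10 else 15
  if (blur_sd < 0 || noise_sd < 0)
    stop("`blur_sd` and `noise_sd` must be >= 0", call. = FALSE)

  structure(
    list(modality = modality, dims = dims, spacing = spacing,
         epi_axes = epi_axes, endo_axes = endo_axes, center = as.numeric(center),
         tissues = tissues, blur_sd = blur_sd, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Specification of a multiplicative PET fading field
#'
#' A Gaussian "dip" multiplying the PET signal to emulate a perfusion defect:
#' `g(x) = 1 - (1 - a_max) * exp(-sum((x - center)^2) / (2 * sigma^2))`.
#' `g` equals `a_max` at the defect centre and returns to 1 away from it, so
#' `a_max = 1` means no fading and `a_max = 0` a complete local signal loss.
#'
#' @param center Defect centre in world mm.
#' @param a_max Remaining signal fraction at the centre, in `[0, 1]`.
#' @param sigma Standard deviation of the Gaussian field, mm (> 0).
#' @return A `fading_spec` object.
#' @export
fading_spec <- function(center, a_max, sigma) {
  center <- as.numeric(center); a_max <- as.numeric(a_max); sigma <- as.numeric(sigma)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be 3 finite mm coordinates", call. = FALSE)
  if (length(a_max) != 1L || is.na(a_max) || a_max < 0 || a_max > 1)
    stop("`a_max` must lie in [0, 1]", call. = FALSE)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be > 0", call. = FALSE)
  structure(list(center = center, a_max = a_max, sigma = sigma),
            class = "fading_spec")
}

#' Default fading field for a phantom
#'
#' Places the defect on the inferior-lateral myocardial wall (mid-wall radius,
#' -45 degrees in the short-axis plane) and sets `sigma` as a fraction of the
#' volume's largest physical extent — the normalized-coordinate convention of
#' smooth bias-field models, under which the canonical fraction is 0.3.
#'
#' @param spec A PET [phantom_spec()].
#' @param a_max Remaining signal fraction at the defect centre.
#' @param sigma_frac `sigma` as a fraction of the largest extent; default 0.3.
#' @return A [fading_spec()].
#' @export
default_fading <- function(spec, a_max = 1, sigma_frac = 0.3) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- (spec$epi_axes[1] + spec$endo_axes[1]) / 2 # mid-wall radius
  ctr <- spec$center + c(r * cos(-pi / 4), r * sin(-pi / 4), 0)
  fading_spec(center = ctr, a_max = a_max,
              sigma = sigma_frac * max(spec$dims * spec$spacing))
}

# label map as an integer array:
# 1 air, 2 lung, 3 soft, 4 blood, 5 myocardium (LV), 6 RV myocardium.
# `pose` places the whole model under a rigid transform (about the spec
# grid's physical centre) and `grid` overrides the sampling grid, so a
# misaligned acquisition can be generated analytically instead of by
# resampling an existing volume.
phantom_labels <- function(spec, pose = NULL, grid = NULL) {
  d <- if (is.null(grid)) spec$dims else grid$dims
  sp <- spec$spacing
  org <- if (is.null(grid)) c(0, 0, 0) else grid$origin
  x <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  y <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  z <- org[3] + (seq_len(d[3]) - 1) * sp[3]

  ctr <- spec$center
  extent <- spec$dims * sp
  lab <- array(1L, d)

  if (is.null(pose)) {
    # squared normalized radii by outer sums (separable: no 3-D loop)
    ell2 <- function(ec, ax) {
      ex <- ((x - ec[1]) / ax[1])^2
      ey <- ((y - ec[2]) / ax[2])^2
      ez <- ((z - ec[3]) / ax[3])^2
      outer(outer(ex, ey, "+"), ez, "+")
    }
    paint <- function(ec, ax, value) lab[ell2(ec, ax) <= 1] <<- value
    paint_model(spec, ctr, extent, paint)
  } else {
    # posed model: map grid coordinates back to the model frame slice by
    # slice, then run the same ellipsoid tests
    Minv <- solve(compose_matrix(as_rigid_params(pose),
                                 center = (spec$dims - 1) * sp / 2))
    xy <- cbind(rep(x, times = length(y)), rep(y, each = length(x)))
    for (k in seq_len(d[3])) {
      P <- cbind(xy, z[k])
      Q <- P %*% t(Minv[1:3, 1:3])
      Q <- sweep(Q, 2, -Minv[1:3, 4])
      slice <- matrix(1L, d[1], d[2])
      paint <- function(ec, ax, value) {
        r2 <- ((Q[, 1] - ec[1]) / ax[1])^2 + ((Q[, 2] - ec[2]) / ax[2])^2 +
          ((Q[, 3] - ec[3]) / ax[3])^2
        slice[r2 <= 1] <<- value
      }
      paint_model(spec, ctr, extent, paint)
      lab[, , k] <- slice
    }
  }
  lab
}

# draws the anatomy via `paint(center, axes, label)`, back to front
paint_model <- function(spec, ctr, extent, paint) {
  if (spec$modality == "ct") {
    paint(ctr, 0.48 * extent, 3L)
    lung_ax <- c(0.16, 0.28, 0.38) * extent
    loff <- c(0.28 * extent[1], 0.04 * extent[2], 0)
    paint(ctr + loff, lung_ax, 2L)
    paint(ctr + loff * c(-1, 1, 1), lung_ax, 2L)
  }
  # right-ventricular crescent, drawn before the LV so the LV wall wins the
  # overlap and the RV remains a crescent. Anatomically the RV sits to the
  # right AND anterior of the LV; the anterior offset also gives rotations
  # about the x axis a lever arm in the y-z plane.
  # RV offset: rightward, anterior, and toward the base — its basal reach
  # (inflow/outflow) is what breaks the model's last in-plane-axis flip
  # symmetry, giving rotations about x and y single well-defined optima
  rv_ctr <- ctr + c(-0.75 * spec$epi_axes[1], -0.30 * spec$epi_axes[2],
                    0.20 * spec$epi_axes[3])
  rv_epi <- 0.64 * spec$epi_axes
  paint(rv_ctr, rv_epi, 6L)
  paint(rv_ctr, 0.78 * rv_epi, 4L)
  paint(ctr, spec$epi_axes, 5L)
  # the endocardial surface is shifted toward the apex: the apical wall is
  # thinner than the basal wall, the apex-base asymmetry of a real ventricle
  # (and the only feature breaking the model's z-mirror symmetry, without
  # which rotations about in-plane axes have sign-symmetric twin optima)
  paint(ctr - c(0, 0, 0.12 * spec$endo_axes[3]), spec$endo_axes, 4L)
  invisible(NULL)
}

phantom_ideal <- function(spec, pose = NULL, grid = NULL) {
  lab <- phantom_labels(spec, pose = pose, grid = grid)
  vals <- spec$tissues[c("air", "lung", "soft", "blood", "myocardium",
                         "rv_myocardium")]
  array(as.numeric(vals)[lab], dim(lab))
}

blur_volume <- function(arr, dims, sd) {
  if (sd <= 0) return(arr)
  array(gauss_blur3(as.numeric(arr), as.integer(dims), rep(sd, 3)), dims)
}

#' Generate a synthetic CT cardiac phantom
#'
#' Builds the piecewise-constant tissue map, convolves it with an isotropic
#' Gaussian kernel (partial-volume effect), and adds zero-mean Gaussian noise:
#' `I = (I0 \%convolve\% h) + n`. Blur is applied before noise, and the same
#' spec and seed always reproduce the identical volume.
#'
#' @param spec A [phantom_spec()] with `modality = "ct"`.
#' @return A [volume_grid()].
#' @examples
#' ct <- make_ct_phantom(phantom_spec("ct", dims = c(48, 48, 12), seed = 7))
#' range(ct$intensities)
#' @export
make_ct_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$modality != "ct") stop("spec modality must be 'ct'", call. = FALSE)
  ideal <- phantom_ideal(spec)
  out <- blur_volume(ideal, spec$dims, spec$blur_sd)
  if (spec$noise_sd > 0) {
    out <- out + with_phantom_seed(spec$seed, {
      array(stats::rnorm(prod(spec$dims), 0, spec$noise_sd), spec$dims)
    })
  }
  volume_grid(out, spacing = spec$spacing)
}

#' Generate a synthetic PET cardiac phantom
#'
#' Only the myocardial shell carries signal; blur is larger than CT's
#' (default SD 2.4 voxels), a multiplicative Gaussian fading field models a
#' perfusion defect, and Gaussian noise is added last:
#' `I = (I0 \%convolve\% h) * g + n`.
#'
#' @param spec A [phantom_spec()] with `modality = "pet"`.
#' @param fading A [fading_spec()], or `NULL` for no fading (`g == 1`).
#' @return A [volume_grid()].
#' @export
make_pet_phantom <- function(spec, fading = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$modality != "pet") stop("spec modality must be 'pet'", call. = FALSE)
  ideal <- phantom_ideal(spec)
  out <- blur_volume(ideal, spec$dims, spec$blur_sd)
  vol <- volume_grid(out, spacing = spec$spacing)
  if (!is.null(fading)) {
    extent_lo <- -spec$spacing / 2
    extent_hi <- (spec$dims - 0.5) * spec$spacing
    if (any(fading$center < extent_lo) || any(fading$center > extent_hi))
      warning("fading center lies outside the grid; g ~ 1 over the volume",
              call. = FALSE)
    vol$intensities <- vol$intensities * fading_field(vol, fading)
  }
  if (spec$noise_sd > 0) {
    vol$intensities <- vol$intensities + with_phantom_seed(spec$seed, {
      array(stats::rnorm(prod(spec$dims), 0, spec$noise_sd), spec$dims)
    })
  }
  vol
}

#' Generate a misaligned PET acquisition analytically
#'
#' Draws the PET cardiac model at a rigidly transformed pose (rotation about
#' the spec grid's physical centre, then translation) on a fresh grid just
#' enclosing the posed heart plus a margin, then applies blur, optional
#' fading, and noise on that grid. This emulates a second acquisition of the
#' same anatomy with a differently placed field of view exactly — no
#' resampling of an existing volume, hence no interpolation blur or padding
#' enters the benchmark data.
#'
#' @param spec A PET [phantom_spec()].
#' @param pose A [rigid_params()] misalignment applied to the model.
#' @param margin Background margin around the posed heart, mm (default 15;
#'   must exceed the blur support for exact edges).
#' @param fading Optional [fading_spec()] in the model frame; its centre is
#'   carried along with the pose.
#' @return A [volume_grid()] whose origin reflects the posed position.
#' @export
posed_pet_acquisition <- function(spec, pose, margin = 15, fading = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$modality != "pet") stop("spec modality must be 'pet'", call. = FALSE)
  pose <- as_rigid_params(pose)
  M <- compose_matrix(pose, center = (spec$dims - 1) * spec$spacing / 2)
  # model-frame corners of the LV and RV bounding boxes
  corner_box <- function(ctr, ax) {
    as.matrix(expand.grid(ctr[1] + c(-1, 1) * ax[1],
                          ctr[2] + c(-1, 1) * ax[2],
                          ctr[3] + c(-1, 1) * ax[3]))
  }
  rv_ctr <- spec$center + c(-0.75 * spec$epi_axes[1],
                            -0.30 * spec$epi_axes[2],
                            0.20 * spec$epi_axes[3])
  corners <- rbind(corner_box(spec$center, spec$epi_axes),
                   corner_box(rv_ctr, 0.64 * spec$epi_axes))
  tc <- t(M[1:3, 1:3] %*% t(corners) + M[1:3, 4])
  pad <- margin + 4 * spec$blur_sd * max(spec$spacing)
  lo <- apply(tc, 2, min) - pad
  hi <- apply(tc, 2, max) + pad
  # the scanner's field of view travels with the patient: clamp the region
  # to an acquisition box of the model's extent centred on the posed heart
  fov_ctr <- as.numeric(M[1:3, 1:3] %*% spec$center + M[1:3, 4])
  half <- (spec$dims - 1) * spec$spacing / 2
  lo <- floor(pmax(lo, fov_ctr - half) / spec$spacing) * spec$spacing
  hi <- ceiling(pmin(hi, fov_ctr + half) / spec$spacing) * spec$spacing
  dims <- as.integer(round((hi - lo) / spec$spacing)) + 1L
  # generate on a padded grid and trim after blurring, so the convolution is
  # exact everywhere inside the returned box (no boundary reflection enters
  # the data; its orientation would vary with the pose)
  bpad <- as.integer(ceiling(4 * spec$blur_sd)) + 1L
  pgrid <- list(dims = dims + 2L * bpad, origin = lo - bpad * spec$spacing)
  ideal <- phantom_ideal(spec, pose = pose, grid = pgrid)
  out <- blur_volume(ideal, pgrid$dims, spec$blur_sd)
  keep <- lapply(1:3, function(a) seq(bpad + 1L, bpad + dims[a]))
  out <- out[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  vol <- volume_grid(out, spacing = spec$spacing, origin = lo)
  grid <- list(dims = dims, origin = lo)
  if (!is.null(fading)) {
    posed_fading <- fading
    posed_fading$center <- as.numeric(M[1:3, 1:3] %*% fading$center + M[1:3, 4])
    vol$intensities <- vol$intensities * fading_field(vol, posed_fading)
  }
  if (spec$noise_sd > 0) {
    vol$intensities <- vol$intensities + with_phantom_seed(spec$seed, {
      array(stats::rnorm(prod(grid$dims), 0, spec$noise_sd), grid$dims)
    })
  }
  vol
}

#' Write or read a phantom spec as a JSON sidecar
#'
#' Serializes every field of a [phantom_spec()] so a generated volume can be
#' reproduced exactly from the file next to it.
#'
#' @param spec A [phantom_spec()].
#' @param path JSON file path.
#' @return `write_phantom_spec()` returns `path` invisibly;
#'   `read_phantom_spec()` returns the reconstructed [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$tissues <- as.list(x$tissues) # keep the label -> value names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom_spec(modality = x$modality, dims = x$dims, spacing = x$spacing,
               epi_axes = x$epi_axes, endo_axes = x$endo_axes,
               center = x$center, tissues = unlist(x$tissues),
               blur_sd = x$blur_sd, noise_sd = x$noise_sd, seed = x$seed)
}

#' Evaluate a fading field on a volume's grid
#'
#' @param vol A [volume_grid()] supplying the grid.
#' @param fading A [fading_spec()].
#' @return 3-D array of multiplicative factors in `[a_max, 1]`.
#' @export
fading_field <- function(vol, fading) {
  assert_volume(vol)
  stopifnot(inherits(fading, "fading_spec"))
  d <- vol$dims; sp <- vol$spacing; o <- vol$origin
  ex <- (o[1] + (seq_len(d[1]) - 1) * sp[1] - fading$center[1])^2
  ey <- (o[2] + (seq_len(d[2]) - 1) * sp[2] - fading$center[2])^2
  ez <- (o[3] + (seq_len(d[3]) - 1) * sp[3] - fading$center[3])^2
  ss <- outer(outer(ex, ey, "+"), ez, "+")
  1 - (1 - fading$a_max) * exp(-ss / (2 * fading$sigma^2))
}

# run expr under a local RNG state seeded for the phantom, restoring the
# caller's state afterwards
with_phantom_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
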