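#' Recipe for synthetic brain-like masks
#'
#' Describes the generator of smooth single-component ellipsoid-like
#' "brain" masks: grid shape, anisotropic-capable voxel spacing,
#' brain-like semi-axes with per-axis jitter, a small random centre
#' offset, and a smooth low-frequency boundary deformation. Defaults
#' emulate a skull-stripped adult brain on a 96^3 grid at 2 mm isotropic
#' spacing (192 mm field of view).
#'
#' @param shape Grid dimensions (default `c(96, 96, 96)`).
#' @param spacing Voxel size in mm (default `c(2, 2, 2)`).
#' @param semi_axes Ellipsoid semi-axes in mm (default `c(70, 55, 50)`).
#' @param axis_jitter Relative per-axis jitter, uniform in
#'   `[-axis_jitter, +axis_jitter]` (default 0.05).
#' @param center_jitter Uniform centre offset amplitude in mm (default 2).
#' @param deform_amplitude Approximate boundary displacement of the
#'   smooth deformation, mm (default 2; 0 gives an exact ellipsoid).
#' @param deform_scale Length scale (wavelength) of the deformation in
#'   mm (default 40).
#' @param n_modes Number of random cosine modes in the deformation
#'   field (default 6).
#' @param margin_mm Required clearance between the foreground and the
#'   volume border, mm (default 6).
#' @return A list of class `mask_recipe`.
#' @export
mask_recipe <- function(shape = c(96, 96, 96), spacing = c(2, 2, 2),
                        semi_axes = c(70, 55, 50), axis_jitter = 0.05,
                        center_jitter = 2, deform_amplitude = 2,
                        deform_scale = 40, n_modes = 6L, margin_mm = 6) {
  stopifnot(length(shape) == 3, length(spacing) == 3,
            length(semi_axes) == 3, all(spacing > 0), all(semi_axes > 0),
            axis_jitter >= 0, center_jitter >= 0, deform_amplitude >= 0,
            deform_scale > 0, n_modes >= 1, margin_mm >= 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 semi_axes = as.numeric(semi_axes),
                 axis_jitter = axis_jitter, center_jitter = center_jitter,
                 deform_amplitude = deform_amplitude,
                 deform_scale = deform_scale, n_modes = as.integer(n_modes),
                 margin_mm = margin_mm),
            class = "mask_recipe")
}

# Physical coordinate arrays of the grid (mm), 0-based index * spacing.
coord_arrays <- function(shape, spacing) {
  x <- (seq_len(shape[1]) - 1) * spacing[1]
  y <- (seq_len(shape[2]) - 1) * spacing[2]
  z <- (seq_len(shape[3]) - 1) * spacing[3]
  list(X = array(rep(x, times = shape[2] * shape[3]), shape),
       Y = array(rep(rep(y, each = shape[1]), times = shape[3]), shape),
       Z = array(rep(z, each = shape[1] * shape[2]), shape))
}

#' Generate a clean synthetic brain mask
#'
#' A jittered ellipsoid whose implicit surface is perturbed by a smooth
#' sum of random cosine modes, then thresholded to a binary mask.
#' Deterministic for a fixed recipe and seed.
#'
#' @param recipe A [mask_recipe()].
#' @param seed Integer seed.
#' @param id Mask identifier (default derived from the seed).
#' @return A [brain_mask].
#' @export
generate_clean <- function(recipe, seed, id = sprintf("clean_%d", seed)) {
  stopifnot(inherits(recipe, "mask_recipe"))
  par <- with_seed(seed, list(
    axes = recipe$semi_axes *
      (1 + stats::runif(3, -recipe$axis_jitter, recipe$axis_jitter)),
    center_off = stats::runif(3, -recipe$center_jitter,
                              recipe$center_jitter),
    dirs = {
      v <- matrix(stats::rnorm(3 * recipe$n_modes), ncol = 3)
      v / sqrt(rowSums(v^2))
    },
    phases = stats::runif(recipe$n_modes, 0, 2 * pi)))
  extent <- (recipe$shape - 1) * recipe$spacing
  center <- extent / 2 + par$center_off
  reach <- par$axes + recipe$deform_amplitude + recipe$margin_mm
  if (any(center - reach < 0) || any(center + reach > extent)) {
    config_error("semi-axes (plus deformation and margin) exceed the grid")
  }
  co <- coord_arrays(recipe$shape, recipe$spacing)
  rho2 <- ((co$X - center[1]) / par$axes[1])^2 +
          ((co$Y - center[2]) / par$axes[2])^2 +
          ((co$Z - center[3]) / par$axes[3])^2
  if (recipe$deform_amplitude > 0) {
    field <- 0
    omega <- 2 * pi / recipe$deform_scale
    for (j in seq_len(recipe$n_modes)) {
      u <- par$dirs[j, ]
      field <- field + cos(omega * (u[1] * co$X + u[2] * co$Y +
                                      u[3] * co$Z) + par$phases[j])
    }
    eps <- 2 * recipe$deform_amplitude / mean(par$axes)
    iso <- 1 + eps * field / recipe$n_modes
  } else {
    iso <- 1
  }
  brain_mask(array(as.integer(rho2 <= iso), recipe$shape),
             spacing = recipe$spacing, id = id)
}

#' Corruption specification
#'
#' @param kind One of `"erode"`, `"dilate"`, `"punch_holes"`,
#'   `"add_blob"`, `"truncate_axial"`, `"translate"`.
#' @param magnitude Corruption strength. Units by kind: erosion/dilation
#'   steps (voxels); hole radius (mm); blob radius (mm); removed
#'   fraction of the foreground z-extent; translation distance (mm).
#' @param seed Integer seed for the corruption's random choices.
#' @param n_holes Holes punched for `"punch_holes"` (default 4).
#' @param blob_distance_mm Gap between blob centre and the mask surface
#'   for `"add_blob"` (default 25 mm; far enough that the spurious
#'   component is clearly extracranial).
#' @return A list of class `corruption_spec`.
#' @export
corruption_spec <- function(kind, magnitude, seed = 1L, n_holes = 4L,
                            blob_distance_mm = 25) {
  kinds <- c("erode", "dilate", "punch_holes", "add_blob",
             "truncate_axial", "translate")
  if (!kind %in% kinds) {
    config_error(paste0("unknown corruption kind: ", kind))
  }
  if (magnitude < 0) config_error("corruption magnitude must be >= 0")
  structure(list(kind = kind, magnitude = magnitude, seed = as.integer(seed),
                 n_holes = as.integer(n_holes),
                 blob_distance_mm = blob_distance_mm),
            class = "corruption_spec")
}

sphere_array <- function(shape, spacing, center_mm, radius_mm) {
  co <- coord_arrays(shape, spacing)
  rho2 <- (co$X - center_mm[1])^2 + (co$Y - center_mm[2])^2 +
    (co$Z - center_mm[3])^2
  array(as.integer(rho2 <= radius_mm^2), shape)
}

#' Apply a corruption to a mask
#'
#' Deterministically corrupts a mask according to `spec` and reports the
#' achieved Dice against the input. A corruption that would empty the
#' mask raises an error rather than returning an empty mask.
#'
#' @param mask A non-empty [brain_mask].
#' @param spec A [corruption_spec()].
#' @param id Identifier of the corrupted mask.
#' @return List with `mask` (the corrupted [brain_mask]) and `dice`
#'   (achieved Dice vs. the input).
#' @export
corrupt_mask <- function(mask, spec, id = paste0(mask$id, "_", spec$kind)) {
  stopifnot(inherits(mask, "brain_mask"), inherits(spec, "corruption_spec"))
  a <- mask$voxels
  if (sum(a) == 0L) empty_mask_error()
  sp <- mask$spacing
  out <- switch(spec$kind,
    erode = {
      b <- a
      for (i in seq_len(round(spec$magnitude))) b <- binary_erode1(b)
      b
    },
    dilate = {
      b <- a
      for (i in seq_len(round(spec$magnitude))) b <- binary_dilate1(b)
      b
    },
    punch_holes = with_seed(spec$seed, {
      core <- binary_erode1(binary_erode1(binary_erode1(a)))
      cand <- which(core == 1L)
      if (length(cand) == 0L) cand <- which(a == 1L)
      centers <- sample(cand, min(spec$n_holes, length(cand)))
      b <- a
      for (ci in centers) {
        ijk <- arrayInd(ci, dim(a))
        hole <- sphere_array(dim(a), sp, (ijk - 1) * sp, spec$magnitude)
        b <- array(as.integer(b == 1L & hole == 0L), dim(a))
      }
      b
    }),
    add_blob = with_seed(spec$seed, {
      surf <- voxel_coords(surface_voxels(a), sp)
      extent <- (dim(a) - 1) * sp
      b <- NULL
      for (try in 1:200) {
        ctr <- stats::runif(3, spec$magnitude, extent - spec$magnitude)
        gap <- sqrt(min(rowSums(sweep(surf, 2, ctr, `-`)^2))) -
          spec$magnitude
        if (gap >= spec$blob_distance_mm - spec$magnitude) {
          b <- array(as.integer(
            a == 1L | sphere_array(dim(a), sp, ctr, spec$magnitude) == 1L),
            dim(a))
          break
        }
      }
      if (is.null(b)) {
        config_error("could not place a blob at the requested distance")
      }
      b
    }),
    truncate_axial = {
      zs <- range(which(apply(a, 3, sum) > 0))
      cut_from <- floor(zs[2] - spec$magnitude * (zs[2] - zs[1]))
      b <- a
      if (cut_from < zs[2]) b[, , (cut_from + 1):zs[2]] <- 0L
      b
    },
    translate = with_seed(spec$seed, {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      steps <- round(spec$magnitude * u / sp)
      b <- a
      for (ax in 1:3) {
        n <- abs(steps[ax])
        if (n > 0) for (i in seq_len(n)) {
          b <- shift1(b, ax, sign(steps[ax]))
        }
      }
      b
    }))
  if (sum(out) == 0L) {
    maskqc_error("data_error", "corruption emptied the mask")
  }
  corrupted <- brain_mask(out, spacing = sp, id = id)
  list(mask = corrupted, dice = dice(mask, corrupted))
}

#' Calibrate a corruption magnitude to a Dice target band
#'
#' Solves for the corruption magnitude by bisection so the achieved
#' Dice against the clean input lands in `dice_band` (below the 0.95
#' sanity threshold by construction). For `"add_blob"` the blob radius
#' is instead grown until the HD95 against the input exceeds
#' `hd_target` mm, which is that corruption's sanity route.
#'
#' @param mask Clean [brain_mask] to corrupt.
#' @param kind Corruption kind, see [corruption_spec()].
#' @param seed Seed passed to the corruption.
#' @param dice_band Target Dice interval (default `c(0.85, 0.93)`).
#' @param hd_target HD95 the blob corruption must exceed (default 15 mm).
#' @param id Identifier for the corrupted mask.
#' @return List with `mask`, `dice`, `magnitude`.
#' @export
calibrate_corruption <- function(mask, kind, seed = 1L,
                                 dice_band = c(0.85, 0.93), hd_target = 15,
                                 id = paste0(mask$id, "_", kind)) {
  # a magnitude so strong it empties the mask counts as Dice 0 during
  # the search; the returned corruption is always non-empty
  mk <- function(mag) {
    tryCatch(corrupt_mask(mask, corruption_spec(kind, mag, seed), id = id),
             data_error = function(e) list(mask = NULL, dice = 0))
  }
  if (kind %in% c("erode", "dilate")) {
    prev <- NULL
    for (steps in 1:20) {
      res <- mk(steps)
      if (is.null(res$mask)) {        # one step too many
        res <- prev
        steps <- steps - 1L
        break
      }
      if (res$dice < dice_band[2]) break
      prev <- res
    }
    if (is.null(res) || is.null(res$mask)) {
      maskqc_error("data_error", "mask too small to corrupt by erosion")
    }
    return(c(res, magnitude = steps))
  }
  if (kind == "add_blob") {
    # HD95 sees the blob only when its surface exceeds 5% of the
    # corrupted surface; size the radius for ~7% and verify.
    n_surf <- sum(surface_voxels(mask$voxels))
    n_blob <- 0.07 / (1 - 0.07) * n_surf
    radius <- max(10, mean(mask$spacing) * sqrt(n_blob / (6 * pi)))
    repeat {
      res <- mk(radius)
      if (hd95(mask, res$mask) > hd_target || radius > 40) break
      radius <- radius * 1.25
    }
    return(c(res, magnitude = radius))
  }
  lims <- switch(kind,
                 punch_holes = c(2, 30),
                 truncate_axial = c(0.02, 0.6),
                 translate = c(2, 50))
  lo <- lims[1]
  hi <- lims[2]
  res <- mk(hi)
  if (!is.null(res$mask) && res$dice >= dice_band[2]) {
    return(c(res, magnitude = hi))  # even the max magnitude is mild
  }
  best <- NULL                      # strongest valid corruption seen
  best_mag <- hi
  if (!is.null(res$mask)) {
    best <- res
  }
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    res <- mk(mid)
    if (is.null(res$mask) || res$dice < dice_band[1]) {
      if (!is.null(res$mask)) {
        best <- res
        best_mag <- mid
      }
      hi <- mid
    } else if (res$dice > dice_band[2]) {
      lo <- mid
    } else {
      return(c(res, magnitude = mid))
    }
  }
  if (!is.null(best)) {
    return(c(best, magnitude = best_mag))
  }
  res <- mk(lo)
  if (is.null(res$mask)) {
    maskqc_error("data_error", "mask too small to corrupt")
  }
  c(res, magnitude = lo)
}

#' Site-like mask recipes emulating a multi-institutional cohort
#'
#' Ground-truth brain-mask cohorts pooled across several institutions
#' show between-site shape differences (scanner field of view, protocol,
#' population) that are larger than within-site variability — the very
#' structure the baseline clustering is meant to capture. This helper
#' returns a small family of recipes whose overall scale differs between
#' "sites" while the within-site jitter stays at the recipe default, so
#' cohorts drawn from it cluster the way a pooled real cohort does.
#'
#' @param ... Arguments forwarded to every [mask_recipe()] (e.g. `shape`,
#'   `spacing`); `semi_axes` is set per site and cannot be overridden.
#' @return List of three [mask_recipe()] objects.
#' @export
site_recipes <- function(...) {
  list(mask_recipe(semi_axes = c(70, 55, 50), ...),
       mask_recipe(semi_axes = c(78, 62, 57), ...),
       mask_recipe(semi_axes = c(62, 50, 46), ...))
}

#' Generate a cohort of clean and corrupted masks on disk
#'
#' Writes `n_clean` clean masks (cycling over the site recipes) and
#' `n_corrupt` corrupted variants (each derived from one of the written
#' clean masks, cycling over corruption kinds, with magnitudes
#' calibrated so every corrupt mask is sanity-positive by construction)
#' as NIfTI files plus a `manifest.csv`. Deterministic for a fixed seed.
#' `n_corrupt = 0` yields a clean-only (baseline) cohort.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_clean Number of clean masks (>= 1).
#' @param n_corrupt Number of corrupted masks (>= 0).
#' @param recipes A [mask_recipe()] or list of recipes cycled over the
#'   clean masks; defaults to the multi-site family [site_recipes()].
#' @param seed Integer master seed.
#' @param kinds Corruption kinds cycled over the corrupt masks.
#' @param dice_band Dice calibration band, see [calibrate_corruption()].
#' @return The manifest data.frame: `mask_id`, `file`, `status`, `kind`,
#'   `source_id`, `dice`, `hd95`, `sanity_positive`.
#' @export
generate_cohort <- function(out_dir, n_clean = 60L, n_corrupt = 40L,
                            recipes = site_recipes(), seed = 17L,
                            kinds = c("erode", "dilate", "punch_holes",
                                      "add_blob", "truncate_axial",
                                      "translate"),
                            dice_band = c(0.85, 0.93)) {
  stopifnot(n_clean >= 1L, n_corrupt >= 0L)
  if (inherits(recipes, "mask_recipe")) recipes <- list(recipes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      n_clean + n_corrupt))
  rows <- vector("list", n_clean + n_corrupt)
  cleans <- vector("list", n_clean)
  for (i in seq_len(n_clean)) {
    id <- sprintf("clean_%03d", i)
    rec_i <- recipes[[((i - 1L) %% length(recipes)) + 1L]]
    m <- generate_clean(rec_i, seeds[i], id = id)
    f <- file.path(out_dir, paste0(id, ".nii.gz"))
    write_mask(m, f)
    cleans[[i]] <- m
    rows[[i]] <- data.frame(mask_id = id, file = basename(f),
                            status = "clean", kind = NA_character_,
                            source_id = id, dice = 1, hd95 = 0,
                            sanity_positive = FALSE)
  }
  for (j in seq_len(n_corrupt)) {
    src_i <- ((j - 1L) %% n_clean) + 1L
    kind <- kinds[((j - 1L) %% length(kinds)) + 1L]
    id <- sprintf("corrupt_%03d_%s", j, kind)
    res <- calibrate_corruption(cleans[[src_i]], kind,
                                seed = seeds[n_clean + j],
                                dice_band = dice_band, id = id)
    h <- hd95(cleans[[src_i]], res$mask)
    f <- file.path(out_dir, paste0(id, ".nii.gz"))
    write_mask(res$mask, f)
    rows[[n_clean + j]] <- data.frame(
      mask_id = id, file = basename(f), status = "corrupt", kind = kind,
      source_id = cleans[[src_i]]$id, dice = res$dice, hd95 = h,
      sanity_positive = sanity_label(res$dice, h))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
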