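#' Construct a brain mask
#'
#' A `brain_mask` is the unit of quality control: a 3D binary volume plus
#' the physical voxel spacing taken from (or destined for) a NIfTI header.
#' Any voxel value greater than zero is treated as foreground, so masks
#' saved as 0/255 or probabilistic maps thresholded upstream are accepted.
#'
#' @param voxels 3D numeric/integer/logical array; values > 0 are foreground.
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param id Opaque identifier string carried through feature tables and
#'   score reports.
#' @return An object of class `brain_mask` with integer 0/1 `voxels`,
#'   `spacing`, and `id`.
#' @export
#' @examples
#' m <- brain_mask(array(c(0, 1), c(4, 4, 4)), spacing = c(1, 1, 2))
#' sum(m$voxels)
brain_mask <- function(voxels, spacing = c(1, 1, 1), id = "mask") {
  if (length(dim(voxels)) != 3L) {
    config_error("`voxels` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    config_error("`spacing` must be 3 strictly positive numbers (mm)")
  }
  vox <- array(as.integer(voxels > 0), dim = dim(voxels))
  structure(list(voxels = vox, spacing = spacing, id = as.character(id)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask '%s'> %s voxels, spacing %s mm, %d foreground\n",
              x$id, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

#' Read a binary mask from a NIfTI file
#'
#' Spacing is taken from the header `pixdim`; voxels are binarized
#' (value > 0 is foreground). The mask id defaults to the file name
#' stripped of its `.nii`/`.nii.gz` extension.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param id Optional identifier; defaults to the file stem.
#' @return A [brain_mask].
#' @export
read_mask <- function(path, id = NULL) {
  if (!file.exists(path)) {
    maskqc_error("data_error", sprintf("mask file not found: %s", path))
  }
  img <- RNifti::readNifti(path)
  if (is.null(id)) {
    id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  brain_mask(array(as.numeric(img), dim = dim(img)[1:3]),
             spacing = RNifti::pixdim(img)[1:3], id = id)
}

#' Write a brain mask to a NIfTI file
#'
#' @param mask A [brain_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "brain_mask"))
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read all NIfTI masks in a directory
#'
#' @param dir Directory containing `.nii`/`.nii.gz` files.
#' @return A list of [brain_mask] objects, sorted by file name.
#' @export
read_mask_dir <- function(dir) {
  if (!dir.exists(dir)) {
    maskqc_error("data_error", sprintf("mask directory not found: %s", dir))
  }
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  lapply(files, read_mask)
}

# ---- low-level voxel helpers (internal) -------------------------------------

# Shift a 3D array by one voxel along `axis` (1..3) in direction `dir`
# (+1/-1), filling the vacated plane with `fill`. Used for erosion,
# dilation and surface extraction with 6-connectivity.
shift1 <- function(a, axis, dir, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (dir > 0) {
    idx_dst[[axis]] <- 2:n
    idx_src[[axis]] <- 1:(n - 1)
  } else {
    idx_dst[[axis]] <- 1:(n - 1)
    idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Count of face-adjacent foreground neighbours at every voxel, with
# outside-the-grid treated as background.
neighbor_count <- function(a) {
  s <- shift1(a, 1, +1) + shift1(a, 1, -1) +
       shift1(a, 2, +1) + shift1(a, 2, -1) +
       shift1(a, 3, +1) + shift1(a, 3, -1)
  s
}

# Logical array marking surface voxels: foreground with at least one
# face-adjacent background neighbour (grid boundary counts as background).
surface_voxels <- function(a) {
  a == 1L & neighbor_count(a) < 6L
}

binary_erode1 <- function(a) {
  array(as.integer(a == 1L & neighbor_count(a) == 6L), dim(a))
}

binary_dilate1 <- function(a) {
  array(as.integer(a == 1L | neighbor_count(a) > 0L), dim(a))
}

# Physical (mm) coordinates of the voxels marked TRUE/1 in `sel`,
# 0-based index times spacing; n x 3 matrix.
voxel_coords <- function(sel, spacing) {
  idx <- which(sel == 1L | sel == TRUE, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, `*`)
}

# Connected component containing the foreground voxel nearest the
# centroid, by seeded region growing under 6-connectivity. Returns the
# component as a 0/1 array; used to verify single-component invariants.
grow_component <- function(a) {
  if (sum(a) == 0L) empty_mask_error()
  idx <- which(a == 1L, arr.ind = TRUE)
  ctr <- colMeans(idx)
  seed_row <- which.min(rowSums(sweep(idx, 2, ctr, `-`)^2))
  comp <- array(0L, dim(a))
  comp[idx[seed_row, 1], idx[seed_row, 2], idx[seed_row, 3]] <- 1L
  repeat {
    grown <- array(as.integer(binary_dilate1(comp) & a == 1L), dim(a))
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

n_components <- function(a) {
  remaining <- a
  n <- 0L
  while (sum(remaining) > 0L) {
    comp <- grow_component(remaining)
    remaining <- array(as.integer(remaining == 1L & comp == 0L), dim(a))
    n <- n + 1L
  }
  n
}

# Evaluate `code` with a temporarily seeded RNG, restoring global state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}
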