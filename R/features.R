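#' Central moment matrix of a binary mask
#'
#' Computes the symmetric 3x3 second central moment matrix of the
#' foreground voxel cloud in physical (mm) coordinates, with unit weight
#' per voxel and the foreground centroid as reference point, together
#' with its eigen-decomposition.
#'
#' Convention: the diagonal holds the (non-negative) per-axis variances
#' about the centroid; off-diagonal entries carry a leading minus sign on
#' the mixed products, i.e. `M[a,b] = -(1/m) * sum(dx_a * dx_b)` for
#' `a != b`, in the style of product-of-inertia tensors. Eigenvalues are
#' returned sorted descending with matching orthonormal eigenvectors.
#'
#' @param mask A [brain_mask] with at least one foreground voxel.
#' @return A list of class `central_moments`: `matrix` (3x3, mm^2),
#'   `eigenvalues` (descending), `eigenvectors` (columns, orthonormal),
#'   `centroid` (mm), `n_voxels`.
#' @export
compute_central_moments <- function(mask) {
  stopifnot(inherits(mask, "brain_mask"))
  m <- sum(mask$voxels)
  if (m == 0L) empty_mask_error()
  xyz <- voxel_coords(mask$voxels, mask$spacing)
  centroid <- colMeans(xyz)
  d <- sweep(xyz, 2, centroid, `-`)
  cov_pop <- crossprod(d) / m
  M <- -cov_pop
  diag(M) <- diag(cov_pop)
  M <- (M + t(M)) / 2
  dimnames(M) <- NULL
  eig <- eigen(M, symmetric = TRUE)   # descending eigenvalues
  structure(list(matrix = M,
                 eigenvalues = eig$values,
                 eigenvectors = eig$vectors,
                 centroid = centroid,
                 n_voxels = m),
            class = "central_moments")
}

#' Names of the supported morphological features
#'
#' The catalogue holds 24 scalar shape descriptors computable from a
#' binary label alone; the default feature list used throughout the
#' package is the 23-entry subset that omits `border_surface_ratio`
#' (it is exactly `border_surface_area / surface_area`, both of which
#' are already in the list).
#'
#' @param default If `TRUE` (default) return the 23-feature default
#'   list; if `FALSE` the full 24-entry catalogue.
#' @return Character vector of feature names in canonical order.
#' @export
feature_catalogue <- function(default = TRUE) {
  full <- c(
    "voxel_count", "physical_size",
    "surface_area", "border_surface_area", "border_surface_ratio",
    "border_voxel_count",
    "elongation", "flatness", "roundness",
    "equiv_sphere_radius", "equiv_sphere_perimeter",
    "equiv_ellipsoid_diam_1", "equiv_ellipsoid_diam_2", "equiv_ellipsoid_diam_3",
    "feret_diameter",
    "principal_moment_1", "principal_moment_2", "principal_moment_3",
    "centroid_offset_1", "centroid_offset_2", "centroid_offset_3",
    "bbox_extent_1", "bbox_extent_2", "bbox_extent_3")
  if (default) setdiff(full, "border_surface_ratio") else full
}

# Fixed, deterministic quasi-uniform directions on the sphere (Fibonacci
# lattice); used for the caliper-diameter support search.
fibonacci_directions <- function(n = 321L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Maximum caliper (Feret) diameter of a point set: the extreme point
# along each probe direction is collected and the maximum pairwise
# distance among those candidates returned. Exact for convex hulls up to
# the angular resolution of the probe set.
feret_diameter <- function(pts, n_dir = 321L) {
  if (nrow(pts) < 2L) return(0)
  dirs <- fibonacci_directions(n_dir)
  proj <- pts %*% t(dirs)
  cand <- unique(rbind(pts[apply(proj, 2, which.max), , drop = FALSE],
                       pts[apply(proj, 2, which.min), , drop = FALSE]))
  d2 <- as.matrix(stats::dist(cand))
  max(d2)
}

# Exposed-face surface areas: list(total, border) in mm^2, counting faces
# between foreground and background (outside the grid = background);
# border faces are the subset lying on the grid boundary.
surface_areas <- function(a, spacing) {
  dims <- dim(a)
  face_area <- c(spacing[2] * spacing[3],
                 spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  total <- 0
  border <- 0
  for (ax in 1:3) {
    nb_plus <- shift1(a, ax, -1L)   # value of the +direction neighbour
    nb_minus <- shift1(a, ax, +1L)  # value of the -direction neighbour
    total <- total + (sum(a == 1L & nb_plus == 0L) +
                      sum(a == 1L & nb_minus == 0L)) * face_area[ax]
    first <- slice_count(a, ax, 1L)
    last <- slice_count(a, ax, dims[ax])
    border <- border + (first + last) * face_area[ax]
  }
  list(total = total, border = border)
}

slice_count <- function(a, axis, i) {
  idx <- lapply(dim(a), seq_len)
  idx[[axis]] <- i
  sum(a[idx[[1]], idx[[2]], idx[[3]]])
}

#' Extract morphological features from a mask
#'
#' Computes the requested shape descriptors of the foreground. Physical
#' units come from the mask spacing; centroid offsets are measured
#' relative to the physical centre of the volume so they quantify
#' off-centering rather than scanner coordinates. Elongation is
#' `sqrt(lambda1/lambda2)` and flatness `sqrt(lambda2/lambda3)` with
#' eigenvalues sorted descending, so both are >= 1 (degenerate zero
#' denominators yield 1). Roundness is the surface area of the
#' volume-equivalent sphere divided by the actual surface area.
#' Equivalent-ellipsoid diameters scale the principal-moment ellipsoid to
#' the foreground volume through the gamma-function unit-ball volume
#' `pi^(3/2)/gamma(5/2)`.
#'
#' @param mask A [brain_mask] with at least one foreground voxel.
#' @param feature_list Character vector of feature names drawn from
#'   [feature_catalogue()]; defaults to the 23-feature default list.
#' @return Named numeric vector in `feature_list` order, with attribute
#'   `mask_id`.
#' @export
#' @examples
#' cube <- array(0L, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- 1L
#' f <- extract_features(brain_mask(cube))
#' f[["voxel_count"]]; f[["physical_size"]]
extract_features <- function(mask, feature_list = feature_catalogue()) {
  stopifnot(inherits(mask, "brain_mask"))
  unknown <- setdiff(feature_list, feature_catalogue(default = FALSE))
  if (length(unknown) > 0) {
    config_error(paste0("unknown feature name(s): ",
                        paste(unknown, collapse = ", ")))
  }
  a <- mask$voxels
  sp <- mask$spacing
  m <- sum(a)
  if (m == 0L) empty_mask_error()

  mom <- compute_central_moments(mask)
  lam <- mom$eigenvalues                    # descending
  vol <- m * prod(sp)
  surf <- surface_areas(a, sp)

  idx <- which(a == 1L, arr.ind = TRUE)
  dims <- dim(a)
  on_border <- rowSums(idx == 1L | sweep(idx, 2, dims, `==`)) > 0
  bbox <- unname(apply(idx, 2, max) - apply(idx, 2, min) + 1) * sp

  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  sphere_perim <- 4 * pi * r_eq^2

  lam_pos <- pmax(lam, 0)
  unit_ball <- pi^(3 / 2) / gamma(5 / 2)    # 4*pi/3 via the gamma function
  lam_prod <- prod(sqrt(lam_pos))
  ell_diam <- if (lam_prod > 0) {
    2 * sqrt(lam_pos) * (vol / (unit_ball * lam_prod))^(1 / 3)
  } else {
    c(0, 0, 0)
  }

  safe_ratio <- function(num, den) if (den <= 0) 1 else sqrt(num / den)

  ctr_offset <- unname(mom$centroid) - (dims - 1) / 2 * sp

  surf_pts <- voxel_coords(surface_voxels(a), sp)

  vals <- c(
    voxel_count = as.numeric(m),
    physical_size = vol,
    surface_area = surf$total,
    border_surface_area = surf$border,
    border_surface_ratio = surf$border / surf$total,
    border_voxel_count = as.numeric(sum(on_border)),
    elongation = safe_ratio(lam_pos[1], lam_pos[2]),
    flatness = safe_ratio(lam_pos[2], lam_pos[3]),
    roundness = sphere_perim / surf$total,
    equiv_sphere_radius = r_eq,
    equiv_sphere_perimeter = sphere_perim,
    equiv_ellipsoid_diam_1 = ell_diam[1],
    equiv_ellipsoid_diam_2 = ell_diam[2],
    equiv_ellipsoid_diam_3 = ell_diam[3],
    feret_diameter = feret_diameter(surf_pts),
    principal_moment_1 = lam[1],
    principal_moment_2 = lam[2],
    principal_moment_3 = lam[3],
    centroid_offset_1 = ctr_offset[1],
    centroid_offset_2 = ctr_offset[2],
    centroid_offset_3 = ctr_offset[3],
    bbox_extent_1 = bbox[1],
    bbox_extent_2 = bbox[2],
    bbox_extent_3 = bbox[3])

  out <- vals[feature_list]
  attr(out, "mask_id") <- mask$id
  out
}

#' Feature table for a set of masks
#'
#' @param masks List of [brain_mask] objects.
#' @param feature_list Feature names, as in [extract_features()].
#' @return A data.frame with `mask_id` plus one column per feature, one
#'   row per mask, suitable for writing as CSV.
#' @export
feature_table <- function(masks, feature_list = feature_catalogue()) {
  rows <- lapply(masks, extract_features, feature_list = feature_list)
  df <- as.data.frame(do.call(rbind, rows))
  data.frame(mask_id = vapply(masks, function(m) m$id, character(1)),
             df, check.names = FALSE)
}

#' Fit a z-score feature scaler
#'
#' Stores the per-feature mean and population (divide-by-N) standard
#' deviation of the fitted set, so that transforming the fitted set
#' yields exactly zero mean and unit variance per feature. Features with
#' zero spread are flagged constant and their std replaced by 1, mapping
#' them to 0 after transform.
#'
#' @param x Numeric matrix (rows = masks, columns = features, named) or a
#'   data.frame from [feature_table()].
#' @return An object of class `feature_scaler` with `means`, `stds`,
#'   `constant` (logical), `feature_names`.
#' @export
fit_scaler <- function(x) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2L) {
    insufficient_data_error("scaler fitting needs at least 2 feature vectors")
  }
  means <- colMeans(x)
  stds <- sqrt(colMeans(sweep(x, 2, means, `-`)^2))
  constant <- stds < 1e-12
  stds[constant] <- 1
  structure(list(means = means, stds = stds, constant = constant,
                 feature_names = colnames(x)),
            class = "feature_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler A [fit_scaler()] result.
#' @param x Named feature vector, matrix, or data.frame with the same
#'   feature names in the same order as at fitting time.
#' @return Normalized matrix (or vector if the input was one row).
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  vec_in <- is.null(dim(x)) || (is.numeric(x) && length(dim(x)) < 2)
  x <- as_feature_matrix(x)
  if (!identical(colnames(x), scaler$feature_names)) {
    config_error("feature names/order do not match the fitted scaler")
  }
  out <- sweep(sweep(x, 2, scaler$means, `-`), 2, scaler$stds, `/`)
  if (vec_in && nrow(out) == 1L) out[1, ] else out
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[, setdiff(names(x), "mask_id"), drop = FALSE])
  } else if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  }
  storage.mode(x) <- "double"
  x
}
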