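# Image quantification: maximum projections, projection-based Lamin level,
# 3D nuclear segmentation, projection morphometry, junction-based apical
# areas and the apico-basal intensity-profile check.

#' Maximum intensity projection
#'
#' Per-pixel maximum of one channel along the z or y axis. The returned
#' matrix carries a \code{"pixel_size"} attribute with the physical sizes
#' of its two axes in um, so downstream fits work in physical units: the
#' z projection is isotropic (\code{voxel_xy}, \code{voxel_xy}); the y
#' projection is anisotropic (\code{voxel_xy}, \code{voxel_z}).
#'
#' @param stack An [image_stack()].
#' @param axis \code{"z"} or \code{"y"}.
#' @param channel Channel name.
#' @return Numeric matrix with attribute \code{pixel_size}.
#' @export
max_project <- function(stack, axis = c("z", "y"), channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  axis <- match.arg(axis)
  a <- get_channel(stack, channel)
  if (axis == "z") {
    proj <- apply(a, c(1, 2), max)
    attr(proj, "pixel_size") <- c(stack$voxel_xy, stack$voxel_xy)
  } else {
    proj <- apply(a, c(1, 3), max)
    attr(proj, "pixel_size") <- c(stack$voxel_xy, stack$voxel_z)
  }
  proj
}

get_channel <- function(stack, channel) {
  if (is.numeric(channel)) return(stack$channels[[channel]])
  if (!channel %in% names(stack$channels))
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(names(stack$channels), collapse = ", ")),
         call. = FALSE)
  stack$channels[[channel]]
}

#' Projection-based Lamin level
#'
#' The thresholded-projection estimator used for whole-mount tissue
#' stacks: the channel is maximum-projected along z, the projection is
#' binarised by automatic (Otsu) thresholding, the mask is multiplied with
#' the projection to select nuclear pixels, and the mean intensity per
#' in-mask pixel is reported as the Lamin level.
#'
#' @param stack An [image_stack()].
#' @param channel Lamin channel name.
#' @param threshold Optional manual threshold overriding Otsu.
#' @return List of class \code{"intensity_report"}: \code{mean_intensity},
#'   \code{total_intensity}, \code{n_pixels}.
#' @export
lamin_level_projection <- function(stack, channel = "lamin",
                                   threshold = NULL) {
  proj <- max_project(stack, "z", channel)
  thr <- if (is.null(threshold)) otsu_threshold(proj) else threshold
  mask <- proj > thr
  if (!any(mask))
    stop("degenerate image: empty mask after thresholding", call. = FALSE)
  masked <- proj * mask
  intensity_report(sum(masked), sum(mask))
}

intensity_report <- function(total, n) {
  structure(list(mean_intensity = total / n, total_intensity = total,
                 n_pixels = as.integer(n)),
            class = "intensity_report")
}

#' @export
print.intensity_report <- function(x, ...) {
  cat(sprintf("<intensity_report> mean %.4g a.u./px over %d px (total %.4g)\n",
              x$mean_intensity, x$n_pixels, x$total_intensity))
  invisible(x)
}

#' Segment the nucleus in 3D
#'
#' Global automatic (Otsu) threshold on the volumetric channel, retention
#' of the largest 3D connected component, slice-wise despeckling
#' (morphological opening, which strips single-voxel noise fringe off the
#' blurred boundary) and slice-wise hole filling. Intended for fields with
#' one dominant, sparsely labelled nucleus.
#'
#' @param stack An [image_stack()].
#' @param channel Volumetric (DAPI-like) channel name.
#' @param threshold Optional manual threshold overriding Otsu.
#' @param despeckle Apply the 3x3 opening (default TRUE).
#' @return Object of class \code{"nuclear_mask"}: logical 3D \code{mask}
#'   plus \code{voxel_xy}, \code{voxel_z}.
#' @export
segment_nucleus_3d <- function(stack, channel = "dapi", threshold = NULL,
                               despeckle = TRUE) {
  a <- get_channel(stack, channel)
  thr <- if (is.null(threshold)) otsu_threshold(a) else threshold
  fg <- a > thr
  if (!any(fg))
    stop("segmentation failed: no foreground voxels above threshold",
         call. = FALSE)
  mask <- largest_component_3d(fg)
  if (despeckle) {
    br <- EBImage::makeBrush(3, "box")
    for (z in seq_len(dim(mask)[3])) {
      sl <- mask[, , z]
      if (any(sl))
        mask[, , z] <- as.matrix(EBImage::opening(sl * 1L, br)) > 0
    }
    if (!any(mask))
      stop("segmentation failed: foreground vanished after despeckling",
           call. = FALSE)
    mask <- largest_component_3d(mask)
  }
  for (z in seq_len(dim(mask)[3])) {
    sl <- mask[, , z]
    if (any(sl))
      mask[, , z] <- as.matrix(EBImage::fillHull(sl * 1L)) > 0
  }
  structure(list(mask = mask, voxel_xy = stack$voxel_xy,
                 voxel_z = stack$voxel_z),
            class = "nuclear_mask")
}

#' @export
print.nuclear_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<nuclear_mask> %d voxels set in %d x %d x %d grid\n",
              sum(x$mask), d[1], d[2], d[3]))
  invisible(x)
}

# largest 26/8-connected 3D component: per-slice 2D labelling merged
# across adjacent slices with union-find
largest_component_3d <- function(fg) {
  d <- dim(fg)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(i, j) {
    ri <- find_root(i); rj <- find_root(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  labs <- array(0L, d)
  offset <- 0L
  prev <- NULL
  for (z in seq_len(d[3])) {
    sl <- matrix(as.integer(EBImage::bwlabel(fg[, , z] * 1L)), d[1], d[2])
    nl <- max(sl)
    if (nl > 0) sl[sl > 0] <- sl[sl > 0] + offset
    parent <- c(parent, seq_len(nl) + offset)
    if (!is.null(prev) && nl > 0) {
      ov <- sl > 0 & prev > 0
      if (any(ov)) {
        pairs <- unique(cbind(sl[ov], prev[ov]))
        for (r in seq_len(nrow(pairs))) link(pairs[r, 1], pairs[r, 2])
      }
    }
    labs[, , z] <- sl
    prev <- sl
    offset <- offset + nl
  }
  roots <- vapply(seq_along(parent), find_root, integer(1))
  vox <- labs[labs > 0]
  counts <- tabulate(roots[vox], nbins = length(parent))
  best <- which.max(counts)
  out <- array(FALSE, d)
  out[labs > 0] <- roots[vox] == best
  out
}

#' Nuclear morphometry from a 3D mask
#'
#' Measures the quantities of the nuclear deformation index: the
#' cross-sectional area is the area of the z-axis maximum projection of
#' the mask (voxel area applied); the height is the axial axis length of a
#' second-moment (image-covariance) ellipse fit to the y-axis maximum
#' projection, computed in physical um so voxel anisotropy cancels. For a
#' flattened (oblate) nucleus this axis is the minor axis of the fitted
#' ellipse. The axis-length convention is \code{4 sqrt(eigenvalue)}, which
#' is exact for a filled ellipse.
#'
#' @param mask A \code{"nuclear_mask"}.
#' @return List of class \code{"nuclear_morphology"}:
#'   \code{cross_section_area} (um^2), \code{height} (um), \code{d_nuc}.
#' @export
nucleus_morphometry <- function(mask) {
  stopifnot(inherits(mask, "nuclear_mask"))
  m <- mask$mask
  if (length(unique(which(apply(m, 3, any)))) < 2)
    stop("degenerate mask: spans a single z plane", call. = FALSE)
  zproj <- apply(m, c(1, 2), any)
  area <- sum(zproj) * mask$voxel_xy^2
  yproj <- apply(m, c(1, 3), any)
  idx <- which(yproj, arr.ind = TRUE)
  xs <- (idx[, 1] - 0.5) * mask$voxel_xy
  zs <- (idx[, 2] - 0.5) * mask$voxel_z
  # second moments with the per-voxel uniform-density correction
  cv <- stats::cov(cbind(xs, zs)) * (nrow(idx) - 1) / nrow(idx)
  cv[1, 1] <- cv[1, 1] + mask$voxel_xy^2 / 12
  cv[2, 2] <- cv[2, 2] + mask$voxel_z^2 / 12
  eg <- eigen(cv, symmetric = TRUE)
  axial <- which.max(abs(eg$vectors[2, ])) # eigenvector most aligned with z
  height <- 4 * sqrt(eg$values[axial])
  structure(list(cross_section_area = area, height = height,
                 d_nuc = nuclear_deformation_index(area, height)),
            class = "nuclear_morphology")
}

#' @export
print.nuclear_morphology <- function(x, ...) {
  cat(sprintf("<nuclear_morphology> A_n = %.4g um^2, h_n = %.4g um, D_nuc = %.4g\n",
              x$cross_section_area, x$height, x$d_nuc))
  invisible(x)
}

#' Cell height from the nucleus
#'
#' For columnar cells whose nucleus sits at the base, the cell height is
#' estimated as the nuclear height plus the distance from the top of the
#' nucleus to the top of the cell.
#'
#' @param mask A \code{"nuclear_mask"}.
#' @param cell_top_z Physical z coordinate of the cell top, um (measured
#'   from the basal face of the stack); must be at or above the nucleus
#'   top.
#' @return Cell height in um.
#' @export
cell_height_from_nucleus <- function(mask, cell_top_z) {
  stopifnot(inherits(mask, "nuclear_mask"))
  morph <- nucleus_morphometry(mask)
  nucleus_top <- max(which(apply(mask$mask, 3, any))) * mask$voxel_z
  if (cell_top_z < nucleus_top)
    stop("cell_top_z lies below the top of the nucleus", call. = FALSE)
  morph$height + (cell_top_z - nucleus_top)
}

#' Lamin intensity inside a 3D nuclear mask
#'
#' Total channel intensity of the masked 3D nucleus (total Lamin) and the
#' per-voxel mean (Lamin level).
#'
#' @param stack An [image_stack()].
#' @param mask A \code{"nuclear_mask"} aligned to the stack.
#' @param channel Lamin channel name.
#' @return An \code{"intensity_report"}.
#' @export
lamin_in_nucleus_3d <- function(stack, mask, channel = "lamin") {
  stopifnot(inherits(mask, "nuclear_mask"))
  a <- get_channel(stack, channel)
  if (!identical(dim(a), dim(mask$mask)))
    stop("mask is not aligned to the stack", call. = FALSE)
  n <- sum(mask$mask)
  if (n == 0) stop("empty mask", call. = FALSE)
  intensity_report(sum(a[mask$mask]), n)
}

#' Apico-basal intensity profile
#'
#' Mean in-mask intensity per z plane, and the ratio of the top-quartile
#' to bottom-quartile plane means. A ratio near 1 indicates that the
#' epitope is detected equally on the apical and basal sides of the
#' nucleus (no conformation-dependent masking).
#'
#' @inheritParams lamin_in_nucleus_3d
#' @return List: \code{profile} (tibble \code{z_um}, \code{mean_intensity}),
#'   \code{apical_basal_ratio}.
#' @export
apicobasal_profile <- function(stack, mask, channel = "lamin") {
  stopifnot(inherits(mask, "nuclear_mask"))
  a <- get_channel(stack, channel)
  planes <- which(apply(mask$mask, 3, any))
  if (length(planes) < 4)
    stop("mask spans fewer than 4 z planes; profile undefined", call. = FALSE)
  prof <- vapply(planes, function(z) {
    sel <- mask$mask[, , z]
    mean(a[, , z][sel])
  }, numeric(1))
  nq <- ceiling(length(planes) / 4)
  ratio <- mean(utils::tail(prof, nq)) / mean(utils::head(prof, nq))
  list(profile = tibble::tibble(z_um = (planes - 0.5) * mask$voxel_z,
                                mean_intensity = prof),
       apical_basal_ratio = ratio)
}

#' Apical cell areas from a junction-network image
#'
#' Binarises the bright junction ridges by automatic thresholding, inverts
#' the network to label the enclosed cells, assigns ridge pixels to their
#' nearest cell so ridge thickness does not bite into the areas, discards
#' border-touching cells, and reports per-cell areas in um^2.
#'
#' @param image Numeric matrix: bright ridges on dark cells.
#' @param pixel_size Pixel size in um.
#' @param threshold Optional manual ridge threshold overriding Otsu.
#' @param min_area_px Labelled regions smaller than this are treated as
#'   noise specks and dropped before ridge assignment.
#' @return Tibble: \code{cell_id}, \code{area_um2}, \code{centroid_x},
#'   \code{centroid_y} (um).
#' @export
apical_areas_from_junctions <- function(image, pixel_size = 1,
                                        threshold = NULL, min_area_px = 9L) {
  stopifnot(is.matrix(image))
  thr <- if (is.null(threshold)) otsu_threshold(image) else threshold
  ridge <- image > thr
  cells <- matrix(as.integer(EBImage::bwlabel((!ridge) * 1L)),
                  nrow(image), ncol(image))
  counts <- tabulate(cells, nbins = max(cells))
  drop <- which(counts < min_area_px)
  if (length(drop)) cells[cells %in% drop] <- 0L
  if (!any(cells > 0))
    stop("no enclosed regions found in the junction image", call. = FALSE)
  cells <- grow_labels(cells)
  nx <- nrow(cells); ny <- ncol(cells)
  border_ids <- setdiff(unique(c(cells[1, ], cells[nx, ],
                                 cells[, 1], cells[, ny])), 0L)
  keep <- setdiff(sort(unique(cells[cells > 0])), border_ids)
  if (length(keep) == 0)
    stop("all enclosed regions touch the image border", call. = FALSE)
  idx <- which(cells %in% keep)
  lab <- cells[idx]
  ix <- (idx - 1L) %% nx + 1L
  iy <- (idx - 1L) %/% nx + 1L
  cnt <- tabulate(factor(lab, levels = keep))
  cx <- tapply((ix - 0.5) * pixel_size, factor(lab, levels = keep), mean)
  cy <- tapply((iy - 0.5) * pixel_size, factor(lab, levels = keep), mean)
  tibble::tibble(cell_id = seq_along(keep),
                 area_um2 = cnt * pixel_size^2,
                 centroid_x = as.numeric(cx), centroid_y = as.numeric(cy))
}

# assign unlabelled (ridge) pixels to an adjacent label, iterating until
# no pixel changes; deterministic neighbour priority (left, right, up, down)
grow_labels <- function(lab) {
  nx <- nrow(lab); ny <- ncol(lab)
  repeat {
    un <- lab == 0L
    if (!any(un)) break
    cand <- matrix(0L, nx, ny)
    take <- function(cand, src) {
      sel <- un & cand == 0L & src > 0L
      cand[sel] <- src[sel]
      cand
    }
    left <- rbind(lab[-1, , drop = FALSE], 0L)
    right <- rbind(0L, lab[-nx, , drop = FALSE])
    up <- cbind(lab[, -1, drop = FALSE], 0L)
    down <- cbind(0L, lab[, -ny, drop = FALSE])
    cand <- take(cand, left); cand <- take(cand, right)
    cand <- take(cand, up); cand <- take(cand, down)
    changed <- cand > 0L
    if (!any(changed)) break
    lab[changed] <- cand[changed]
  }
  lab
}

#' Write / read an image stack as TIFF with a JSON sidecar
#'
#' Each channel goes to \code{<prefix>_<channel>.tif} as a multi-page
#' 16-bit TIFF (one page per z plane); voxel sizes, channel names and a
#' per-channel intensity scale are stored in \code{<prefix>.json}.
#'
#' @param stack An [image_stack()].
#' @param prefix Path prefix (no extension).
#' @return \code{write_image_stack}: the prefix, invisibly;
#'   \code{read_image_stack}: an [image_stack()].
#' @export
write_image_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "image_stack"))
  scales <- vapply(stack$channels, function(a) max(a, 1e-12), numeric(1))
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]] / scales[[ch]]
    pages <- lapply(seq_len(dim(a)[3]), function(z) a[, , z])
    tiff::writeTIFF(pages, paste0(prefix, "_", ch, ".tif"),
                    bits.per.sample = 16, compression = "none",
                    reduce = FALSE)
  }
  jsonlite::write_json(
    list(voxel_xy_um = stack$voxel_xy, voxel_z_um = stack$voxel_z,
         channels = as.list(scales)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  chans <- lapply(names(meta$channels), function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    a <- array(0, c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) a[, , z] <- pages[[z]]
    a * meta$channels[[ch]]
  })
  names(chans) <- names(meta$channels)
  image_stack(chans, meta$voxel_xy_um, meta$voxel_z_um)
}
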