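#' Construct a volume object
#'
#' The unit of subject-level I/O: a 3D scalar grid with voxel spacing.
#' The third array axis is the axial (slice) axis.
#'
#' @param data 3D numeric array.
#' @param voxel_size_mm Positive length-3 voxel size in mm; default is the
#'   acquisition geometry of high-resolution axial T2 at 3T,
#'   `c(0.69, 0.69, 2)`.
#' @param subject_id Identifier carried through slicing, prediction and
#'   reporting.
#' @return Object of class `pvs_volume`.
#' @export
pvs_volume <- function(data, voxel_size_mm = c(0.69, 0.69, 2),
                       subject_id = "subject") {
  stopifnot(length(dim(data)) == 3L, length(voxel_size_mm) == 3L,
            all(voxel_size_mm > 0))
  if (!all(is.finite(data))) stop("volume contains non-finite voxels")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 subject_id = subject_id),
            class = "pvs_volume")
}

#' @export
print.pvs_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pvs_volume '%s'> %d x %d x %d voxels, %.2f x %.2f x %.2f mm\n",
              x$subject_id, d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a single 3D
#'   scalar image.
#' @param mask If `TRUE`, require values in `{0, 1}` (a label volume).
#' @param subject_id Identifier; defaults to the file name stem.
#' @return A [pvs_volume()].
#' @export
read_volume <- function(path, mask = FALSE, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img <- array(img, d[1:3])
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop("expected a 3D single-channel volume, got ", length(d), " dimensions")
  }
  dat <- array(as.numeric(img), d)
  if (!all(is.finite(dat))) stop("volume contains non-finite voxels")
  if (mask && !all(dat %in% c(0, 1))) {
    stop("label volume contains values outside {0, 1}")
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  pvs_volume(dat, voxel_size_mm = RNifti::pixdim(img)[1:3],
             subject_id = subject_id)
}

#' Write a volume to NIfTI
#'
#' Images are written as 32-bit float, masks as unsigned 8-bit with values
#' in `{0, 1}`; voxel size goes into the header.
#'
#' @param volume A [pvs_volume()] or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param mask Write as a label volume.
#' @param voxel_size_mm Required when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, mask = FALSE, voxel_size_mm = NULL) {
  if (inherits(volume, "pvs_volume")) {
    dat <- volume$data
    voxel_size_mm <- volume$voxel_size_mm
  } else {
    dat <- volume
    if (is.null(voxel_size_mm)) stop("voxel_size_mm required for bare arrays")
  }
  if (mask && !all(dat %in% c(0, 1))) {
    stop("mask values must lie in {0, 1}")
  }
  attr(dat, "pixdim") <- voxel_size_mm
  RNifti::writeNifti(RNifti::asNifti(dat), path,
                     datatype = if (mask) "uint8" else "float")
  invisible(path)
}

#' Z-score intensity normalisation
#'
#' Rescales a volume to zero mean and unit variance (population variance),
#' removing per-scanner intensity scale and offset; the z-score is
#' invariant under any positive affine rescaling of the input. A constant
#' volume is mapped to all zeros with a warning.
#'
#' @param volume A [pvs_volume()].
#' @return The normalised [pvs_volume()].
#' @export
normalize_volume <- function(volume) {
  x <- volume$data
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    warning("constant volume: normalised to all zeros")
    volume$data <- array(0, dim(x))
  } else {
    volume$data <- (x - m) / s
  }
  volume
}

#' Decompose a volume into padded axial slice pairs
#'
#' Produces one image (and optionally label) matrix per axial slice,
#' zero-padded symmetrically so both sides are divisible by `pad_to`
#' (use `2^(levels - 1)` for a network with `levels` resolution rows).
#' Padding, not resizing: interpolation would blur the thin structures the
#' segmenter must keep. The padding geometry is recorded for exact
#' inversion by [reassemble()].
#'
#' @param image A [pvs_volume()].
#' @param label Optional aligned binary [pvs_volume()] (absent at
#'   inference).
#' @param pad_to Required side multiple (default 8).
#' @return Object of class `slice_set`: list with `images` (list of
#'   matrices), `labels` (list or `NULL`), `slice_index`, `subject_id`,
#'   `pad` (`row_lo`, `row_hi`, `col_lo`, `col_hi`), `orig_dim`,
#'   `voxel_size_mm`.
#' @export
to_slices <- function(image, label = NULL, pad_to = 8L) {
  stopifnot(pad_to >= 1L)
  d <- dim(image$data)
  if (!is.null(label)) {
    if (!identical(dim(label$data), d)) {
      stop("image and label grids are not aligned: ",
           paste(d, collapse = "x"), " vs ",
           paste(dim(label$data), collapse = "x"))
    }
    if (!all(label$data %in% c(0, 1))) stop("label values must be 0/1")
  }
  pad_of <- function(n) {
    total <- (pad_to - n %% pad_to) %% pad_to
    c(lo = total %/% 2L, hi = total - total %/% 2L)
  }
  pr <- pad_of(d[1L]); pc <- pad_of(d[2L])
  pad_mat <- function(m) {
    out <- matrix(0, d[1L] + pr["lo"] + pr["hi"], d[2L] + pc["lo"] + pc["hi"])
    out[pr["lo"] + seq_len(d[1L]), pc["lo"] + seq_len(d[2L])] <- m
    out
  }
  images <- lapply(seq_len(d[3L]), function(k) pad_mat(image$data[, , k]))
  labels <- if (is.null(label)) NULL else {
    lapply(seq_len(d[3L]), function(k) pad_mat(label$data[, , k]))
  }
  structure(list(
    images = images, labels = labels, slice_index = seq_len(d[3L]) - 1L,
    subject_id = image$subject_id,
    pad = list(row_lo = unname(pr["lo"]), row_hi = unname(pr["hi"]),
               col_lo = unname(pc["lo"]), col_hi = unname(pc["hi"])),
    orig_dim = d, voxel_size_mm = image$voxel_size_mm
  ), class = "slice_set")
}

#' @export
print.slice_set <- function(x, ...) {
  cat(sprintf(
    "<slice_set '%s'> %d slices of %d x %d (padded from %d x %d)%s\n",
    x$subject_id, length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
    x$orig_dim[1], x$orig_dim[2],
    if (is.null(x$labels)) "" else ", with labels"))
  invisible(x)
}

#' Reassemble per-slice probability maps into a 3D binary mask
#'
#' Crops the recorded padding and stacks slices back along z. A voxel is
#' foreground iff its probability strictly exceeds `threshold` (a value
#' exactly at the threshold stays background; the strict rule makes the
#' binarisation bit-reproducible).
#'
#' @param maps List of per-slice probability matrices (padded geometry),
#'   one per slice, in slice order.
#' @param geometry A `slice_set` (or list with `pad`, `orig_dim`,
#'   `voxel_size_mm`, `subject_id`) describing the padding to invert.
#' @param threshold Probability threshold, default 0.5.
#' @return Binary mask as a [pvs_volume()].
#' @export
reassemble <- function(maps, geometry, threshold = 0.5) {
  d <- geometry$orig_dim
  if (length(maps) != d[3L]) {
    stop("expected ", d[3L], " slice maps, got ", length(maps))
  }
  pad <- geometry$pad
  out <- array(0, d)
  rows <- pad$row_lo + seq_len(d[1L])
  cols <- pad$col_lo + seq_len(d[2L])
  for (k in seq_len(d[3L])) {
    m <- maps[[k]]
    if (nrow(m) != d[1L] + pad$row_lo + pad$row_hi ||
        ncol(m) != d[2L] + pad$col_lo + pad$col_hi) {
      stop("slice ", k, " has inconsistent shape")
    }
    out[, , k] <- (m[rows, cols] > threshold) + 0
  }
  pvs_volume(out, voxel_size_mm = geometry$voxel_size_mm,
             subject_id = geometry$subject_id)
}
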