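# Readers/writers, intensity normalization, resampling, and study pairing.
#
# Coordinate convention (documented for center-of-mass reporting): row index
# runs anterior -> posterior (AP), column index right -> left (RL), slice
# ordering superior -> inferior (SI); indices are reported 0-based.

#' Construct an MR slice
#'
#' Lightweight container for one 2-D slice: an intensity matrix, its modality,
#' pixel spacing in mm, and the source intensity range.
#'
#' @param intensities Numeric matrix (H x W), all values finite.
#' @param modality One of \code{"T1pre"}, \code{"T2"}, \code{"T1ce"}.
#' @param spacing Length-2 numeric, mm per pixel (row, col).
#' @return A list of class \code{mr_slice}.
#' @export
mr_slice <- function(intensities, modality = c("T1pre", "T2", "T1ce"),
                     spacing = c(1, 1)) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(intensities), nrow(intensities) > 0, ncol(intensities) > 0)
  if (!all(is.finite(intensities)))
    abort("mr_slice intensities must all be finite.")
  structure(list(intensities = intensities, modality = modality,
                 spacing = as.numeric(spacing),
                 intensity_range = range(intensities)),
            class = "mr_slice")
}

#' @export
print.mr_slice <- function(x, ...) {
  cat(sprintf("<mr_slice %s  %d x %d  spacing %.3g x %.3g mm  range [%.4g, %.4g]>\n",
              x$modality, nrow(x$intensities), ncol(x$intensities),
              x$spacing[1], x$spacing[2],
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

write_png_255 <- function(mat, path) {
  png::writePNG(pmin(pmax(round(mat), 0), 255) / 255, path)
}

#' Read one slice from disk
#'
#' Supports 8/16-bit PNG and NIfTI (\code{.nii}/\code{.nii.gz}). PNG
#' intensities are rescaled to \code{[0,255]}; NIfTI intensities are returned
#' as stored with spacing taken from the header. PNG spacing defaults to
#' 1.0 mm unless supplied (e.g. from a manifest). DICOM series are not
#' supported by this build.
#'
#' @param path File path.
#' @param modality Modality label for the returned slice.
#' @param spacing Optional spacing override in mm (row, col).
#' @return An [mr_slice()].
#' @export
read_slice <- function(path, modality = "T1pre", spacing = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read slice: file not found: ", path))
  lower <- tolower(path)
  img <- tryCatch({
    if (grepl("\\.png$", lower)) {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]
      a * 255
    } else if (grepl("\\.nii(\\.gz)?$", lower)) {
      v <- RNifti::readNifti(path)
      pd <- RNifti::pixdim(v)
      a <- as.array(v)
      if (length(dim(a)) == 3L) a <- a[, , 1L]
      if (is.null(spacing)) spacing <- pd[1:2]
      a
    } else {
      abort(paste0("unsupported slice format: ", path))
    }
  }, error = function(e) abort(paste0("failed to read ", path, ": ", conditionMessage(e))))
  mr_slice(img, modality, spacing %||% c(1, 1))
}

#' Write one slice to disk
#'
#' PNG output is quantized to 8 bit assuming a \code{[0,255]} scale; NIfTI
#' output stores intensities and spacing as-is.
#'
#' @param slice An [mr_slice()] (or bare matrix, assumed \code{[0,255]}).
#' @param path Destination ending in \code{.png}, \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
write_slice <- function(slice, path) {
  mat <- if (inherits(slice, "mr_slice")) slice$intensities else slice
  sp <- if (inherits(slice, "mr_slice")) slice$spacing else c(1, 1)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    write_png_255(mat, path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    hdr <- RNifti::niftiHeader(list(
      dim = c(3, nrow(mat), ncol(mat), 1, 1, 1, 1, 1),
      pixdim = c(-1, sp[1], sp[2], 1, 0, 0, 0, 0)))
    v <- RNifti::asNifti(array(mat, c(dim(mat), 1L)), reference = hdr)
    RNifti::writeNifti(v, path)
  } else abort(paste0("unsupported slice format: ", path))
  invisible(path)
}

# exact area-averaging resize matrix: each output cell averages the source
# interval it covers (handles non-integer ratios such as 640 -> 256)
area_weights <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  r <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * r
    hi <- i * r
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) A[i, j] <- ov / r
    }
  }
  A
}

linear_weights <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  for (i in seq_len(n_out)) {
    p <- min(max(pos[i], 1), n_in)
    j0 <- floor(p); j1 <- min(j0 + 1, n_in)
    f <- p - j0
    A[i, j0] <- A[i, j0] + (1 - f)
    A[i, j1] <- A[i, j1] + f
  }
  A
}

#' Resample a slice to a target size
#'
#' Downsampling uses exact area averaging (so constants are preserved and
#' non-integer ratios such as 640 to 256 are handled); upsampling falls back
#' to bilinear interpolation with a warning. Spacing is rescaled so the
#' physical extent is preserved.
#'
#' @param slice An [mr_slice()].
#' @param target Target side length in pixels; must be divisible by 4.
#' @return A resampled [mr_slice()].
#' @export
resample_to <- function(slice, target) {
  stopifnot(inherits(slice, "mr_slice"))
  if (target %% 4 != 0) abort("`target` must be divisible by 4.")
  H <- nrow(slice$intensities); W <- ncol(slice$intensities)
  if (H == target && W == target) return(slice)
  up <- target > H || target > W
  if (up) warn("resample_to: upsampling via bilinear interpolation.")
  Ar <- if (target < H) area_weights(H, target) else linear_weights(H, target)
  Ac <- if (target < W) area_weights(W, target) else linear_weights(W, target)
  out <- Ar %*% slice$intensities %*% t(Ac)
  mr_slice(out, slice$modality, slice$spacing * c(H, W) / target)
}

#' Normalize slice intensities
#'
#' \code{metric_255}: clip at the 0.5 and 99.5 intensity percentiles, then
#' map affinely to \code{[0,255]} — the scale on which all image-quality
#' metrics are computed (their formulas assume an 8-bit dynamic range,
#' L = 255). \code{model_pm1}: affine map of the \code{metric_255} result to
#' \code{[-1,1]}, the range the tanh-output generator operates on.
#'
#' @param slice An [mr_slice()].
#' @param mode \code{"metric_255"} or \code{"model_pm1"}.
#' @param probs Clipping percentiles for \code{metric_255}.
#' @return A normalized [mr_slice()].
#' @export
normalize <- function(slice, mode = c("metric_255", "model_pm1"),
                      probs = c(0.005, 0.995)) {
  stopifnot(inherits(slice, "mr_slice"))
  mode <- match.arg(mode)
  x <- slice$intensities
  q <- quantile(x, probs, names = FALSE)
  if (q[2] <= q[1]) {
    warn("normalize: constant image; mapping to the scale minimum.")
    y <- matrix(0, nrow(x), ncol(x))
  } else {
    y <- (pmin(pmax(x, q[1]), q[2]) - q[1]) / (q[2] - q[1]) * 255
  }
  if (mode == "model_pm1") y <- y / 127.5 - 1
  mr_slice(y, slice$modality, slice$spacing)
}

#' Map a model-scale image back to the metric scale
#'
#' Inverse of the \code{model_pm1} affine: \code{(x + 1) * 127.5}.
#'
#' @param x Numeric matrix or array on \code{[-1,1]}.
#' @return The same object on \code{[0,255]}.
#' @export
to_metric_scale <- function(x) (x + 1) * 127.5

#' Load and validate a study manifest
#'
#' Reads the manifest CSV written by [make_dataset()] (columns
#' \code{study_id}, \code{split}, per-modality paths, \code{spacing_mm}),
#' resolves relative paths against the manifest's directory, and validates
#' that the train/val/test splits are pairwise disjoint (a violated split is
#' a hard error).
#'
#' @param path Manifest CSV path.
#' @return A tibble manifest with absolute file paths.
#' @export
load_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("study_id", "split", "t1pre_path", "t2_path", "t1ce_path")
  if (!all(need %in% names(m)))
    abort(paste0("manifest is missing columns: ",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  if (anyDuplicated(m$study_id))
    abort("manifest splits are not disjoint: a study_id appears more than once.")
  if (!all(m$split %in% c("train", "val", "test")))
    abort("manifest split values must be train/val/test.")
  base <- dirname(normalizePath(path))
  for (col in c("t1pre_path", "t2_path", "t1ce_path")) {
    p <- m[[col]]
    m[[col]] <- ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  m
}

#' Load one study triplet listed in a manifest
#'
#' @param manifest A [load_manifest()] tibble.
#' @param study_id The study to load.
#' @return A \code{study_triplet} (fields \code{t1pre}, \code{t2},
#'   \code{t1ce}, \code{study_id}).
#' @export
load_study <- function(manifest, study_id) {
  row <- manifest[manifest$study_id == study_id, ]
  if (nrow(row) != 1L) abort(paste0("study not found in manifest: ", study_id))
  sp <- if ("spacing_mm" %in% names(row)) rep(row$spacing_mm[[1]], 2) else NULL
  structure(list(
    t1pre = read_slice(row$t1pre_path[[1]], "T1pre", sp),
    t2 = read_slice(row$t2_path[[1]], "T2", sp),
    t1ce = read_slice(row$t1ce_path[[1]], "T1ce", sp),
    study_id = study_id
  ), class = "study_triplet")
}
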