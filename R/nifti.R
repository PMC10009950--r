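#' Construct a voxel dataset
#'
#' A stack of modulated gray-matter volume images, one per subject, on a
#' common grid. Values are stored as a 4-D array with the subject axis
#' last (`[x, y, z, subject]`, the NIfTI time-axis convention).
#'
#' @param values 4-D numeric array, subject axis last.
#' @param voxel_size Numeric length-3, mm per axis.
#' @param subject_ids Character vector aligned with the subject axis.
#' @return A `voxel_dataset` object.
#' @export
voxel_dataset <- function(values, voxel_size, subject_ids = NULL) {
  if (length(dim(values)) != 4L) {
    stop("values must be a 4-D array (x, y, z, subject)", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive numbers (mm)", call. = FALSE)
  }
  ns <- dim(values)[4L]
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(ns))
  if (length(subject_ids) != ns) {
    stop("subject_ids length (", length(subject_ids),
         ") disagrees with subject axis (", ns, ")", call. = FALSE)
  }
  structure(list(values = values, voxel_size = voxel_size,
                 subject_ids = as.character(subject_ids)),
            class = "voxel_dataset")
}

#' @export
print.voxel_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat("voxel_dataset:", d[4L], "subjects on a", paste(d[1:3], collapse = "x"),
      "grid,", paste(x$voxel_size, collapse = "x"), "mm voxels\n")
  invisible(x)
}

#' Grid shape of a voxel dataset
#' @param dataset A [voxel_dataset()].
#' @return Integer length-3 grid dimensions.
#' @export
grid_shape <- function(dataset) dim(dataset$values)[1:3]

#' Number of subjects in a voxel dataset
#' @param dataset A [voxel_dataset()].
#' @return Integer subject count.
#' @export
n_subjects <- function(dataset) dim(dataset$values)[4L]

#' Flatten a voxel dataset to a subjects-by-voxels matrix
#'
#' @param dataset A [voxel_dataset()].
#' @param mask Optional logical 3-D array selecting voxels (columns).
#' @return Numeric matrix, rows = subjects, columns = (masked) voxels in
#'   column-major grid order.
#' @export
dataset_matrix <- function(dataset, mask = NULL) {
  d <- dim(dataset$values)
  m <- matrix(dataset$values, nrow = prod(d[1:3]), ncol = d[4L])
  if (!is.null(mask)) {
    check_mask_grid(mask, dataset)
    m <- m[as.logical(mask), , drop = FALSE]
  }
  t(m)
}

#' Assert that a cohort and voxel dataset are aligned
#'
#' Every pipeline stage working on both rejects a dataset whose subject
#' axis disagrees with the cohort.
#'
#' @param dataset A [voxel_dataset()].
#' @param cohort A [cohort_table()].
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
check_alignment <- function(dataset, cohort) {
  if (n_subjects(dataset) != nrow(cohort)) {
    stop("subject axis (", n_subjects(dataset),
         ") disagrees with cohort size (", nrow(cohort), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a stack of gray-matter volume images
#'
#' Accepts either one 4-D NIfTI image or a list of 3-D images sharing grid
#' shape and voxel size; subjects are stacked in input order.
#'
#' @param paths Character vector of NIfTI paths (.nii/.nii.gz).
#' @param subject_ids Optional subject ids aligned with input order.
#' @return A [voxel_dataset()].
#' @export
read_volume_stack <- function(paths, subject_ids = NULL) {
  stopifnot(length(paths) >= 1L)
  imgs <- lapply(paths, RNifti::readNifti)
  pix <- lapply(imgs, function(im) RNifti::pixdim(im)[1:3])
  dims <- lapply(imgs, dim)
  if (length(paths) == 1L && length(dims[[1L]]) == 4L) {
    arr <- array(as.numeric(imgs[[1L]]), dim = dims[[1L]])
    return(voxel_dataset(arr, pix[[1L]], subject_ids))
  }
  ref <- dims[[1L]]
  for (i in seq_along(imgs)) {
    if (length(dims[[i]]) != 3L || !identical(dims[[i]], ref)) {
      stop("grid shape mismatch in '", paths[i], "': ",
           paste(dims[[i]], collapse = "x"), " vs ",
           paste(ref, collapse = "x"), call. = FALSE)
    }
    if (max(abs(pix[[i]] - pix[[1L]])) > 1e-4) {
      stop("voxel size mismatch in '", paths[i], "'", call. = FALSE)
    }
  }
  arr <- array(0, dim = c(ref, length(imgs)))
  for (i in seq_along(imgs)) arr[, , , i] <- as.numeric(imgs[[i]])
  voxel_dataset(arr, pix[[1L]], subject_ids)
}

#' Write a 3-D map (or mask) as NIfTI
#'
#' Outputs default to 32-bit float; masks are written as written (0/1).
#'
#' @param values 3-D numeric or logical array.
#' @param voxel_size Numeric length-3, mm.
#' @param path Output path (.nii or .nii.gz).
#' @param datatype NIfTI datatype string (default "float").
#' @return `path`, invisibly.
#' @export
write_map <- function(values, voxel_size, path, datatype = "float") {
  arr <- array(as.numeric(values), dim = dim(values))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- as.numeric(voxel_size)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a voxel dataset as a 4-D NIfTI image
#'
#' @param dataset A [voxel_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume_stack <- function(dataset, path) {
  img <- RNifti::asNifti(dataset$values)
  RNifti::pixdim(img) <- c(dataset$voxel_size, 1)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Construct an ROI mask
#'
#' @param name ROI name.
#' @param mask Logical (or 0/1) 3-D array; must contain at least one voxel.
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(name, mask) {
  m <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(m)) != 3L) stop("mask must be 3-D", call. = FALSE)
  if (!any(m)) stop("mask '", name, "' is empty", call. = FALSE)
  structure(list(name = name, mask = m), class = "roi_mask")
}

#' Read an ROI (or GM) mask from NIfTI
#'
#' Voxels with intensity strictly greater than 0.5 are inside the mask
#' (binarization convention for probabilistic masks).
#'
#' @param path NIfTI path.
#' @param dataset Optional [voxel_dataset()] to check grid congruence
#'   against (shape identical, voxel size within 1e-4 mm).
#' @param name Mask name; defaults to the file name.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, dataset = NULL, name = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("mask image must be 3-D", call. = FALSE)
  if (is.null(name)) name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (!is.null(dataset)) {
    if (!identical(dim(img), as.integer(grid_shape(dataset)))) {
      stop("mask grid ", paste(dim(img), collapse = "x"),
           " incongruent with dataset grid ",
           paste(grid_shape(dataset), collapse = "x"), call. = FALSE)
    }
    if (max(abs(RNifti::pixdim(img)[1:3] - dataset$voxel_size)) > 1e-4) {
      stop("mask voxel size incongruent with dataset", call. = FALSE)
    }
  }
  roi_mask(name, array(as.numeric(img) > 0.5, dim = dim(img)))
}

# internal: mask congruent with dataset grid
check_mask_grid <- function(mask, dataset) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(as.integer(dim(m)), as.integer(grid_shape(dataset)))) {
    stop("mask grid incongruent with dataset grid", call. = FALSE)
  }
  invisible(TRUE)
}
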