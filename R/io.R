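#' Write a volume (signal or concentration) as NIfTI-1 with a JSON sidecar
#'
#' The array and affine go into a \code{.nii.gz}; reference regions, truth
#' and calibration metadata (when present) go into a JSON sidecar next to it.
#'
#' @param volume An \code{"na_raw"} or \code{"na_image"} object.
#' @param path Output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
write_sodium_nifti <- function(volume, path) {
  arr <- if (!is.null(volume$signal)) volume$signal else volume$data
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- abs(diag(volume$affine)[1:3])
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  side <- list(
    background_region = volume$background_region,
    eye_regions = volume$eye_regions,
    calibration = if (!is.null(volume$calibration))
      unclass(volume$calibration),
    truth = if (!is.null(volume$truth)) unclass(volume$truth))
  jsonlite::write_json(side[!vapply(side, is.null, TRUE)],
                       sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a sodium volume written by \code{\link{write_sodium_nifti}}
#'
#' @param path NIfTI path; the JSON sidecar is read from the matching name.
#' @return A list in the \code{"na_raw"} layout (signal, affine, regions).
#' @export
read_sodium_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side_path <- sidecar_path(path)
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
  else list()
  as_region <- function(m) if (is.null(m)) NULL else
    matrix(as.integer(as.matrix(m)), ncol = 3)
  structure(list(signal = array(as.numeric(img), dim(img)),
                 affine = unclass(RNifti::xform(img)),
                 background_region = as_region(side$background_region),
                 eye_regions = lapply(side$eye_regions, as_region),
                 truth = side$truth),
            class = "na_raw")
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write tissue-fraction maps as three NIfTI files
#'
#' @param fractions An \code{"na_fractions"} triple.
#' @param prefix Path prefix; files become \code{<prefix>_gm.nii.gz} etc.
#' @return Character vector of the three paths, invisibly.
#' @export
write_fraction_niftis <- function(fractions, prefix) {
  paths <- paste0(prefix, "_", c("gm", "wm", "csf"), ".nii.gz")
  fields <- c("f_gm", "f_wm", "f_csf")
  for (i in 1:3) {
    img <- RNifti::asNifti(fractions[[fields[i]]])
    RNifti::pixdim(img) <- abs(diag(fractions$affine)[1:3])
    RNifti::qform(img) <- structure(fractions$affine, code = 2L)
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Read tissue-fraction maps from three NIfTI files
#'
#' @param gm,wm,csf Paths to the three fraction volumes (shared grid).
#' @return An \code{"na_fractions"} triple.
#' @export
read_fraction_niftis <- function(gm, wm, csf) {
  imgs <- lapply(c(gm, wm, csf), RNifti::readNifti)
  arr <- lapply(imgs, function(im) array(as.numeric(im), dim(im)))
  new_fractions(arr[[1]], arr[[2]], arr[[3]], unclass(RNifti::xform(imgs[[1]])))
}

#' Read / write a cohort table as CSV
#'
#' Plain CSV in the long subject-visit schema of
#' \code{\link{generate_cohort}}; validated on read.
#'
#' @param path CSV path.
#' @return \code{read_cohort_csv}: the validated cohort \code{data.frame}.
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  class(cohort) <- c("na_cohort", "data.frame")
  cohort
}

#' @rdname read_cohort_csv
#' @param cohort Cohort table to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a bare 3-D volume as NIfTI
#'
#' Minimal helpers for single scalar fields (e.g. an eye fraction map) that
#' do not need a sidecar.
#'
#' @param arr 3-D array.
#' @param affine 4x4 grid-to-world matrix.
#' @param path NIfTI path.
#' @return \code{write_volume_nifti}: \code{path}, invisibly;
#'   \code{read_volume_nifti}: list with \code{data} and \code{affine}.
#' @export
write_volume_nifti <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- abs(diag(affine)[1:3])
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       affine = unclass(RNifti::xform(img)))
}
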