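#' Materialize the MNI152 1 mm brain mask
#'
#' Writes the standard-space whole-brain mask on the 1 mm MNI152 grid
#' (197 x 233 x 189) to a NIfTI file by calling the host Python's nilearn,
#' which bundles the ICBM152 2009 template, and reads it back as a logical
#' array. Used to tile the reference template; requires a `python` with
#' nilearn on the PATH (no network access is needed, the template ships
#' with nilearn).
#'
#' @param path Optional output path for the NIfTI mask (a tempfile by
#'   default).
#' @param python Python executable to use.
#' @return Logical 3D array of the brain mask.
#' @export
mni_brain_mask <- function(path = tempfile(fileext = ".nii.gz"),
                           python = "python") {
  script <- paste(
    "from nilearn.datasets import load_mni152_brain_mask",
    sprintf("load_mni152_brain_mask(resolution=1).to_filename(%s)",
            deparse(path)),
    sep = "; ")
  status <- suppressWarnings(
    system2(python, c("-c", shQuote(script)), stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(path))
    stop("could not materialize the MNI152 brain mask ",
         "(python with nilearn required)")
  m <- RNifti::readNifti(path)
  array(m != 0, dim = dim(m))
}
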