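#' Write / read a label volume as NIfTI-1 with a JSON sidecar
#'
#' The voxel grid is stored as integer NIfTI with the voxel size (in
#' micrometres) in the header pixdim; the label map and region hierarchy
#' go to a JSON sidecar next to the image (`<path>.json` with the `.nii`
#' suffix stripped).
#'
#' @param vol a `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid + 0L)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::pixunits(img) <- c("um", "s")
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(voxel_size_um = vol$voxel_size,
                            label_map = as.list(vol$label_map),
                            hierarchy = vol$hierarchy),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_nifti
#' @export
read_label_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  structure(list(grid = array(as.integer(img), dim = dim(img)),
                 voxel_size = as.numeric(meta$voxel_size_um),
                 label_map = unlist(meta$label_map),
                 hierarchy = as.data.frame(meta$hierarchy),
                 shapes = NULL),
            class = "label_volume")
}

#' Write / read a cell table as TSV
#' @param cells a `cell_population`.
#' @param path file path.
#' @export
write_cell_tsv <- function(cells, path) {
  utils::write.table(as.data.frame(cells), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_tsv
#' @export
read_cell_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(d, class = c("cell_population", "data.frame"))
}

#' Read / write gene sets in GMT format
#'
#' Reading goes through `fgsea::gmtPathways()`; writing emits the
#' standard three-plus-column tab layout (name, description, genes).
#'
#' @param sets named list of gene-id vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

# small TSV writer used by the reporting layer
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
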