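# File interfaces: NIfTI-1 volumes (RAS+, isotropic spacing in mm) via
# RNifti, JSON study manifests, and mesh export in Abaqus INP and
# VTK-legacy dialects (C3D10 / VTK quadratic-tetra node ordering: corners
# 1-4 then midsides (1,2) (2,3) (3,1) (1,4) (2,4) (3,4)).

#' Write a volume as NIfTI-1
#' @param x a `qct_image` or a 3D array/mask.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel size, mm (taken from `x` when it is a `qct_image`).
#' @export
write_nifti_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "qct_image")) {
    data <- x$data; spacing <- x$spacing
  } else {
    data <- x
    stop_if_not(!is.null(spacing), "spacing required for raw arrays")
  }
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  img <- RNifti::asNifti(data, reference = NULL)
  RNifti::pixdim(img) <- rep(spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a `qct_image`
#' @param path NIfTI file.
#' @param units unit tag to attach (`"HU"` or `"g/cm3"`).
#' @export
read_nifti_volume <- function(path, units = "HU") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  stop_if_not(max(abs(diff(sp))) < 1e-6, "anisotropic spacing not supported")
  new_qct_image(array(as.numeric(img), dim(img)), sp[1], units)
}

#' Write a study to disk (NIfTI volumes + JSON manifest)
#' @param study a `vfe_study`.
#' @param out_dir output directory.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = study$seed, vertebrae = list())
  for (v in study$vertebrae) {
    qct_file <- file.path(out_dir, sprintf("%s_qct.nii.gz", v$id))
    write_nifti_volume(v$qct, qct_file)
    masks <- list()
    for (nm in names(v$masks)) {
      mf <- file.path(out_dir, sprintf("%s_%s.nii.gz", v$id, nm))
      write_nifti_volume(v$masks[[nm]], mf, spacing = v$phantom$spacing)
      op <- as.integer(substr(nm, 3, 3))
      rep <- as.integer(substr(nm, 8, 8))
      masks[[nm]] <- list(file = basename(mf), operator = op, repeat_id = rep,
                          seed = v$seeds[[nm]])
    }
    manifest$vertebrae[[v$id]] <- list(
      id = v$id, condition = v$condition, qct = basename(qct_file),
      qct_seed = v$seeds$qct, masks = masks)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Export a mesh with materials as Abaqus INP
#' @param model an `fe_model`.
#' @param path output `.inp` path.
#' @export
write_inp <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  n <- model$mesh$nodes
  writeLines(sprintf("%d, %.6f, %.6f, %.6f", seq_len(nrow(n)),
                     n[, 1], n[, 2], n[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D10", con)
  cc <- model$mesh$conn
  writeLines(paste0(seq_len(nrow(cc)), ", ",
                    apply(cc, 1, paste, collapse = ", ")), con)
  writeLines("** per-element rho_QCT (g/cm3), E (MPa), sigma_y1 (MPa), E_py (MPa)", con)
  writeLines(sprintf("** %d, %.5f, %.3f, %.4f, %.4f", seq_len(nrow(cc)),
                     model$rho_qct, model$material$E, model$material$sigma_y1,
                     model$material$E_py), con)
  invisible(path)
}

#' Export a result as VTK legacy unstructured grid with point data
#' @param model an `fe_model`.
#' @param path output `.vtk` path.
#' @param result optional `fe_result` (adds displacements and principal
#'   strains as point data).
#' @export
write_vtk <- function(model, path, result = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- model$mesh$nodes; cc <- model$mesh$conn
  writeLines(c("# vtk DataFile Version 3.0", "vertebraFE model", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(n))), con)
  writeLines(sprintf("%.6f %.6f %.6f", n[, 1], n[, 2], n[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(cc), nrow(cc) * 11), con)
  writeLines(paste(10, apply(cc - 1L, 1, paste, collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(cc)), con)
  writeLines(rep("24", nrow(cc)), con)  # VTK_QUADRATIC_TETRA
  writeLines(sprintf("CELL_DATA %d", nrow(cc)), con)
  writeLines(c("SCALARS E double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.4f", model$material$E), con)
  if (!is.null(result)) {
    writeLines(sprintf("POINT_DATA %d", nrow(n)), con)
    writeLines("VECTORS displacement double", con)
    writeLines(sprintf("%.8e %.8e %.8e", result$u[, 1], result$u[, 2],
                       result$u[, 3]), con)
    writeLines(c("SCALARS eps_p1 double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.8e", result$eps_p1), con)
    writeLines(c("SCALARS eps_p3 double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.8e", result$eps_p3), con)
  }
  invisible(path)
}
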