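# On-disk formats: NIfTI image stacks, YAML/JSON phantom configuration,
# CSV/JSON tabular exchange.

#' Read a NIfTI image stack
#'
#' @param path Path to a `.nii` / `.nii.gz` file with at least 3 dimensions
#'   (row, col, slice\[, frame\]).
#' @return List with `data` (array), `pixel_spacing` (mm), and
#'   `slice_thickness` (mm).
#' @export
read_image_stack <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) < 3) stop("stack requires >= 3 dims")
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    stop("missing or invalid pixel spacing (pixdim) in NIfTI header")
  }
  # pixdim is stored as float32 in the header; round away its quantisation
  pd <- round(pd, 6)
  list(data = array(as.numeric(img), dim(img)),
       pixel_spacing = pd[1:2],
       slice_thickness = pd[3])
}

#' Write a NIfTI image stack
#'
#' @param data Numeric or logical array with >= 3 dimensions.
#' @param path Output `.nii.gz` path.
#' @param pixel_spacing In-plane pixel size, mm (scalar or length 2).
#' @param slice_thickness Slice thickness, mm.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(data, path, pixel_spacing, slice_thickness) {
  if (length(dim(data)) < 3) stop("stack requires >= 3 dims")
  sp <- rep_len(pixel_spacing, 2)
  img <- RNifti::asNifti(array(as.numeric(data), dim(data)))
  pd <- c(sp, slice_thickness, rep(1, length(dim(data)) - 3))
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a phantom configuration from YAML or JSON
#'
#' The file holds named [phantom_config()] arguments; unknown names are an
#' error. Format chosen by extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path Configuration file path.
#' @return A validated `phantom_config`.
#' @export
read_phantom_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                "yaml" = , "yml" = yaml::read_yaml(path),
                "json" = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format: .", ext))
  known <- names(formals(phantom_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  td <- raw$tag_directions
  if (!is.null(td)) {
    if (is.matrix(td)) {
      td <- lapply(seq_len(nrow(td)), function(i) as.numeric(td[i, ]))
    } else if (is.list(td)) {
      td <- lapply(td, function(v) as.numeric(unlist(v)))
    } else {
      td <- list(as.numeric(td[1:2]), as.numeric(td[3:4]))
    }
    raw$tag_directions <- td
  }
  do.call(phantom_config, raw)
}

#' Write a phantom configuration to YAML or JSON
#'
#' @param cfg A `phantom_config`.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_phantom_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$tag_directions <- do.call(rbind, x$tag_directions)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "yaml" = , "yml" = yaml::write_yaml(x, path),
         "json" = jsonlite::write_json(x, path, auto_unbox = TRUE,
                                       digits = NA),
         stop("unsupported config format: .", ext))
  invisible(path)
}

#' Write a dyssynchrony report (or any list) as JSON
#'
#' @param x A list-like object (e.g. `dyssynchrony_report`,
#'   `tissue_extents`).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read back a JSON report as a list
#'
#' @param path `.json` path written by [write_report_json()].
#' @return A list.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a cohort table as CSV
#'
#' @param table A `cohort_table` (or data frame).
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path `.csv` path with a header row.
#' @return A `cohort_table` data frame.
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
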