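#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`) via RNifti and uncompressed
#' MetaImage (`.mhd` + raw file). Voxel spacing is taken from the header and
#' never assumed; a header without spacing is an error. The through-plane
#' axis is taken to be the third array axis (transverse stacks).
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.mhd` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    spacing <- abs(RNifti::pixdim(img)[1:3])
    if (length(spacing) < 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("NIfTI header of ", path, " lacks a positive voxel spacing")
    arr <- array(as.numeric(img), dim(img)[1:3])
    image_volume(arr, spacing = spacing)
  } else if (grepl("\\.mhd$", lower)) {
    read_metaimage(path)
  } else {
    stop("unsupported format for ", path,
         "; supported: NIfTI (.nii, .nii.gz) and MetaImage (.mhd)")
  }
}

#' Read a binary segmentation mask aligned to a reference volume
#'
#' Reads with [read_volume()] semantics, checks the grid against the
#' reference, and binarizes: any value > 0.5 becomes 1 (so label maps with
#' labels other than 1 collapse to foreground).
#'
#' @param path Path to the mask file.
#' @param reference The [image_volume()] the mask must align to.
#' @return A [seg_mask()] on the reference grid.
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "image_volume"))
  raw <- read_volume(path)
  if (!identical(dim(raw$intensities), dim(reference$intensities)))
    stop(sprintf("mask grid %s does not match reference grid %s",
                 paste(dim(raw$intensities), collapse = "x"),
                 paste(dim(reference$intensities), collapse = "x")))
  seg_mask(raw$intensities > 0.5, spacing = reference$spacing)
}

#' Write a volume or mask to NIfTI or MetaImage
#'
#' Format chosen from the extension (`.nii`, `.nii.gz`, `.mhd`). Masks are
#' written as unsigned 8-bit, images as 32-bit float. When the object carries
#' provenance, a JSON sidecar `<path>.json` records it.
#'
#' @param x An [image_volume()] or [seg_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "seg_mask")) {
    arr <- x$voxels
    spacing <- x$spacing
    datatype <- "uint8"
    prov <- character()
  } else if (inherits(x, "image_volume")) {
    arr <- x$intensities
    spacing <- x$spacing
    datatype <- "float"
    prov <- x$provenance
  } else stop("`x` must be an image_volume or seg_mask")
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    nii <- RNifti::asNifti(structure(array(as.numeric(arr), dim(arr)),
                                     pixdim = spacing),
                           datatype = datatype)
    RNifti::writeNifti(nii, path)
  } else if (grepl("\\.mhd$", lower)) {
    write_metaimage(arr, spacing, path, datatype)
  } else {
    stop("unsupported output format for ", path,
         "; supported: NIfTI (.nii, .nii.gz) and MetaImage (.mhd)")
  }
  if (length(prov))
    jsonlite::write_json(list(provenance = prov), paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Minimal uncompressed MetaImage reader: text header + raw little-endian data.
read_metaimage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  need <- function(key) {
    if (is.null(kv[[key]])) stop("MetaImage header ", path, " missing ", key)
    kv[[key]]
  }
  ndims <- as.integer(need("NDims"))
  if (ndims != 3L) stop("only 3D MetaImage supported, got NDims=", ndims)
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  spacing_key <- if (!is.null(kv[["ElementSpacing"]])) "ElementSpacing"
                 else if (!is.null(kv[["ElementSize"]])) "ElementSize"
                 else stop("MetaImage header ", path,
                           " has no ElementSpacing; refusing to assume 1 mm")
  spacing <- as.numeric(strsplit(kv[[spacing_key]], "\\s+")[[1]])
  etype <- need("ElementType")
  type_map <- list(MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
                   MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
                   MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
                   MET_INT = list(what = "integer", size = 4, signed = TRUE),
                   MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
                   MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE))
  tm <- type_map[[etype]]
  if (is.null(tm)) stop("unsupported MetaImage ElementType ", etype)
  datafile <- need("ElementDataFile")
  if (identical(datafile, "LOCAL"))
    stop("LOCAL MetaImage data not supported; use a separate .raw file")
  datapath <- file.path(dirname(path), datafile)
  if (!file.exists(datapath)) stop("MetaImage data file not found: ", datapath)
  n <- prod(dims)
  con <- file(datapath, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = tm$what, n = n, size = tm$size,
                  signed = tm$signed, endian = "little")
  if (length(vals) != n)
    stop("MetaImage data file ", datapath, " shorter than DimSize implies")
  image_volume(array(as.numeric(vals), dims), spacing = spacing)
}

write_metaimage <- function(arr, spacing, path, datatype) {
  rawname <- sub("\\.mhd$", ".raw", basename(path))
  etype <- if (datatype == "uint8") "MET_UCHAR" else "MET_FLOAT"
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    paste("DimSize =", paste(dim(arr), collapse = " ")),
    paste("ElementSpacing =", paste(format(spacing, digits = 12), collapse = " ")),
    "ElementByteOrderMSB = False",
    paste("ElementType =", etype),
    paste("ElementDataFile =", rawname)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  if (etype == "MET_UCHAR")
    writeBin(as.integer(arr), con, size = 1, endian = "little")
  else
    writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

#' Preprocessing settings for T2-weighted volumes
#'
#' @param normalize One of `"none"`, `"zscore"` (zero mean / unit SD over the
#'   normalization region) or `"rescale"` (linear map sending the 1st
#'   percentile to 0 and the 99th to 1).
#' @param bias_correct Logical; when `TRUE`, `bias_fun` is applied first.
#' @param bias_fun Optional bias-field correction hook: a function
#'   `f(array, spacing)` returning a corrected array of the same shape.
#'   External N4-style implementations plug in here.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(normalize = c("none", "zscore", "rescale"),
                              bias_correct = FALSE, bias_fun = NULL) {
  normalize <- match.arg(normalize)
  if (bias_correct && !is.function(bias_fun))
    stop("bias_correct = TRUE requires `bias_fun`, a function(array, spacing)")
  structure(list(normalize = normalize, bias_correct = bias_correct,
                 bias_fun = bias_fun), class = "preprocess_config")
}

#' Preprocess a volume (bias-correction hook + intensity normalization)
#'
#' Applies, in order and each individually switchable: (1) the optional
#' bias-field correction hook, (2) the chosen intensity normalization.
#' The steps that ran are appended to the volume's provenance. Grid shape
#' and spacing are never altered.
#'
#' @param volume An [image_volume()].
#' @param config A [preprocess_config()].
#' @param mask Optional [seg_mask()]; when given, z-score statistics are
#'   computed over the mask dilated by 3 voxels rather than the whole grid.
#' @return The preprocessed [image_volume()].
#' @export
preprocess <- function(volume, config = preprocess_config(), mask = NULL) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(config, "preprocess_config"))
  arr <- volume$intensities
  prov <- volume$provenance
  if (isTRUE(config$bias_correct)) {
    arr <- config$bias_fun(arr, volume$spacing)
    if (!identical(dim(arr), dim(volume$intensities)))
      stop("bias_fun changed the grid shape")
    prov <- c(prov, "bias_correct")
  }
  if (config$normalize == "zscore") {
    region <- if (is.null(mask)) rep(TRUE, length(arr)) else {
      dil <- morpho_op(mask$voxels, ball_offsets(3), "dilate")
      as.logical(dil)
    }
    mu <- mean(arr[region])
    sdv <- stats::sd(arr[region])
    if (sdv == 0) stop("z-score normalization undefined: zero intensity SD")
    arr <- (arr - mu) / sdv
    prov <- c(prov, "normalize:zscore")
  } else if (config$normalize == "rescale") {
    q <- stats::quantile(arr, c(0.01, 0.99), names = FALSE, type = 7)
    if (q[2] == q[1]) stop("percentile rescale undefined: flat intensities")
    arr <- (arr - q[1]) / (q[2] - q[1])
    prov <- c(prov, "normalize:rescale")
  } else {
    prov <- c(prov, "normalize:none")
  }
  image_volume(arr, spacing = volume$spacing, provenance = prov)
}
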