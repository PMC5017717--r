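#' Read a 3D image (MetaImage or NIfTI)
#'
#' Supported extensions: \code{.mhd}/\code{.mha} (MetaImage; header +
#' raw block) and \code{.nii}/\code{.nii.gz} (NIfTI-1, via RNifti).
#' Voxels, spacing, origin and orientation are mapped faithfully; the
#' affine stored in the file is taken as mapping 0-based voxel indices
#' to world mm.
#'
#' @param path file path.
#' @return an \code{\link{image3d}}.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(sub("^.*?(\\.[a-z]+(\\.gz)?)$", "\\1", basename(path)))
  switch(ext,
         ".mhd" = , ".mha" = read_metaimage(path),
         ".nii" = , ".nii.gz" = read_nifti_image(path),
         stop("unsupported image extension: ", ext))
}

#' Write a 3D image (MetaImage or NIfTI)
#'
#' @param image an \code{\link{image3d}}.
#' @param path output path; format chosen by extension (\code{.mhd}
#'   writes a header plus a sibling \code{.raw}; \code{.mha} inlines the
#'   data; \code{.nii}/\code{.nii.gz} via RNifti).
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image3d"))
  ext <- tolower(sub("^.*?(\\.[a-z]+(\\.gz)?)$", "\\1", basename(path)))
  switch(ext,
         ".mhd" = write_metaimage(image, path, local = FALSE),
         ".mha" = write_metaimage(image, path, local = TRUE),
         ".nii" = , ".nii.gz" = write_nifti_image(image, path),
         stop("unsupported image extension: ", ext))
  invisible(path)
}

read_nifti_image <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("expected a 3D NIfTI volume: ", path)
  M <- RNifti::xform(img)
  A <- M[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  direction <- sweep(A, 2, spacing, "/")
  image3d(array(as.numeric(img), dim(img)), spacing = spacing,
          origin = M[1:3, 4], direction = direction)
}

write_nifti_image <- function(image, path) {
  M <- rbind(cbind(sweep(image$direction, 2, image$spacing, "*"),
                   image$origin), c(0, 0, 0, 1))
  img <- RNifti::asNifti(image$voxels)
  img <- RNifti::`sform<-`(img, structure(M, code = 2L))
  RNifti::writeNifti(img, path)
}

metaimage_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                     MET_SHORT = "integer", MET_USHORT = "integer",
                     MET_INT = "integer", MET_FLOAT = "double",
                     MET_DOUBLE = "double")
metaimage_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2,
                     MET_USHORT = 2, MET_INT = 4, MET_FLOAT = 4,
                     MET_DOUBLE = 8)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3D MetaImage volumes are supported")
  type <- hdr$ElementType
  if (is.na(metaimage_sizes[type])) stop("unsupported ElementType: ", type)
  n <- prod(dims)
  size <- metaimage_sizes[[type]]
  signed <- !(type %in% c("MET_UCHAR", "MET_USHORT"))
  endian <- if (identical(hdr$BinaryDataByteOrderMSB, "True")) "big" else "little"
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
    vals <- readBin(raw_con, metaimage_types[[type]], n = n, size = size,
                    signed = signed, endian = endian)
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stop("missing raw data file: ", raw_path)
    if (file.info(raw_path)$size < n * size)
      stop("raw data file is truncated: ", raw_path)
    vals <- readBin(raw_path, metaimage_types[[type]], n = n, size = size,
                    signed = signed, endian = endian)
  }
  if (length(vals) < n) stop("raw data is truncated: ", path)
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% hdr$ElementSize,
                                 "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  direction <- if (!is.null(hdr$TransformMatrix))
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3, 3)
  else diag(3)
  image3d(array(as.numeric(vals), dims), spacing = spacing, origin = origin,
          direction = direction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_metaimage <- function(image, path, local = FALSE) {
  d <- dim(image$voxels)
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("TransformMatrix =", paste(format(as.numeric(image$direction), trim = TRUE), collapse = " ")),
           paste("Offset =", paste(format(image$origin, trim = TRUE), collapse = " ")),
           "CenterOfRotation = 0 0 0",
           paste("ElementSpacing =", paste(format(image$spacing, trim = TRUE), collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (local) {
    writeBin(as.numeric(image$voxels), con, size = 8, endian = "little")
    close(con)
  } else {
    close(con)
    writeBin(as.numeric(image$voxels),
             file.path(dirname(path), datafile), size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a landmark / seed-point file
#'
#' Plain-text point list: first line the dialect keyword (\code{point}
#' for world mm, \code{index} for 0-based voxel indices), second line
#' the point count, then one whitespace-delimited point per line.
#'
#' @param path file path.
#' @param meta image geometry, required for the \code{index} dialect
#'   (points are converted to world mm).
#' @return n x 3 matrix of world coordinates mm.
#' @export
read_landmarks <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  dialect <- tolower(lines[1])
  if (!dialect %in% c("point", "index"))
    stop("unknown landmark dialect '", lines[1], "' in ", path)
  n <- suppressWarnings(as.integer(lines[2]))
  if (is.na(n)) stop("missing point count in ", path)
  body <- lines[-(1:2)]
  if (length(body) != n)
    stop("landmark count mismatch in ", path, ": header says ", n,
         " but file has ", length(body), " point lines (line ",
         length(body) + 3, ")")
  pts <- t(vapply(body, function(l) as.numeric(strsplit(l, "\\s+")[[1]][1:3]),
                  numeric(3)))
  rownames(pts) <- NULL
  if (any(!is.finite(pts))) stop("non-finite coordinates in ", path)
  if (dialect == "index") {
    if (is.null(meta))
      stop("'index' dialect requires an image geometry for conversion")
    pts <- world_from_index(meta, pts, check = FALSE)
  }
  pts
}

#' Write a landmark file in the world-mm dialect
#'
#' @param points n x 3 matrix of world mm.
#' @param path output path.
#' @export
write_landmarks <- function(points, path) {
  pts <- as_point_matrix(points)
  lines <- c("point", nrow(pts),
             apply(pts, 1, function(p) paste(format(p, trim = TRUE, digits = 17),
                                             collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

transform_to_list <- function(t) {
  if (inherits(t, "rigid_transform"))
    list(type = "rigid", rotation = as.numeric(t$rotation),
         translation = t$translation, center = t$center)
  else if (inherits(t, "bspline_ffd"))
    list(type = "bspline_ffd", control_spacing = t$control_spacing,
         grid_origin = t$grid_origin, grid_shape = t$grid_shape,
         coefficients = as.numeric(t$coefficients))
  else if (inherits(t, "composite_transform"))
    list(type = "composite",
         components = lapply(t$transforms, transform_to_list))
  else stop("unknown transform class")
}

transform_from_list <- function(l) {
  switch(l$type,
         rigid = rigid_transform(matrix(l$rotation, 3, 3), l$translation,
                                 l$center),
         bspline_ffd = bspline_ffd(l$control_spacing, l$grid_origin,
                                   l$grid_shape,
                                   array(l$coefficients,
                                         c(l$grid_shape, 3))),
         composite = composite_transform(lapply(l$components,
                                                transform_from_list)),
         stop("unknown transform type tag: ", l$type))
}

#' Write / read a spatial transform as JSON
#'
#' Documented schema: a JSON object with \code{format} (currently 1), a
#' \code{type} tag (\code{rigid}, \code{bspline_ffd}, \code{composite}),
#' the geometry and parameter arrays, and for composites the ordered
#' component list (last applied first).  The transform maps fixed-image
#' world coordinates into the moving image.  Round-trips at full double
#' precision.
#'
#' @param transform a spatial transform.
#' @param path file path.
#' @export
write_transform <- function(transform, path) {
  obj <- c(list(format = 1), transform_to_list(transform))
  # I(17) = 17 significant digits: lossless for IEEE doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(obj$format) || obj$format != 1)
    stop("unknown transform file version in ", path)
  transform_from_list(obj)
}

#' Write / read registration control parameters as YAML
#'
#' @param control a \code{\link{reg_control}}.
#' @param path file path.
#' @export
write_config <- function(control, path) {
  yaml::write_yaml(unclass(control), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- yaml::read_yaml(path)
  defaults <- reg_control()
  known <- intersect(names(vals), names(defaults))
  do.call(reg_control, vals[known])
}

#' Write an evaluation report (JSON + delimited text)
#'
#' @param report an \code{\link{evaluation_report}}.
#' @param path output path; \code{.json} or anything else for
#'   tab-delimited text.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(dsc = report$dsc, msd = report$msd,
                              mcd = report$mcd,
                              n_landmarks = report$n_landmarks,
                              success = report$success),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    df <- data.frame(metric = c("DSC", "MSD_mm",
                                if (!is.null(report$mcd)) "MCD_mm"),
                     value = c(report$dsc, report$msd, report$mcd))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
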