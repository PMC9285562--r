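## Volume I/O: NIfTI (via RNifti), MetaImage (.mha/.mhd + .raw) and a raw
## binary + JSON sidecar format.  Geometry is restricted to axis-aligned
## volumes: spacing from the header, origin from the translation part of the
## transform.  DICOM series are rejected with an informative error (no
## reader dependency available).

metTypes <- list(
  MET_DOUBLE = list(what = "double", size = 8L),
  MET_FLOAT  = list(what = "double", size = 4L),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE))

#' Read a volumetric image
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mha` single
#' file or `.mhd` header + raw blob) and a raw little-endian array with a
#' JSON sidecar (`foo.raw` + `foo.json` holding `dim`, `spacing`, `origin`,
#' `datatype`).  Only axis-aligned geometries are supported; spacing and
#' origin are populated from the file metadata.
#'
#' @param path file path (for raw+JSON, either the `.raw` or `.json` path).
#' @param format one of `"auto"`, `"nifti"`, `"metaimage"`, `"rawjson"`.
#' @return A [VolumetricImage-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, format = c("auto", "nifti", "metaimage", "rawjson")) {
  format <- match.arg(format)
  if (dir.exists(path))
    stop("'", path, "' is a directory; DICOM series input is not supported ",
         "by this build. Convert the series to NIfTI or MetaImage first.",
         call. = FALSE)
  if (!file.exists(path) && format %in% c("auto", "rawjson") &&
      !file.exists(rawJsonSidecar(path)))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else if (grepl("\\.(mha|mhd)$", path)) "metaimage"
      else if (grepl("\\.(raw|json)$", path)) "rawjson"
      else if (grepl("\\.dcm$", path, ignore.case = TRUE))
        stop("DICOM input is not supported by this build; convert to NIfTI ",
             "or MetaImage first.", call. = FALSE)
      else stop("cannot infer format from extension of '", path, "'",
                call. = FALSE)
  }
  switch(format,
    nifti = readVolumeNifti(path),
    metaimage = readVolumeMeta(path),
    rawjson = readVolumeRawJson(path))
}

readVolumeNifti <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) d <- d[1:3]
  assertThat(length(d) == 3L, "NIfTI volume must be 3-D")
  sp <- RNifti::pixdim(im)[1:3]
  xf <- RNifti::xform(im)
  org <- as.numeric(xf[1:3, 4])
  VolumetricImage(array(as.numeric(im), d), spacing = abs(sp), origin = org)
}

readVolumeMeta <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list(); nbytes <- 0L
  repeat {
    line <- readBin(con, "raw", 4096L)
    nl <- which(line == as.raw(10L))[1]
    if (is.na(nl)) stop("malformed MetaImage header in ", path, call. = FALSE)
    seek(con, nbytes + nl, origin = "start")
    nbytes <- nbytes + nl
    txt <- rawToChar(line[seq_len(nl - 1L)])
    kv <- strsplit(txt, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", txt,
                               call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  assertThat(identical(hdr$NDims, "3"), "only 3-D MetaImage volumes supported")
  if (identical(toupper(hdr$CompressedData %||% "FALSE"), "TRUE"))
    stop("compressed MetaImage data not supported", call. = FALSE)
  if (identical(toupper(hdr$BinaryDataByteOrderMSB %||% "FALSE"), "TRUE"))
    stop("big-endian MetaImage data not supported", call. = FALSE)
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  org <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  ty <- metTypes[[hdr$ElementType %||% "MET_DOUBLE"]]
  if (is.null(ty)) stop("unsupported ElementType ", hdr$ElementType, call. = FALSE)
  n <- prod(d)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, ty$what, n, size = ty$size, endian = "little",
                    signed = isTRUE(ty$signed) || ty$size > 2L)
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    assertThat(file.exists(rawPath), paste("missing data file", rawPath))
    vals <- readBin(rawPath, ty$what, n, size = ty$size, endian = "little",
                    signed = isTRUE(ty$signed) || ty$size > 2L)
  }
  assertThat(length(vals) == n, "MetaImage data shorter than DimSize implies")
  VolumetricImage(array(as.numeric(vals), d), spacing = sp, origin = org)
}

rawJsonSidecar <- function(path) sub("\\.(raw|json)$", ".json", path)

readVolumeRawJson <- function(path) {
  jsonPath <- rawJsonSidecar(path)
  rawPath <- sub("\\.(raw|json)$", ".raw", path)
  assertThat(file.exists(jsonPath), paste("missing JSON sidecar", jsonPath))
  assertThat(file.exists(rawPath), paste("missing raw data file", rawPath))
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  assertThat(!is.null(meta$dim) && !is.null(meta$spacing),
             "sidecar must contain 'dim' and 'spacing'")
  d <- as.integer(meta$dim)
  size <- if (identical(meta$datatype, "float32")) 4L else 8L
  vals <- readBin(rawPath, "double", prod(d), size = size, endian = "little")
  assertThat(length(vals) == prod(d), "raw file shorter than dim implies")
  VolumetricImage(array(vals, d), spacing = as.numeric(meta$spacing),
                  origin = as.numeric(meta$origin %||% c(0, 0, 0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volumetric image or derived field
#'
#' Format is inferred from the extension: `.nii`/`.nii.gz` (NIfTI), `.mha`
#' (MetaImage, data embedded), `.mhd` (MetaImage header + sibling `.raw`),
#' `.raw`/`.json` (raw doubles + JSON sidecar).
#'
#' @param img a [VolumetricImage-class] (or a bare 3-D array, written with
#'   the supplied spacing/origin).
#' @param path output path.
#' @param spacing,origin geometry used when `img` is a bare array.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(img, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is(img, "VolumetricImage"))
    img <- VolumetricImage(img, spacing = spacing, origin = origin)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    im <- RNifti::asNifti(img@data)
    RNifti::pixdim(im) <- img@spacing
    m <- diag(c(img@spacing, 1))
    m[1:3, 4] <- img@origin
    attr(m, "code") <- 2L
    im <- RNifti::`qform<-`(im, m)
    RNifti::writeNifti(im, path)
  } else if (grepl("\\.mha$", path)) {
    writeVolumeMeta(img, path, local = TRUE)
  } else if (grepl("\\.mhd$", path)) {
    writeVolumeMeta(img, path, local = FALSE)
  } else if (grepl("\\.(raw|json)$", path)) {
    jsonPath <- rawJsonSidecar(path)
    rawPath <- sub("\\.(raw|json)$", ".raw", path)
    jsonlite::write_json(list(dim = dim(img@data), spacing = img@spacing,
                              origin = img@origin, datatype = "float64"),
                         jsonPath, auto_unbox = FALSE, digits = NA)
    writeBin(as.numeric(img@data), rawPath, size = 8L, endian = "little")
  } else stop("cannot infer output format from extension of '", path, "'",
              call. = FALSE)
  invisible(path)
}

writeVolumeMeta <- function(img, path, local) {
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(img@data), collapse = " ")),
    paste("ElementSpacing =", paste(format(img@spacing, digits = 17),
                                    collapse = " ")),
    paste("Offset =", paste(format(img@origin, digits = 17), collapse = " ")),
    "ElementType = MET_DOUBLE")
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con, sep = "\n")
    writeBin(as.numeric(img@data), con, size = 8L, endian = "little")
  } else {
    rawName <- sub("\\.mhd$", ".raw", basename(path))
    writeLines(c(hdr, paste("ElementDataFile =", rawName)), path)
    writeBin(as.numeric(img@data), file.path(dirname(path), rawName),
             size = 8L, endian = "little")
  }
}
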