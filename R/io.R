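#' Read a CT volume in Hounsfield units
#'
#' Reads a NIfTI-1 file (`.nii`, `.nii.gz`), a MetaImage file (`.mha`,
#' `.mhd`), or a directory holding exactly one uncompressed DICOM series.
#' DICOM stored values are converted to HU with the rescale slope/intercept
#' from the headers; no intensity windowing is applied by any reader. Voxel
#' spacing is always taken from the file headers and never silently assumed.
#'
#' @param path file path, or directory path for a DICOM series.
#' @return A [ct_volume].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) renalws_error(sprintf("no such file: %s", path))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return(read_nifti_volume(path))
  if (grepl("\\.(mha|mhd)$", lp)) return(read_metaimage(path))
  renalws_error(sprintf("unrecognised volume format: %s", path))
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) renalws_error(sprintf("cannot read NIfTI '%s': %s",
                                                           path, conditionMessage(e))))
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 4L) {
    warning("4D NIfTI: using the first volume")
    arr <- arr[, , , 1, drop = TRUE]
  } else if (nd != 3L) {
    renalws_error(sprintf("NIfTI '%s' is %dD; need a 3D volume", path, nd))
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    renalws_error(sprintf("NIfTI '%s' has missing or invalid voxel spacing", path))
  ct_volume(array(as.double(arr), dim(arr)), sp)
}

#' Write a CT volume
#'
#' Writes a volume as NIfTI (`.nii`, `.nii.gz`) or uncompressed MetaImage
#' (`.mha`), preserving voxel spacing.
#'
#' @param vol a [ct_volume].
#' @param path output file path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_ct_volume(vol))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", lp)) {
    write_metaimage(vol$data, vol$spacing, path, element_type = "MET_DOUBLE")
  } else {
    renalws_error(sprintf("unsupported output format: %s", path))
  }
  invisible(path)
}

#' Write a binary mask or label image
#'
#' Binary masks are stored as unsigned 8-bit and label images as unsigned
#' 16-bit integers (label 0 is reserved for background / watershed lines).
#' The round trip through [read_volume()] is lossless.
#'
#' @param mask logical 3D array (binary mask) or non-negative integer 3D
#'   array (label image).
#' @param path output path (`.nii`, `.nii.gz`, or `.mha`).
#' @param spacing voxel spacing in mm of the parent volume.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3D array")
  if (is.logical(mask)) {
    arr <- array(as.integer(mask), dim(mask))
    dtype <- "uint8"; met <- "MET_UCHAR"
  } else {
    arr <- mask
    storage.mode(arr) <- "integer"
    if (any(arr < 0L) || any(arr > 65535L)) stop("label values must be in [0, 65535]")
    dtype <- "uint16"; met <- "MET_USHORT"
  }
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path, datatype = dtype)
  } else if (grepl("\\.mha$", lp)) {
    write_metaimage(arr, spacing, path, element_type = met)
  } else {
    renalws_error(sprintf("unsupported output format: %s", path))
  }
  invisible(path)
}

#' Read a binary mask
#'
#' @param path a mask previously written by [write_mask()].
#' @return logical 3D array with attribute `"spacing"`.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  m <- vol$data > 0
  attr(m, "spacing") <- vol$spacing
  m
}

## ---- MetaImage (.mha/.mhd) ------------------------------------------------
## No installed R package reads MetaImage, so the (simple) format is handled
## here: an ASCII key=value header followed by raw binary voxels, either in
## the same file (.mha, ElementDataFile = LOCAL) or a sidecar .raw (.mhd).

.met_types <- list(
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) renalws_error(sprintf("'%s': truncated MetaImage header", path))
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L) renalws_error(sprintf("'%s': malformed MetaImage header line: %s", path, line))
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  nd <- as.integer(hdr$NDims %||% "0")
  if (nd != 3L) renalws_error(sprintf("'%s': need NDims = 3, got %d", path, nd))
  dm <- as.integer(strsplit(trimws(hdr$DimSize), "\\s+")[[1]])
  sp <- hdr$ElementSpacing %||% hdr$ElementSize
  if (is.null(sp)) renalws_error(sprintf("'%s': MetaImage header lacks ElementSpacing", path))
  sp <- as.numeric(strsplit(trimws(sp), "\\s+")[[1]])
  if (length(dm) != 3L || length(sp) != 3L)
    renalws_error(sprintf("'%s': DimSize/ElementSpacing must have 3 entries", path))
  et <- hdr$ElementType
  tinfo <- .met_types[[et %||% ""]]
  if (is.null(tinfo)) renalws_error(sprintf("'%s': unsupported ElementType '%s'", path, et))
  if (tolower(hdr$CompressedData %||% "false") == "true")
    renalws_error(sprintf("'%s': compressed MetaImage data is not supported", path))
  msb <- tolower(hdr$ElementByteOrderMSB %||% hdr$BinaryDataByteOrderMSB %||% "false") == "true"
  n <- prod(dm)
  df <- trimws(hdr$ElementDataFile)
  if (toupper(df) == "LOCAL") {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), df)
    if (!file.exists(raw_path)) renalws_error(sprintf("'%s': data file '%s' not found", path, df))
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, what = tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = if (msb) "big" else "little")
  if (length(vals) != n) renalws_error(sprintf("'%s': expected %d voxels, read %d", path, n, length(vals)))
  ct_volume(array(as.double(vals), dm), sp)
}

write_metaimage <- function(arr, spacing, path, element_type = "MET_DOUBLE") {
  tinfo <- .met_types[[element_type]]
  if (is.null(tinfo)) stop("unsupported ElementType: ", element_type)
  dm <- dim(arr)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("DimSize = %d %d %d", dm[1], dm[2], dm[3]),
           sprintf("ElementSpacing = %.10g %.10g %.10g", spacing[1], spacing[2], spacing[3]),
           sprintf("ElementType = %s", element_type),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  vals <- as.vector(arr)
  if (tinfo$what == "integer") vals <- as.integer(vals)
  writeBin(vals, con, size = tinfo$size, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- DICOM series (read-only) ---------------------------------------------
## Minimal single-frame CT reader: uncompressed little-endian transfer
## syntaxes (implicit 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1),
## one series per directory. Slices are sorted along the patient z axis and
## stored values are rescaled to HU.

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) renalws_error(sprintf("'%s': no files in DICOM directory", dir))
  slices <- lapply(files, read_dicom_file)
  slices <- slices[!vapply(slices, is.null, logical(1))]
  if (length(slices) == 0L) renalws_error(sprintf("'%s': no readable DICOM slices", dir))
  uids <- unique(vapply(slices, function(s) s$series_uid %||% "", character(1)))
  if (length(uids) > 1L)
    renalws_error(sprintf("'%s': directory holds %d DICOM series; expected exactly one",
                          dir, length(uids)))
  rc <- unique(t(vapply(slices, function(s) c(s$rows, s$cols), integer(2))))
  if (nrow(rc) > 1L) renalws_error(sprintf("'%s': inconsistent slice dimensions", dir))
  zs <- vapply(slices, function(s) s$zpos, numeric(1))
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  if (length(slices) >= 2L) {
    dz <- diff(zs)
    if (any(dz <= 0)) renalws_error(sprintf("'%s': duplicate slice positions", dir))
    if (max(dz) - min(dz) > 1e-3 * max(dz))
      warning("non-uniform slice spacing; using the mean")
    dz <- mean(dz)
  } else {
    dz <- slices[[1]]$slice_thickness
    if (is.null(dz)) renalws_error(sprintf("'%s': cannot determine slice spacing", dir))
  }
  ps <- slices[[1]]$pixel_spacing        # (row spacing = dy, column spacing = dx)
  if (is.null(ps)) renalws_error(sprintf("'%s': DICOM PixelSpacing missing", dir))
  nxy <- c(slices[[1]]$cols, slices[[1]]$rows)
  arr <- array(0, c(nxy, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    # PixelData is row-major; matrix(nrow = cols) yields [x = col, y = row]
    arr[, , k] <- matrix(s$slope * s$pixels + s$intercept, nrow = s$cols)
  }
  ct_volume(arr, c(ps[2], ps[1], dz))
}

.dcm_u16 <- function(raw, off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
.dcm_u32 <- function(raw, off) {
  .dcm_u16(raw, off) + 65536 * .dcm_u16(raw, off + 2)
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  off <- 0L
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") off <- 132L
  explicit <- TRUE
  ts <- NULL
  out <- list(slope = 1, intercept = 0, slice_thickness = NULL)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  n <- length(raw)
  in_meta <- off > 0L
  repeat {
    if (off + 8 > n) break
    group <- .dcm_u16(raw, off); elem <- .dcm_u16(raw, off + 2)
    if (in_meta && group != 2L) {
      # end of the (always explicit) file meta group
      in_meta <- FALSE
      if (!is.null(ts)) {
        if (ts == "1.2.840.10008.1.2") explicit <- FALSE
        else if (ts != "1.2.840.10008.1.2.1")
          renalws_error(sprintf("'%s': unsupported DICOM transfer syntax %s", path, ts))
      }
    }
    use_explicit <- if (group == 2L) TRUE else explicit
    if (use_explicit) {
      vr <- rawToChar(raw[(off + 5):(off + 6)])
      if (vr %in% long_vrs) {
        len <- .dcm_u32(raw, off + 8); hdr <- 12L
      } else {
        len <- .dcm_u16(raw, off + 6); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- .dcm_u32(raw, off + 4); hdr <- 8L
    }
    if (len == 4294967295) renalws_error(sprintf("'%s': undefined-length DICOM elements unsupported", path))
    body <- off + hdr
    if (body + len > n) break
    val_raw <- if (len > 0) raw[(body + 1):(body + len)] else raw(0)
    tag <- sprintf("%04x,%04x", group, elem)
    str_val <- function() trimws(rawToChar(val_raw[val_raw != as.raw(0)]))
    num_val <- function() as.numeric(strsplit(str_val(), "\\\\")[[1]])
    int2 <- function() .dcm_u16(val_raw, 0L)
    switch(tag,
      "0002,0010" = ts <- str_val(),
      "0020,000e" = out$series_uid <- str_val(),
      "0028,0010" = out$rows <- int2(),
      "0028,0011" = out$cols <- int2(),
      "0028,0100" = out$bits_alloc <- int2(),
      "0028,0103" = out$pixel_rep <- int2(),
      "0028,0030" = out$pixel_spacing <- num_val(),
      "0018,0050" = out$slice_thickness <- num_val()[1],
      "0020,0032" = out$ipp <- num_val(),
      "0020,1041" = out$slice_loc <- num_val()[1],
      "0028,1052" = out$intercept <- num_val()[1],
      "0028,1053" = out$slope <- num_val()[1],
      "7fe0,0010" = out$pixel_raw <- val_raw,
      NULL)
    off <- body + len
    if (tag == "7fe0,0010") break
  }
  if (is.null(out$rows) || is.null(out$cols) || is.null(out$pixel_raw)) return(NULL)
  bits <- out$bits_alloc %||% 16L
  if (bits != 16L) renalws_error(sprintf("'%s': only 16-bit DICOM pixel data supported", path))
  signed <- isTRUE((out$pixel_rep %||% 0L) == 1L)
  out$pixels <- readBin(out$pixel_raw, "integer", n = out$rows * out$cols,
                        size = 2L, signed = signed, endian = "little")
  if (!signed) out$pixels <- ifelse(out$pixels < 0, out$pixels + 65536L, out$pixels)
  out$zpos <- if (!is.null(out$ipp)) out$ipp[3] else (out$slice_loc %||% 0)
  out
}
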