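#' Volume input / output
#'
#' Volumes travel either as multi-page TIFF stacks (one page per z-slice,
#' via the tiff package) or as NRRD (raw-gzip encoding, minimal header,
#' written and read directly since no NRRD package is available in R).
#' Voxel size and label semantics are carried in a JSON sidecar
#' (`<file>.json`) for TIFF, and in the NRRD header itself.
#'
#' @name volume_io
NULL

.sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a volume as a multi-page TIFF stack
#'
#' Grayscale data are scaled to 16-bit; label volumes are written as their
#' integer labels. The JSON sidecar records `voxel_mm`, `kind`, value
#' scaling, and label semantics.
#'
#' @param vol a [label_volume] or [gray_volume].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  d <- dim(vol$data)
  is_lab <- inherits(vol, "label_volume")
  offset <- if (is_lab) 0 else min(vol$data)
  rng <- max(vol$data) - offset
  scale <- if (is_lab) max(max(vol$data), 1L) else if (rng > 0) rng else 1
  pages <- lapply(seq_len(d[3]), function(z)
    (vol$data[, , z] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(voxel_mm = vol$voxel_mm,
               kind = if (is_lab) "label" else "gray",
               scale = scale, offset = offset,
               semantics = if (is_lab) as.list(vol$semantics) else NULL)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) a[, , z] <- pages[[z]]
  off <- if (is.null(meta$offset)) 0 else meta$offset
  a <- a * meta$scale + off
  if (identical(meta$kind, "label")) {
    sem <- unlist(meta$semantics)
    label_volume(array(as.integer(round(a)), dim(a)), meta$voxel_mm,
                 setNames(as.integer(sem), names(sem)))
  } else {
    gray_volume(a, meta$voxel_mm)
  }
}

#' Write / read a volume as NRRD (gzip raw encoding)
#'
#' A minimal detached-free NRRD0004 writer/reader supporting the fields
#' this package produces: 3D, int/double, gzip encoding, isotropic
#' spacings. Label semantics ride in a key/value pair.
#'
#' @param vol a [label_volume] or [gray_volume].
#' @param path output `.nrrd` path.
#' @return `path`, invisibly.
#' @export
write_volume_nrrd <- function(vol, path) {
  d <- dim(vol$data)
  is_lab <- inherits(vol, "label_volume")
  type <- if (is_lab) "int" else "double"
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.10g %.10g %.10g", vol$voxel_mm,
                   vol$voxel_mm, vol$voxel_mm),
           "endian: little",
           "encoding: gzip",
           sprintf("kinds: domain domain domain"))
  if (is_lab)
    hdr <- c(hdr, sprintf("semantics:=%s",
                          paste(names(vol$semantics), vol$semantics,
                                sep = "=", collapse = ",")))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c(hdr, ""), con, sep = "\n")
  raw_data <- if (is_lab)
    writeBin(as.integer(vol$data), raw(), size = 4L, endian = "little")
  else
    writeBin(as.double(vol$data), raw(), size = 8L, endian = "little")
  writeBin(memCompress(raw_data, "gzip"), con)
  invisible(path)
}

#' @rdname write_volume_nrrd
#' @export
read_volume_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  # header ends at the first blank line (\n\n)
  nl <- which(raw_all == as.raw(10))
  blank <- nl[which(diff(nl) == 1L)[1] + 1L]
  if (is.na(blank)) .pc_stop("malformed NRRD: no blank line after header")
  hdr <- strsplit(rawToChar(raw_all[seq_len(blank)]), "\n")[[1]]
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", key, ": "), "", ln[1])
  }
  sizes <- as.integer(strsplit(get_field("sizes"), " ")[[1]])
  spac <- as.numeric(strsplit(get_field("spacings"), " ")[[1]])
  type <- get_field("type")
  if (!identical(get_field("encoding"), "gzip"))
    .pc_stop("only gzip-encoded NRRD supported")
  payload <- memDecompress(raw_all[(blank + 1L):length(raw_all)], "gzip")
  n <- prod(sizes)
  if (identical(type, "int")) {
    a <- array(readBin(payload, "integer", n, size = 4L, endian = "little"),
               sizes)
    sem_ln <- grep("^semantics:=", hdr, value = TRUE)
    sem <- tooth_semantics()
    if (length(sem_ln)) {
      kv <- strsplit(strsplit(sub("^semantics:=", "", sem_ln[1]), ",")[[1]], "=")
      sem <- setNames(as.integer(vapply(kv, `[`, "", 2)),
                      vapply(kv, `[`, "", 1))
    }
    label_volume(a, spac[1], sem)
  } else {
    gray_volume(array(readBin(payload, "double", n, size = 8L,
                              endian = "little"), sizes), spac[1])
  }
}
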