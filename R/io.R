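# File formats: multi-page 16-bit TIFF with a JSON metadata sidecar, and
# a zarr-v2-compatible chunked array store for large volumes and float
# intermediates. Pages are (rows = y, cols = x or x') planes; page index
# is z for volumes and scan position s for raw stacks.

sidecar_path <- function(path) paste0(path, ".json")

write_pages_tiff <- function(path, arr, bits = 16L) {
  maxv <- 2^bits - 1
  pages <- lapply(seq_len(dim(arr)[1L]), function(k) arr[k, , ] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "LZW",
                  reduce = FALSE)
}

read_pages_tiff <- function(path, bits = 16L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  maxv <- 2^bits - 1
  d <- dim(pages[[1L]])
  arr <- array(0, c(length(pages), d[1L], d[2L]))
  for (k in seq_along(pages)) arr[k, , ] <- round(pages[[k]] * maxv)
  arr
}

#' Write an oblique stack as multi-page 16-bit TIFF plus metadata sidecar
#'
#' Integer counts in [0, 65535] round-trip bit-exactly; the acquisition
#' geometry is stored in `<path>.json`.
#'
#' @param stack an [oblique_stack()] with integer-valued counts.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "oblique_stack"))
  v <- stack$data
  if (any(v < 0 | v > 65535) || any(v != round(v))) {
    stop("stack counts must be integers within the 16-bit range; rescale first")
  }
  write_pages_tiff(path, v)
  g <- stack$geometry
  meta <- list(kind = "oblique_stack", n_frames = stack$n_frames,
               frame_shape = g$frame_shape, tilt_angle_deg = g$tilt_angle_deg,
               scan_step_um = g$scan_step_um, pixel_size_um = g$pixel_size_um,
               scan_mode = g$scan_mode, view_id = g$view_id,
               scan_origin_um = g$scan_origin_um,
               axis_order = "page=s, rows=y, cols=x'")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an oblique stack written by [write_stack()]
#'
#' @param path TIFF path; `<path>.json` must exist.
#' @return an [oblique_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing metadata sidecar: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  need <- c("tilt_angle_deg", "scan_step_um", "pixel_size_um", "view_id")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) {
    stop("metadata sidecar lacks required fields: ", paste(miss, collapse = ", "))
  }
  geom <- acq_geometry(scan_step_um = meta$scan_step_um,
                       pixel_size_um = meta$pixel_size_um,
                       tilt_angle_deg = meta$tilt_angle_deg,
                       scan_mode = if (is.null(meta$scan_mode)) "stage" else meta$scan_mode,
                       view_id = meta$view_id,
                       scan_origin_um = if (is.null(meta$scan_origin_um)) 0 else meta$scan_origin_um)
  oblique_stack(read_pages_tiff(path), geom)
}

#' Write a volume as multi-page 16-bit TIFF plus metadata sidecar
#'
#' Float volumes are scaled to the 16-bit range with the scale factor
#' declared in the sidecar, so values are recovered within one count of
#' the original after inverse scaling; integer volumes within range are
#' stored losslessly (`scale = 1`). Small negative values (e.g. ringing
#' from Fourier-domain operations) are clamped to zero on export.
#'
#' @param volume an [ortho_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ortho_volume"))
  v <- pmax(volume$data, 0)
  integral <- all(v == round(v)) && max(v) <= 65535
  scale <- if (integral) 1 else max(v) / 65535
  if (scale <= 0) scale <- 1
  write_pages_tiff(path, round(v / scale))
  meta <- list(kind = "ortho_volume", shape = dim(v),
               voxel_size_um = volume$voxel_size_um,
               origin_um = volume$origin_um, scale = scale,
               axis_order = "page=z, rows=y, cols=x")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path; `<path>.json` must exist.
#' @return an [ortho_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing metadata sidecar: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$voxel_size_um)) stop("metadata sidecar lacks voxel_size_um")
  arr <- read_pages_tiff(path) * (if (is.null(meta$scale)) 1 else meta$scale)
  ortho_volume(arr, meta$voxel_size_um,
               if (is.null(meta$origin_um)) c(0, 0, 0) else meta$origin_um)
}

zarr_dtype <- function(dtype) switch(dtype, u2 = "<u2", f4 = "<f4",
                                     stop("unsupported dtype: ", dtype))

#' Write a 3D array to a chunked compressed store (zarr v2 layout)
#'
#' Directory store with a `.zarray` JSON descriptor, zlib-compressed
#' C-order chunks named `i.j.k`, and an optional `.zattrs` for
#' domain metadata. Lossless: round trips are bit-exact for `"u2"`
#' (16-bit unsigned) and exact to float32 for `"f4"`.
#'
#' @param arr 3D numeric array.
#' @param path store directory (created; must not already exist).
#' @param chunks integer chunk shape. Default `c(64, 64, 64)` clamped to
#'   the array shape.
#' @param dtype `"u2"` (integer counts) or `"f4"` (float intermediate).
#' @param attrs optional named list written to `.zattrs`.
#' @return `path`, invisibly.
#' @export
write_chunked_store <- function(arr, path, chunks = c(64L, 64L, 64L),
                                dtype = c("u2", "f4"), attrs = NULL) {
  dtype <- match.arg(dtype)
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  if (dir.exists(path)) stop("store directory already exists: ", path)
  d <- dim(arr)
  chunks <- pmin(as.integer(chunks), d)
  if (dtype == "u2" && (any(arr < 0 | arr > 65535) || any(arr != round(arr)))) {
    stop("u2 store requires integer values within the 16-bit range")
  }
  dir.create(path, recursive = TRUE)
  zarray <- list(zarr_format = 2L, shape = d, chunks = chunks,
                 dtype = zarr_dtype(dtype),
                 compressor = list(id = "zlib", level = 6L),
                 fill_value = 0, order = "C", filters = NULL)
  jsonlite::write_json(zarray, file.path(path, ".zarray"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(attrs)) {
    jsonlite::write_json(attrs, file.path(path, ".zattrs"), auto_unbox = TRUE,
                         digits = NA)
  }
  ng <- ceiling(d / chunks)
  for (c1 in seq_len(ng[1L])) for (c2 in seq_len(ng[2L])) for (c3 in seq_len(ng[3L])) {
    block <- array(0, chunks)
    i1 <- ((c1 - 1L) * chunks[1L] + 1L):min(c1 * chunks[1L], d[1L])
    i2 <- ((c2 - 1L) * chunks[2L] + 1L):min(c2 * chunks[2L], d[2L])
    i3 <- ((c3 - 1L) * chunks[3L] + 1L):min(c3 * chunks[3L], d[3L])
    block[seq_along(i1), seq_along(i2), seq_along(i3)] <- arr[i1, i2, i3]
    flat <- as.vector(aperm(block, c(3L, 2L, 1L)))   # C order
    raw <- if (dtype == "u2") {
      writeBin(as.integer(flat), raw(), size = 2L, endian = "little")
    } else {
      writeBin(as.numeric(flat), raw(), size = 4L, endian = "little")
    }
    writeBin(memCompress(raw, type = "gzip"),
             file.path(path, paste(c1 - 1L, c2 - 1L, c3 - 1L, sep = ".")))
  }
  invisible(path)
}

#' Read a 3D array from a chunked store written by [write_chunked_store()]
#'
#' @param path store directory containing `.zarray`.
#' @return list with `data` (3D array) and `attrs` (list or NULL).
#' @export
read_chunked_store <- function(path) {
  zp <- file.path(path, ".zarray")
  if (!file.exists(zp)) stop("not a chunked store (missing .zarray): ", path)
  za <- jsonlite::read_json(zp, simplifyVector = TRUE)
  d <- as.integer(za$shape); chunks <- as.integer(za$chunks)
  dtype <- switch(za$dtype, "<u2" = "u2", "<f4" = "f4",
                  stop("unsupported dtype in store: ", za$dtype))
  arr <- array(0, d)
  ng <- ceiling(d / chunks)
  for (c1 in seq_len(ng[1L])) for (c2 in seq_len(ng[2L])) for (c3 in seq_len(ng[3L])) {
    f <- file.path(path, paste(c1 - 1L, c2 - 1L, c3 - 1L, sep = "."))
    raw <- memDecompress(readBin(f, raw(), file.size(f)), type = "gzip")
    flat <- if (dtype == "u2") {
      readBin(raw, integer(), n = prod(chunks), size = 2L, signed = FALSE,
              endian = "little")
    } else {
      readBin(raw, numeric(), n = prod(chunks), size = 4L, endian = "little")
    }
    block <- aperm(array(flat, rev(chunks)), c(3L, 2L, 1L))
    i1 <- ((c1 - 1L) * chunks[1L] + 1L):min(c1 * chunks[1L], d[1L])
    i2 <- ((c2 - 1L) * chunks[2L] + 1L):min(c2 * chunks[2L], d[2L])
    i3 <- ((c3 - 1L) * chunks[3L] + 1L):min(c3 * chunks[3L], d[3L])
    arr[i1, i2, i3] <- block[seq_along(i1), seq_along(i2), seq_along(i3)]
  }
  ap <- file.path(path, ".zattrs")
  attrs <- if (file.exists(ap)) jsonlite::read_json(ap, simplifyVector = TRUE) else NULL
  list(data = arr, attrs = attrs)
}
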