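#' Voxel volume container
#'
#' A `voxel_volume` is the carrier object between all pipeline stages: a 3D
#' array of voxel values (grayscale intensity or binary phase) on an isotropic
#' grid, together with the voxel edge length in millimetres and the physical
#' coordinate of the corner of voxel `[1,1,1]`.  Voxel centres sit at
#' `origin_mm + (index - 1 + 0.5) * spacing_mm` (0.5-offset, voxel-centred
#' convention).
#'
#' @param data 3D numeric/logical array.  Binary volumes contain only 0
#'   (background/marrow) and 1 (bone).
#' @param spacing_mm isotropic voxel edge length in mm (single positive value).
#' @param origin_mm physical coordinate (mm) of the corner of the first voxel;
#'   length-3 numeric.
#' @param meta optional named list of provenance metadata (generator spec,
#'   seed, achieved volume fraction, ...).
#' @return An object of class `voxel_volume`.
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 4)), spacing_mm = 0.05)
#' dim(v$data)
#' @export
voxel_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 2L))
    stop("all three grid dimensions must be >= 2")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  if (length(origin_mm) != 3L || !is.numeric(origin_mm))
    stop("`origin_mm` must be a length-3 numeric")
  storage.mode(data) <- "double"
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm), meta = meta),
    class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.4g mm (%s)\n",
              d[1], d[2], d[3], x$spacing_mm,
              if (is_binary(x)) "binary" else "grayscale"))
  if (is_binary(x))
    cat(sprintf("  foreground: %d voxels (%.1f%% of grid)\n",
                sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

#' Test whether a volume is binary (values only 0/1)
#' @param v a [voxel_volume()]
#' @return logical
#' @export
is_binary <- function(v) {
  stopifnot(inherits(v, "voxel_volume"))
  all(v$data %in% c(0, 1))
}

assert_binary <- function(v) {
  if (!is_binary(v))
    stop("a binary volume (values 0/1) is required; run otsu_threshold() first")
  invisible(v)
}

vol_dims <- function(v) dim(v$data)

#' Read a voxel volume from disk
#'
#' Supports NRRD (`.nrrd`, raw or ascii encoding, spacing taken from the
#' header) and single multi-page TIFF (`.tif`/`.tiff`; TIFF carries no 3D
#' spacing, so `spacing_mm` must be supplied).  A directory path is read as a
#' TIFF stack (one file per z-slice, lexicographic order).
#'
#' @param path file or directory path.
#' @param spacing_mm voxel size override in mm; required for TIFF input.
#' @return a [voxel_volume()]
#' @export
read_volume <- function(path, spacing_mm = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF slices found in directory: ", path)
    slices <- lapply(files, function(f) tiff::readTIFF(f) * 255)
    if (is.null(spacing_mm))
      stop("TIFF carries no 3D spacing metadata; supply `spacing_mm`")
    data <- simplify2array(slices)
    return(voxel_volume(data, spacing_mm))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(spacing_mm))
      stop("TIFF carries no 3D spacing metadata; supply `spacing_mm`")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    data <- simplify2array(lapply(pages, function(p) p * 255))
    voxel_volume(data, spacing_mm)
  } else if (ext == "nrrd") {
    read_nrrd(path, spacing_mm)
  } else {
    stop("unsupported volume format: .", ext, " (use .nrrd or .tif/.tiff)")
  }
}

#' Write a voxel volume to disk
#'
#' NRRD output stores the data as raw doubles with spacing and origin in the
#' header (lossless round trip).  TIFF output writes one 8-bit page per
#' z-slice with values scaled by 1/255; integer-valued volumes in \[0, 255\]
#' (including binary volumes) round-trip exactly, but spacing is not stored.
#' A JSON metadata sidecar (`<path>.json`) records spacing and any generator
#' metadata.
#'
#' @param v a [voxel_volume()]
#' @param path output path; format chosen by extension (`.nrrd`, `.tif`).
#' @param sidecar write the JSON metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, sidecar = TRUE) {
  stopifnot(inherits(v, "voxel_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    d <- dim(v$data)
    pages <- lapply(seq_len(d[3]), function(k) v$data[, , k] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else if (ext == "nrrd") {
    write_nrrd(v, path)
  } else {
    stop("unsupported volume format: .", ext, " (use .nrrd or .tif/.tiff)")
  }
  if (sidecar) {
    meta <- c(list(spacing_mm = v$spacing_mm, origin_mm = v$origin_mm,
                   dims = dim(v$data)), v$meta)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

# ---- minimal NRRD (no NRRD reader exists in the installed R stack) ----

write_nrrd <- function(v, path) {
  s <- v$spacing_mm
  o <- v$origin_mm
  d <- dim(v$data)
  hdr <- c(
    "NRRD0004",
    "# generated by daefbone",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "endian: little",
    "encoding: raw",
    "space dimension: 3",
    sprintf("space directions: (%.12g,0,0) (0,%.12g,0) (0,0,%.12g)", s, s, s),
    sprintf("space origin: (%.12g,%.12g,%.12g)", o[1], o[2], o[3]),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(v$data), con, size = 8L, endian = "little")
  invisible(path)
}

read_nrrd <- function(path, spacing_mm = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || line == "") break
    hdr <- c(hdr, line)
  }
  if (!length(hdr) || !grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path)
  field <- function(name) {
    hit <- grep(paste0("^", name, ": *"), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", name, ": *"), "", hit[1])
  }
  sizes <- as.integer(strsplit(trimws(field("sizes")), " +")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  type <- field("type")
  enc <- field("encoding")
  sp <- NULL
  if (!is.null(field("spacings"))) {
    sp <- as.numeric(strsplit(trimws(field("spacings")), " +")[[1]])
  } else if (!is.null(field("space directions"))) {
    vecs <- regmatches(field("space directions"),
                       gregexpr("\\(([^)]*)\\)", field("space directions")))[[1]]
    m <- sapply(vecs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]))
    sp <- sqrt(colSums(m^2))
  }
  origin <- c(0, 0, 0)
  if (!is.null(field("space origin")))
    origin <- as.numeric(strsplit(gsub("[()]", "", field("space origin")), ",")[[1]])
  if (!is.null(sp)) {
    if (max(abs(sp - sp[1])) > 1e-9 * sp[1])
      stop("anisotropic voxel spacing in NRRD header; resample the volume ",
           "to an isotropic grid before analysis")
    spacing_mm <- sp[1]
  }
  if (is.null(spacing_mm))
    stop("no spacing in NRRD header; supply `spacing_mm`")
  n <- prod(sizes)
  raw_type <- switch(type,
    "double" = list(what = numeric(), size = 8L),
    "float"  = list(what = numeric(), size = 4L),
    "uchar"  = , "uint8" = , "unsigned char" = list(what = integer(), size = 1L),
    "short"  = , "int16" = list(what = integer(), size = 2L),
    "int"    = , "int32" = list(what = integer(), size = 4L),
    stop("unsupported NRRD type: ", type))
  if (identical(enc, "raw")) {
    vals <- readBin(con, what = raw_type$what, n = n, size = raw_type$size,
                    endian = "little",
                    signed = !type %in% c("uchar", "uint8", "unsigned char"))
  } else if (identical(enc, "ascii") || identical(enc, "text")) {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  voxel_volume(array(as.numeric(vals), sizes), spacing_mm, origin)
}
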