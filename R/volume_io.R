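#' Read a 3D volume from disk
#'
#' Supported layouts:
#' * a multi-page TIFF file (pages become slices, first axis `z`);
#' * a directory of single-slice TIFF files, stacked in lexicographic
#'   filename order (`z000.tif`, `z001.tif`, ...);
#' * a raw little/big-endian binary next to a plain-text sidecar header
#'   `<path>.hdr` with keys `dims`, `dtype`, `spacing_um`, `byte_order`
#'   (see [write_volume()]).
#'
#' TIFF files carry no spacing metadata here; unless `spacing_override`
#' is given, the default of 9 um (the acquisition this package targets)
#' is applied with a warning.
#'
#' @param path File or directory path.
#' @param spacing_override Voxel spacing in um, overriding any metadata.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, spacing_override = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF slices found in directory ", path)
    idx <- suppressWarnings(as.integer(gsub("\\D", "",
                                            basename(files))))
    if (!anyNA(idx) && length(idx) > 1L) {
      gaps <- setdiff(seq(min(idx), max(idx)), idx)
      if (length(gaps))
        stop("slice stack in ", path, " has missing indices: ",
             paste(utils::head(gaps, 5L), collapse = ", "))
    }
    slices <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
    return(stack_slices(slices, spacing_override, src = path))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- paste0(path, ".hdr")
  if (grepl("\\.raw$", path) || file.exists(hdr)) {
    if (!file.exists(hdr)) stop("raw volume ", path,
                                " has no sidecar header ", hdr)
    return(read_raw_volume(path, hdr, spacing_override))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack_slices(pages, spacing_override, src = path)
}

stack_slices <- function(slices, spacing_override, src) {
  dims <- unique(lapply(slices, dim))
  if (length(dims) != 1L)
    stop("slices in ", src, " have inconsistent dimensions")
  d <- dims[[1]][1:2]
  a <- array(0, c(length(slices), d[1], d[2]))
  for (k in seq_along(slices)) a[k, , ] <- slices[[k]]
  if (all(a == round(a))) storage.mode(a) <- "integer"
  if (is.null(spacing_override)) {
    warning("no spacing metadata for ", src, "; assuming 9 um voxels")
    spacing_override <- 9
  }
  voxel_volume(a, spacing_override)
}

read_raw_volume <- function(path, hdr, spacing_override) {
  kv <- read_sidecar(hdr)
  need <- c("dims", "dtype")
  if (!all(need %in% names(kv)))
    stop("sidecar ", hdr, " must define: ", paste(need, collapse = ", "))
  dims <- as.integer(strsplit(kv[["dims"]], "[ ,x]+")[[1]])
  if (length(dims) != 3L || anyNA(dims)) stop("bad dims in ", hdr)
  dtype <- kv[["dtype"]]
  endian <- switch(hdr_field(kv, "byte_order") %||% "little",
                   little = "little", big = "big",
                   stop("bad byte_order in ", hdr))
  spacing <- spacing_override
  if (is.null(spacing)) {
    sp <- hdr_field(kv, "spacing_um")
    if (is.null(sp)) {
      warning("no spacing_um in ", hdr, "; assuming 9 um voxels")
      spacing <- 9
    } else {
      spacing <- as.numeric(strsplit(sp, "[ ,x]+")[[1]])
      if (length(spacing) == 3L &&
          (max(spacing) - min(spacing)) > 1e-9 * max(spacing))
        stop("anisotropic spacing_um (", sp, ") in ", hdr,
             "; only cubic voxels are supported")
      spacing <- spacing[1L]
    }
  }
  n <- prod(dims)
  con <- file(path, "rb"); on.exit(close(con))
  a <- switch(dtype,
    uint8  = array(as.integer(readBin(con, "integer", n, size = 1,
                                      signed = FALSE, endian = endian)), dims),
    uint16 = array(as.integer(readBin(con, "integer", n, size = 2,
                                      signed = FALSE, endian = endian)), dims),
    int32  = array(readBin(con, "integer", n, size = 4, endian = endian),
                   dims),
    float32 = array(readBin(con, "numeric", n, size = 4, endian = endian),
                    dims),
    float64 = array(readBin(con, "numeric", n, size = 8, endian = endian),
                    dims),
    stop("unsupported dtype '", dtype, "' in ", hdr))
  voxel_volume(a, spacing)
}

read_sidecar <- function(hdr) {
  lines <- readLines(hdr, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  stats::setNames(vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")),
                         ""),
                  vapply(kv, function(x) trimws(x[1]), ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hdr_field <- function(kv, key)
  if (key %in% names(kv)) kv[[key]] else NULL

#' Write a 3D volume to disk
#'
#' `format = "tiff"` writes a multi-page TIFF (integer data in
#' `[0, 65535]` stored losslessly at 8 or 16 bits; floats must already be
#' scaled to `[0, 1]` and are stored as 32-bit float).
#' `format = "raw"` writes platform-independent binary plus a text sidecar
#' `<path>.hdr`; this is the format that round-trips arbitrary floats.
#'
#' @param volume A [voxel_volume()].
#' @param path Output file path.
#' @param format `"tiff"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("tiff", "raw")) {
  stopifnot(is_voxel_volume(volume))
  format <- match.arg(format)
  a <- volume$data
  if (format == "tiff") {
    d <- dim(a)
    if (is.integer(a) || all(a == round(a))) {
      if (min(a) < 0 || max(a) > 65535)
        stop("integer TIFF output supports the range [0, 65535]; ",
             "use format = \"raw\"")
      bits <- if (max(a) > 255) 16L else 8L
      denom <- 2^bits - 1
      pages <- lapply(seq_len(d[1]), function(k)
        matrix(a[k, , ] / denom, d[2], d[3]))
    } else {
      if (min(a) < 0 || max(a) > 1)
        stop("float TIFF output requires values in [0, 1]; ",
             "use format = \"raw\"")
      bits <- 32L
      pages <- lapply(seq_len(d[1]), function(k) matrix(a[k, , ], d[2], d[3]))
    }
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    dtype <- if (is.integer(a)) {
      if (min(a) >= 0 && max(a) <= 255) "uint8"
      else if (min(a) >= 0 && max(a) <= 65535) "uint16"
      else "int32"
    } else "float64"
    size <- c(uint8 = 1L, uint16 = 2L, int32 = 4L, float64 = 8L)[[dtype]]
    con <- file(path, "wb")
    writeBin(if (size == 8) as.numeric(a) else as.integer(a), con,
             size = size, endian = "little")
    close(con)
    writeLines(c(paste("dims:", paste(dim(a), collapse = " ")),
                 paste("dtype:", dtype),
                 paste("spacing_um:", format(volume$spacing)),
                 "byte_order: little"),
               paste0(path, ".hdr"))
  }
  invisible(path)
}
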