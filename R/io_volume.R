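#' Write a 3-D integer label volume as NRRD
#'
#' Minimal NRRD writer (NRRD0004) supporting `ascii` (text, fixture-friendly)
#' and `raw` (little-endian int32) encodings. There is no NRRD reader among
#' the installed packages, so the package carries its own small one.
#'
#' @param labels 3-D integer array, or an `annotation_volume`.
#' @param path Output path.
#' @param encoding "ascii" (default) or "raw".
#' @param voxel_size Voxel spacing recorded in the header (taken from the
#'   atlas when one is passed).
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(labels, path, encoding = c("ascii", "raw"),
                       voxel_size = 1) {
  encoding <- match.arg(encoding)
  if (inherits(labels, "annotation_volume")) {
    voxel_size <- labels$voxel_size
    labels <- labels$labels
  }
  stopifnot(length(dim(labels)) == 3)
  hdr <- c("NRRD0004",
           "type: int32",
           "dimension: 3",
           paste0("sizes: ", paste(dim(labels), collapse = " ")),
           paste0("spacings: ", paste(rep(voxel_size, 3), collapse = " ")),
           "endian: little",
           paste0("encoding: ", encoding),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(as.integer(labels), collapse = " "), con)
  } else {
    writeBin(as.integer(labels), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a minimal NRRD label volume
#'
#' Supports the subset written by [write_nrrd()]: 3-D int32, ascii or raw
#' little-endian encoding, attached data.
#'
#' @param path NRRD file path.
#' @return List with `labels` (3-D integer array) and `voxel_size`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    hdr <- c(hdr, line)
  }
  get_field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0(key, ":"))]
    if (length(ln) == 0) return(NULL)
    trimws(sub("^[^:]+:", "", ln[1]))
  }
  sizes <- as.integer(strsplit(get_field("sizes"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get_field("spacings") %||% "1 1 1",
                                 "\\s+")[[1]])[1]
  encoding <- get_field("encoding")
  n <- prod(sizes)
  data <- if (identical(encoding, "ascii")) {
    as.integer(scan(con, what = numeric(), n = n, quiet = TRUE))
  } else {
    readBin(con, integer(), n = n, size = 4, endian = "little")
  }
  list(labels = array(data, dim = sizes), voxel_size = spacing)
}

#' Write an annotation volume: NRRD labels + CSV region table
#' @param atlas An `annotation_volume`.
#' @param prefix Path prefix; writes `<prefix>.nrrd` and `<prefix>_regions.csv`.
#' @param encoding Passed to [write_nrrd()].
#' @export
write_atlas <- function(atlas, prefix, encoding = "ascii") {
  write_nrrd(atlas, paste0(prefix, ".nrrd"), encoding = encoding)
  utils::write.csv(atlas$regions, paste0(prefix, "_regions.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' Read an annotation volume written by [write_atlas()]
#' @param prefix Path prefix used at write time.
#' @param mirror_axis Mirror axis to record (header does not carry it).
#' @param origin Origin (um).
#' @export
read_atlas <- function(prefix, mirror_axis = 3, origin = c(0, 0, 0)) {
  v <- read_nrrd(paste0(prefix, ".nrrd"))
  regions <- utils::read.csv(paste0(prefix, "_regions.csv"))
  annotation_volume(v$labels, v$voxel_size, origin = origin,
                    mirror_axis = mirror_axis, regions = regions)
}
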