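#' Volume I/O in NRRD format
#'
#' Minimal NRRD (.nrrd) reader/writer for 3D scalar volumes: ASCII header
#' plus raw little-endian payload. Densities are stored as `float32`,
#' masks as `uint8` (0/1); origin and spacing travel in the
#' `space origin` / `space directions` fields, so a write-read round trip
#' preserves grid and values bit-exactly for these types. NIfTI input is
#' not supported (no NIfTI codec is available in the R dependency set)
#' and raises a format error.
#'
#' @param obj a [phantom()] or a logical mask (3D array). For a bare mask
#'   supply `grid`.
#' @param path file path ending in `.nrrd`.
#' @param grid required [voxel_grid()] when writing a bare mask array.
#' @return `write_volume` returns `path` invisibly.
#' @export
write_volume <- function(obj, path, grid = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path))
    stop("write_volume: NIfTI is not supported; use NRRD (.nrrd)")
  if (inherits(obj, "phantom")) {
    grid <- obj$grid
    data <- obj$density
    type <- "float"
  } else if (is.logical(obj)) {
    if (is.null(grid)) stop("write_volume: mask output needs `grid`")
    data <- obj
    type <- "uint8"
  } else stop("write_volume: expected a phantom or a logical mask")
  stopifnot(identical(dim(data), as.integer(grid$dims)))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# fvheeplan volume",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(grid$dims, collapse = " ")),
    paste0("space directions: ",
           sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   grid$spacing[1], grid$spacing[2], grid$spacing[3])),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    paste0("space origin: ",
           sprintf("(%.17g,%.17g,%.17g)",
                   grid$origin[1], grid$origin[2], grid$origin[3])),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  if (type == "float") {
    writeBin(as.numeric(data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(data), con, size = 1L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_volume
#' @param as for `read_volume`: "auto" returns a phantom for float
#'   payloads and a logical mask (with the grid attached as attribute
#'   `grid`) for uint8.
#' @return `read_volume` returns a [phantom()] or a logical mask array
#'   with attribute `grid`.
#' @export
read_volume <- function(path, as = "auto") {
  if (grepl("\\.nii(\\.gz)?$", path))
    stop("read_volume: NIfTI is not supported; use NRRD (.nrrd)")
  con <- file(path, "rb")
  on.exit(close(con))
  # byte-wise line reader: readLines buffers ahead and would desync the
  # subsequent readBin of the raw payload
  read_line <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L) return(NULL)
      if (b == as.raw(10L)) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  magic <- read_line()
  if (is.null(magic) || !startsWith(magic, "NRRD"))
    stop("read_volume: not an NRRD file")
  fields <- list()
  repeat {
    ln <- read_line()
    if (is.null(ln)) stop("read_volume: truncated header")
    if (ln == "") break
    if (startsWith(ln, "#")) next
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2L) fields[[kv[1]]] <- kv[2]
  }
  dim_n <- as.integer(fields[["dimension"]])
  if (is.null(dim_n) || dim_n != 3L)
    stop("read_volume: expected a 3D scalar volume, got dimension ",
         fields[["dimension"]])
  sizes <- as.integer(strsplit(fields[["sizes"]], " ")[[1]])
  type <- fields[["type"]]
  if (!identical(fields[["encoding"]], "raw"))
    stop("read_volume: only raw encoding is supported")
  nums <- function(s) as.numeric(regmatches(s, gregexpr(
    "[-+0-9.eE]+", s))[[1]])
  dirs <- nums(fields[["space directions"]])
  spacing <- c(dirs[1], dirs[5], dirs[9])
  origin <- nums(fields[["space origin"]])
  g <- voxel_grid(origin, spacing, sizes)

  n <- prod(sizes)
  if (type %in% c("float", "float32")) {
    vals <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
    phantom(g, array(vals, dim = sizes))
  } else if (type %in% c("uint8", "uchar", "unsigned char")) {
    vals <- readBin(con, integer(), n = n, size = 1L, signed = FALSE,
                    endian = "little")
    m <- array(vals != 0L, dim = sizes)
    attr(m, "grid") <- g
    m
  } else stop("read_volume: unsupported type '", type, "'")
}

#' Case-template JSON sidecar
#'
#' @param template a [case_template()].
#' @param path JSON file path.
#' @export
write_case_template <- function(template, path) {
  stopifnot(inherits(template, "case_template"))
  jsonlite::write_json(unclass(template), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_case_template
#' @export
read_case_template <- function(path) {
  x <- jsonlite::fromJSON(path)
  case_template(x$name, x$beam_angles, energy = x$energy,
                margin = x$margin, spacing_factor = x$spacing_factor,
                d_pres = x$d_pres, n_fractions = x$n_fractions,
                normalization = x$normalization)
}
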