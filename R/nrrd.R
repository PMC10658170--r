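# Minimal NRRD reader/writer for 3-D volumes.
#
# Supports the subset of NRRD used for binary voxel grids: 3-D arrays,
# raw or gzip encoding, little-endian integer/float types, optional
# `space directions` (diagonal) and `space origin` fields.  Data are
# stored with the first axis fastest, which coincides with R's
# column-major layout, so no transposition is needed.

.nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8"          = list(what = "integer", size = 1, signed = TRUE),
  "uchar"         = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8"         = list(what = "integer", size = 1, signed = FALSE),
  "short"         = list(what = "integer", size = 2, signed = TRUE),
  "int16"         = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "uint16"        = list(what = "integer", size = 2, signed = FALSE),
  "int"           = list(what = "integer", size = 4, signed = TRUE),
  "int32"         = list(what = "integer", size = 4, signed = TRUE),
  "unsigned int"  = list(what = "integer", size = 4, signed = FALSE),
  "uint32"        = list(what = "integer", size = 4, signed = FALSE),
  "float"         = list(what = "double", size = 4, signed = TRUE),
  "double"        = list(what = "double", size = 8, signed = TRUE)
)

.parse_nrrd_vectors <- function(value) {
  # "(1,0,0) (0,1,0) (0,0,1)" -> list of numeric vectors
  chunks <- regmatches(value, gregexpr("\\(([^)]*)\\)", value))[[1]]
  lapply(chunks, function(ch) {
    as.numeric(strsplit(gsub("[()]", "", ch), ",")[[1]])
  })
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic)) {
    stop("not an NRRD file: ", path)
  }
  header <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("unexpected end of NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line))
    pos <- regexpr(":=?", line)
    key <- tolower(trimws(substr(line, 1L, pos - 1L)))
    value <- trimws(substr(line, pos + attr(pos, "match.length"), nchar(line)))
    header[[key]] <- value
  }
  dim_n <- as.integer(header[["dimension"]])
  if (is.null(dim_n) || is.na(dim_n)) stop("NRRD header lacks 'dimension'")
  if (dim_n != 3L) stop("only 3-D NRRD volumes are supported, got dimension ", dim_n)
  sizes <- as.integer(strsplit(header[["sizes"]], "\\s+")[[1]])
  type <- .nrrd_types[[tolower(header[["type"]])]]
  if (is.null(type)) stop("unsupported NRRD type: ", header[["type"]])
  encoding <- tolower(header[["encoding"]])
  endian <- if (!is.null(header[["endian"]])) tolower(header[["endian"]]) else "little"

  payload <- readBin(con, "raw", n = file.size(path))
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding: ", encoding)
  }
  n <- prod(sizes)
  vals <- readBin(payload, what = type$what, n = n, size = type$size,
                  signed = if (type$size >= 4) TRUE else type$signed,
                  endian = endian)
  if (length(vals) != n) stop("NRRD payload truncated in ", path)
  arr <- array(vals, dim = sizes)

  spacing <- c(1, 1, 1)
  if (!is.null(header[["space directions"]])) {
    dirs <- .parse_nrrd_vectors(header[["space directions"]])
    if (length(dirs) == 3L) {
      spacing <- vapply(dirs, function(v) sqrt(sum(v^2)), numeric(1))
    }
  } else if (!is.null(header[["spacings"]])) {
    spacing <- as.numeric(strsplit(header[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(header[["space origin"]])) {
    org <- .parse_nrrd_vectors(header[["space origin"]])
    if (length(org) == 1L) origin <- org[[1]]
  }
  list(data = arr, spacing = spacing, origin = origin)
}

write_nrrd <- function(data, path, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       encoding = "gzip") {
  stopifnot(length(dim(data)) == 3L)
  header <- c(
    "NRRD0004",
    "type: unsigned char",
    "dimension: 3",
    "space: left-posterior-superior",
    paste("sizes:", paste(dim(data), collapse = " ")),
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
            spacing[1], spacing[2], spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    paste("encoding:", encoding),
    sprintf("space origin: (%g,%g,%g)", origin[1], origin[2], origin[3]),
    ""
  )
  payload <- as.raw(as.integer(data))
  if (encoding == "gzip") {
    # a true RFC 1952 gzip stream (memCompress emits zlib framing, which
    # other NRRD readers reject)
    tmp <- tempfile()
    con_gz <- gzfile(tmp, "wb")
    writeBin(payload, con_gz)
    close(con_gz)
    payload <- readBin(tmp, "raw", n = file.size(tmp))
    unlink(tmp)
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding: ", encoding)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}
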