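## Minimal MATLAB level-5 MAT container support (internal).
##
## Only what the calibration record needs: little-endian files holding
## named double vectors/scalars and single-row char arrays, written as
## uncompressed miMATRIX elements. The reader parses exactly the element
## layout this writer emits (plus MATLAB-compatible padding rules), which
## is sufficient to round-trip records and to load them into MATLAB/Octave.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT32 <- 5L; MI_UINT32 <- 6L
MI_DOUBLE <- 9L; MI_UINT16 <- 4L; MI_MATRIX <- 14L
MX_CHAR <- 4L; MX_DOUBLE <- 6L

pad8 <- function(nbytes) (8L - nbytes %% 8L) %% 8L

mat5_tag <- function(type, nbytes) {
  c(writeBin_raw_int(type), writeBin_raw_int(nbytes))
}

writeBin_raw_int <- function(x, size = 4L) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

mat5_element <- function(name, value) {
  if (is.character(value)) {
    stopifnot(length(value) == 1L)
    codes <- utf8ToInt(value)
    data <- writeBin(as.integer(codes), raw(), size = 2L, endian = "little")
    data_tag <- mat5_tag(MI_UINT16, length(data))
    dims <- c(1L, length(codes))
    cls <- MX_CHAR
  } else {
    value <- as.numeric(value)
    data <- writeBin(value, raw(), size = 8L, endian = "little")
    data_tag <- mat5_tag(MI_DOUBLE, length(data))
    dims <- c(length(value), 1L)
    cls <- MX_DOUBLE
  }
  flags <- c(mat5_tag(MI_UINT32, 8L),
             writeBin_raw_int(cls), writeBin_raw_int(0L))
  dim_el <- c(mat5_tag(MI_INT32, 8L),
              writeBin_raw_int(dims[1]), writeBin_raw_int(dims[2]))
  name_raw <- charToRaw(name)
  name_el <- c(mat5_tag(MI_INT8, length(name_raw)), name_raw,
               raw(pad8(length(name_raw))))
  data_el <- c(data_tag, data, raw(pad8(length(data))))
  body <- c(flags, dim_el, name_el, data_el)
  c(mat5_tag(MI_MATRIX, length(body)), body)
}

mat5_write <- function(path, vars) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by ramanprep on %s",
                  iso_timestamp())
  desc_raw <- charToRaw(desc)
  header <- c(desc_raw, rep(charToRaw(" "), 116L - length(desc_raw)),
              raw(8L),                       # subsystem offset
              as.raw(c(0x00, 0x01)),         # version 0x0100, little-endian
              charToRaw("IM"))
  body <- unlist(lapply(names(vars), function(nm) mat5_element(nm, vars[[nm]])))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}

read_int <- function(raw, off, size = 4L, signed = TRUE) {
  readBin(raw[(off + 1L):(off + size)], "integer", size = size,
          endian = "little", signed = signed)
}

mat5_read <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 128L) stop("not a MAT level-5 file: header too short",
                                 call. = FALSE)
  if (rawToChar(bytes[127:128]) != "IM")
    stop("unsupported MAT file: expected little-endian ('IM') marker",
         call. = FALSE)
  off <- 128L
  vars <- list()
  while (off + 8L <= length(bytes)) {
    type <- read_int(bytes, off)
    nbytes <- read_int(bytes, off + 4L)
    if (type != MI_MATRIX)
      stop(sprintf("unsupported MAT element type %d", type), call. = FALSE)
    el <- bytes[(off + 9L):(off + 8L + nbytes)]
    parsed <- mat5_parse_matrix(el)
    vars[[parsed$name]] <- parsed$value
    off <- off + 8L + nbytes + pad8(nbytes)
  }
  vars
}

mat5_parse_matrix <- function(el) {
  p <- 0L
  sub <- function() {
    type <- read_int(el, p); nb <- read_int(el, p + 4L)
    dat <- if (nb > 0L) el[(p + 9L):(p + 8L + nb)] else raw(0)
    p <<- p + 8L + nb + pad8(nb)
    list(type = type, data = dat)
  }
  flags <- sub()
  cls <- as.integer(flags$data[1])
  dims <- sub()
  d1 <- read_int(dims$data, 0L); d2 <- read_int(dims$data, 4L)
  name_el <- sub()
  name <- rawToChar(name_el$data)
  data_el <- sub()
  value <- if (cls == MX_CHAR) {
    codes <- readBin(data_el$data, "integer", n = length(data_el$data) / 2L,
                     size = 2L, endian = "little", signed = FALSE)
    intToUtf8(codes)
  } else {
    readBin(data_el$data, "double", n = length(data_el$data) / 8L,
            size = 8L, endian = "little")
  }
  list(name = name, value = value, dims = c(d1, d2))
}
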