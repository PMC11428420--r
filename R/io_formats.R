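# ---------------------------------------------------------------------------
# Minimal file-format plumbing.  Nothing in the pre-installed R stack reads
# NPZ/PNG/DICOM, so small special-purpose readers/writers are implemented
# here:
#   * NPY v1/v2 (little-endian numeric dtypes) inside a ZIP container (NPZ),
#     stored or deflated, numpy-compatible;
#   * PNG grayscale, color type 0, bit depth 8/16, filters 0-4 on read,
#     filter 0 on write, zlib through the system libz;
#   * DICOM single-frame little-endian (explicit or implicit VR) read-only,
#     RescaleSlope/Intercept applied so pixels come back in HU.
# ---------------------------------------------------------------------------

# --- npy -------------------------------------------------------------------

npy_bytes <- function(m) {
  # write float64, C (row-major) order
  hdr <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                 nrow(m), ncol(m))
  total <- 10L + nchar(hdr) + 1L
  pad <- (64L - total %% 64L) %% 64L
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(hdr)), con, size = 2L, endian = "little")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
  rawConnectionValue(con)
}

parse_npy <- function(bytes) {
  if (length(bytes) < 10 || bytes[1] != 0x93 ||
      rawToChar(bytes[2:6]) != "NUMPY")
    stop("not an npy payload")
  major <- as.integer(bytes[7])
  if (major == 1L) {
    hlen <- readBin(bytes[9:10], "integer", size = 2L, endian = "little",
                    signed = FALSE)
    off <- 10L
  } else {
    hlen <- readBin(bytes[9:12], "integer", size = 4L, endian = "little")
    off <- 12L
  }
  hdr <- rawToChar(bytes[(off + 1):(off + hlen)])
  descr <- regmatches(hdr, regexec("'descr':\\s*'([^']+)'", hdr))[[1]][2]
  fortran <- grepl("'fortran_order':\\s*True", hdr)
  shp <- regmatches(hdr, regexec("'shape':\\s*\\(([^)]*)\\)", hdr))[[1]][2]
  dims <- as.integer(strsplit(gsub("\\s", "", shp), ",")[[1]])
  dims <- dims[!is.na(dims)]
  data <- bytes[(off + hlen + 1):length(bytes)]
  n <- prod(dims)
  v <- switch(descr,
              "<f8" = readBin(data, "double", n, size = 8L, endian = "little"),
              "<f4" = readBin(data, "double", n, size = 4L, endian = "little"),
              "<i8" = readBin(data, "double", n, size = 8L, endian = "little"),
              "<i4" = readBin(data, "integer", n, size = 4L, endian = "little"),
              "<i2" = readBin(data, "integer", n, size = 2L, endian = "little"),
              "<u2" = readBin(data, "integer", n, size = 2L, endian = "little",
                              signed = FALSE),
              "|u1" = as.integer(data[seq_len(n)]),
              "<u1" = as.integer(data[seq_len(n)]),
              stop("unsupported npy dtype: ", descr))
  v <- as.numeric(v)
  if (length(dims) == 1L) return(matrix(v, nrow = dims[1], ncol = 1L))
  if (length(dims) != 2L) stop("only 1-d/2-d npy arrays are supported")
  if (fortran) matrix(v, nrow = dims[1], ncol = dims[2])
  else t(matrix(v, nrow = dims[2], ncol = dims[1]))
}

# --- zip container ----------------------------------------------------------

write_zip_stored <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0L
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) {
    x <- as.numeric(x) %% 2^32
    writeBin(as.integer(bitwAnd(x %% 2^16, 0xFFFF)), con, size = 2L,
             endian = "little")
    writeBin(as.integer(x %/% 2^16), con, size = 2L, endian = "little")
  }
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    data <- entries[[i]]
    offsets[i] <- pos
    crcs[i] <- cpp_crc32(data)
    writeBin(as.raw(c(0x50, 0x4b, 0x03, 0x04)), con)
    w16(20); w16(0); w16(0); w16(0); w16(0)
    w32(crcs[i]); w32(length(data)); w32(length(data))
    w16(nchar(nm)); w16(0)
    writeChar(nm, con, eos = NULL)
    writeBin(data, con)
    pos <- pos + 30L + nchar(nm) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    data <- entries[[i]]
    writeBin(as.raw(c(0x50, 0x4b, 0x01, 0x02)), con)
    w16(20); w16(20); w16(0); w16(0); w16(0); w16(0)
    w32(crcs[i]); w32(length(data)); w32(length(data))
    w16(nchar(nm)); w16(0); w16(0); w16(0); w16(0)
    w32(0); w32(offsets[i])
    writeChar(nm, con, eos = NULL)
    pos <- pos + 46L + nchar(nm)
  }
  writeBin(as.raw(c(0x50, 0x4b, 0x05, 0x06)), con)
  w16(0); w16(0); w16(length(entries)); w16(length(entries))
  w32(pos - cd_start); w32(cd_start); w16(0)
  invisible(path)
}

read_u16 <- function(b, off) readBin(b[(off + 1):(off + 2)], "integer",
                                     size = 2L, endian = "little",
                                     signed = FALSE)
read_u32 <- function(b, off) {
  lo <- read_u16(b, off); hi <- read_u16(b, off + 2L)
  lo + hi * 65536
}

read_zip <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  # locate end-of-central-directory record
  tail_start <- max(0L, length(b) - 65558L)
  eocd <- NA_integer_
  for (off in seq(length(b) - 22L, tail_start)) {
    if (b[off + 1] == 0x50 && b[off + 2] == 0x4b && b[off + 3] == 0x05 &&
        b[off + 4] == 0x06) { eocd <- off; break }
  }
  if (is.na(eocd)) stop("not a zip archive: ", path)
  n_entries <- read_u16(b, eocd + 10L)
  cd_off <- read_u32(b, eocd + 16L)
  out <- list()
  off <- cd_off
  for (i in seq_len(n_entries)) {
    if (read_u32(b, off) != 0x02014b50) stop("corrupt zip central directory")
    method <- read_u16(b, off + 10L)
    csize <- read_u32(b, off + 20L)
    nmlen <- read_u16(b, off + 28L)
    extlen <- read_u16(b, off + 30L)
    cmtlen <- read_u16(b, off + 32L)
    lho <- read_u32(b, off + 42L)
    nm <- rawToChar(b[(off + 47L):(off + 46L + nmlen)])
    # local header gives the actual name/extra lengths before the data
    lnm <- read_u16(b, lho + 26L)
    lext <- read_u16(b, lho + 28L)
    dstart <- lho + 30L + lnm + lext
    data <- b[(dstart + 1):(dstart + csize)]
    if (method == 8L) data <- cpp_inflate(data, -15L)
    else if (method != 0L) stop("unsupported zip compression method: ", method)
    out[[nm]] <- data
    off <- off + 46L + nmlen + extlen + cmtlen
  }
  out
}

#' Write / read a numeric matrix as NPZ
#'
#' Stores a single float64 array named `pixels.npy` in a stored-method ZIP,
#' loadable with `numpy.load`. Round trip is bit exact.
#'
#' @param m numeric matrix.
#' @param path destination path.
#' @keywords internal
write_npz <- function(m, path) {
  write_zip_stored(list("pixels.npy" = npy_bytes(m)), path)
}

read_npz <- function(path) {
  entries <- read_zip(path)
  npys <- grep("\\.npy$", names(entries), value = TRUE)
  if (!length(npys)) stop("npz contains no .npy entry: ", path)
  parse_npy(entries[[npys[1]]])
}

write_npz_image <- function(img, path) {
  write_npz(img$pixels, path)
}

read_npz_image <- function(path, domain_tag = "low_dose",
                           background_value = -2048, source_id = path) {
  px <- read_npz(path)
  normalized <- min(px) >= 0 && max(px) <= 1
  ct_image(px, domain_tag = domain_tag, normalized = normalized,
           background_value = background_value, source_id = source_id,
           norm_min = NA_real_, norm_max = NA_real_)
}

# --- png --------------------------------------------------------------------

as_int32 <- function(x) {  # unsigned 32-bit value -> R signed integer bits
  as.integer(if (x > 2^31 - 1) x - 2^32 else x)
}

png_chunk <- function(con, type, payload) {
  writeBin(length(payload), con, size = 4L, endian = "big")
  body <- c(charToRaw(type), payload)
  writeBin(body, con)
  writeBin(as_int32(cpp_crc32(body)), con, size = 4L, endian = "big")
}

write_png_image <- function(img, path, bit_depth = 16L) {
  stopifnot(bit_depth %in% c(8L, 16L))
  p <- img$pixels
  lo <- min(p); hi <- max(p)
  if (!img$normalized) {
    p <- if (hi > lo) (p - lo) / (hi - lo) else p * 0
  }
  maxv <- 2^bit_depth - 1
  q <- round(p * maxv)
  h <- nrow(q); w <- ncol(q)
  # scanlines: filter byte 0 + row pixels, big-endian samples
  if (bit_depth == 8L) {
    rows <- lapply(seq_len(h), function(i) as.raw(c(0L, q[i, ])))
  } else {
    rows <- lapply(seq_len(h), function(i) {
      v <- as.integer(q[i, ])
      c(as.raw(0L), as.raw(rbind(v %/% 256L, v %% 256L)))
    })
  }
  payload <- cpp_deflate(unlist(rows), 15L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)), con)
  ihdr <- rawConnection(raw(0), "wb")
  writeBin(w, ihdr, size = 4L, endian = "big")
  writeBin(h, ihdr, size = 4L, endian = "big")
  writeBin(as.raw(c(bit_depth, 0L, 0L, 0L, 0L)), ihdr)
  ihdr_raw <- rawConnectionValue(ihdr); close(ihdr)
  png_chunk(con, "IHDR", ihdr_raw)
  png_chunk(con, "IDAT", payload)
  png_chunk(con, "IEND", raw(0))
  invisible(path)
}

read_png_image <- function(path, domain_tag = "low_dose", source_id = path) {
  b <- readBin(path, "raw", file.info(path)$size)
  sig <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))
  if (length(b) < 8 || !identical(b[1:8], sig))
    stop("not a PNG file: ", path)
  off <- 8L
  width <- height <- bit_depth <- color_type <- NULL
  idat <- raw(0)
  while (off < length(b)) {
    len <- readBin(b[(off + 1):(off + 4)], "integer", size = 4L,
                   endian = "big")
    type <- rawToChar(b[(off + 5):(off + 8)])
    payload <- if (len > 0) b[(off + 9):(off + 8 + len)] else raw(0)
    if (type == "IHDR") {
      width <- readBin(payload[1:4], "integer", size = 4L, endian = "big")
      height <- readBin(payload[5:8], "integer", size = 4L, endian = "big")
      bit_depth <- as.integer(payload[9])
      color_type <- as.integer(payload[10])
    } else if (type == "IDAT") {
      idat <- c(idat, payload)
    } else if (type == "IEND") break
    off <- off + 12L + len
  }
  if (is.null(width)) stop("PNG missing IHDR: ", path)
  if (color_type != 0L || !bit_depth %in% c(8L, 16L))
    stop("read_png_image: only 8/16-bit grayscale PNG supported (", path, ")")
  bytes <- cpp_inflate(idat, 15L)
  bpp <- bit_depth %/% 8L
  stride <- 1L + width * bpp
  m <- matrix(0, nrow = height, ncol = width)
  prev <- integer(width * bpp)
  paeth <- function(a, bb, cc) {
    p <- a + bb - cc
    pa <- abs(p - a); pb <- abs(p - bb); pc <- abs(p - cc)
    ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, bb, cc))
  }
  for (i in seq_len(height)) {
    row0 <- (i - 1L) * stride
    ft <- as.integer(bytes[row0 + 1L])
    cur <- as.integer(bytes[(row0 + 2L):(row0 + stride)])
    n <- length(cur)
    if (ft == 1L) {
      for (j in seq_len(n)) {
        a <- if (j > bpp) cur[j - bpp] else 0L
        cur[j] <- (cur[j] + a) %% 256L
      }
    } else if (ft == 2L) {
      cur <- (cur + prev) %% 256L
    } else if (ft == 3L) {
      for (j in seq_len(n)) {
        a <- if (j > bpp) cur[j - bpp] else 0L
        cur[j] <- (cur[j] + (a + prev[j]) %/% 2L) %% 256L
      }
    } else if (ft == 4L) {
      for (j in seq_len(n)) {
        a <- if (j > bpp) cur[j - bpp] else 0L
        cc <- if (j > bpp) prev[j - bpp] else 0L
        cur[j] <- (cur[j] + paeth(a, prev[j], cc)) %% 256L
      }
    } else if (ft != 0L) stop("unsupported PNG filter type: ", ft)
    prev <- cur
    m[i, ] <- if (bpp == 1L) cur
              else cur[seq(1L, n, 2L)] * 256L + cur[seq(2L, n, 2L)]
  }
  maxv <- 2^bit_depth - 1
  ct_image(m / maxv, domain_tag = domain_tag, normalized = TRUE,
           source_id = source_id)
}

# --- dicom ------------------------------------------------------------------

read_dicom_image <- function(path, domain_tag = "low_dose",
                             background_value = -2048, source_id = path) {
  b <- readBin(path, "raw", file.info(path)$size)
  if (length(b) < 132 || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  off <- 132L
  explicit <- TRUE
  transfer_syntax <- "1.2.840.10008.1.2.1"
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off < length(b)) {
    group <- read_u16(b, off); elem <- read_u16(b, off + 2L)
    off <- off + 4L
    in_meta <- group == 0x0002
    expl <- if (in_meta) TRUE else explicit
    if (expl) {
      vr <- rawToChar(b[(off + 1):(off + 2)])
      if (vr %in% long_vrs) {
        len <- read_u32(b, off + 4L)
        off <- off + 8L
      } else {
        len <- read_u16(b, off + 2L)
        off <- off + 4L
      }
    } else {
      vr <- ""
      len <- read_u32(b, off)
      off <- off + 4L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements unsupported")
    value <- if (len > 0) b[(off + 1):(off + len)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, value = value)
    off <- off + len
    if (key == "0002,0010")
      transfer_syntax <- gsub("[\\x00 ]+$", "", rawToChar(value))
    if (key == "7fe0,0010") break
    if (off >= length(b)) break
    # after the meta group, switch VR mode per transfer syntax
    nxt_group <- if (off + 2L <= length(b)) read_u16(b, off) else NA_integer_
    if (!is.na(nxt_group) && nxt_group != 0x0002)
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
  }
  get_us <- function(key, default = NULL) {
    t <- tags[[key]]
    if (is.null(t)) return(default)
    read_u16(t$value, 0L)
  }
  get_str <- function(key, default = "") {
    t <- tags[[key]]
    if (is.null(t)) return(default)
    trimws(rawToChar(t$value))
  }
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("DICOM missing Rows/Columns: ", path)
  bits <- get_us("0028,0100", 16L)
  pixrep <- get_us("0028,0103", 0L)
  photometric <- get_str("0028,0004", "MONOCHROME2")
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2"))
    stop("unsupported photometric interpretation '", photometric, "': ", path)
  slope <- as.numeric(get_str("0028,1053", "1"))
  intercept <- as.numeric(get_str("0028,1052", "0"))
  pd <- tags[["7fe0,0010"]]
  if (is.null(pd)) stop("DICOM missing PixelData: ", path)
  n <- rows * cols
  v <- if (bits == 16L)
    readBin(pd$value, "integer", n, size = 2L, endian = "little",
            signed = pixrep == 1L)
  else as.integer(pd$value[seq_len(n)])
  hu <- slope * as.numeric(v) + intercept
  if (photometric == "MONOCHROME1") hu <- max(hu) + min(hu) - hu
  px <- matrix(hu, nrow = rows, ncol = cols, byrow = TRUE)
  ct_image(px, domain_tag = domain_tag, background_value = background_value,
           source_id = source_id)
}
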