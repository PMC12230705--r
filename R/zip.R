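# Minimal deterministic ZIP writer (stored entries, fixed timestamps) and
# a reader wrapper around utils::unzip. A hand-written writer is what the
# archive byte-determinism contract needs: member order, timestamps and
# compression settings are all pinned.

.crc32_table <- local({
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(poly, bitwShiftR(c, 1L))
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1L] <- c
  }
  tab
})

# CRC-32 (IEEE 802.3) of a raw vector, returned as a double in [0, 2^32)
crc32 <- function(bytes) {
  crc <- -1L
  tab <- .crc32_table
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 4294967296 else as.double(crc)
}

u16_raw <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

u32_raw <- function(x) {
  lo <- x %% 65536
  hi <- x %/% 65536
  c(u16_raw(lo), u16_raw(hi))
}

# build a ZIP archive from named raw vectors, members in the given order;
# stored (no compression), DOS timestamp fixed at 1980-01-01 00:00:00
zip_build <- function(files) {
  stopifnot(is.list(files), length(files) > 0L, !is.null(names(files)))
  dos_time <- u16_raw(0L)
  dos_date <- u16_raw(33L)  # 1980-01-01
  locals <- list()
  centrals <- list()
  offset <- 0
  for (i in seq_along(files)) {
    name <- names(files)[i]
    data <- files[[i]]
    if (is.character(data)) data <- charToRaw(paste(data, collapse = "\n"))
    stopifnot(is.raw(data))
    nm <- charToRaw(name)
    crc <- crc32(data)
    n <- length(data)
    common <- c(u16_raw(20L),        # version needed
                u16_raw(0L),         # flags
                u16_raw(0L),         # method: stored
                dos_time, dos_date,
                u32_raw(crc), u32_raw(n), u32_raw(n),
                u16_raw(length(nm)), u16_raw(0L))  # name len, extra len
    local <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), common, nm, data)
    central <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16_raw(20L), common,
                 u16_raw(0L),  # comment len
                 u16_raw(0L),  # disk number
                 u16_raw(0L),  # internal attrs
                 u32_raw(0),   # external attrs
                 u32_raw(offset), nm)
    locals[[i]] <- local
    centrals[[i]] <- central
    offset <- offset + length(local)
  }
  cd <- unlist(centrals)
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            u16_raw(0L), u16_raw(0L),
            u16_raw(length(files)), u16_raw(length(files)),
            u32_raw(length(cd)), u32_raw(offset),
            u16_raw(0L))
  c(unlist(locals), cd, eocd)
}

# member-name safety: forward slashes only, no traversal, no absolute paths
check_member_path <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("empty archive member path", call. = FALSE)
  }
  if (grepl("\\\\", name)) {
    stop("archive member path must use forward slashes: ", name,
         call. = FALSE)
  }
  if (startsWith(name, "/") || grepl("^[A-Za-z]:", name)) {
    stop("absolute archive member path rejected: ", name, call. = FALSE)
  }
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  if (any(parts == "..")) {
    stop("archive member path escapes the archive root: ", name,
         call. = FALSE)
  }
  invisible(name)
}

# extract all members of a ZIP (raw vector) to named raw vectors
zip_extract <- function(bytes) {
  stopifnot(is.raw(bytes))
  zf <- tempfile(fileext = ".zip")
  on.exit(unlink(zf), add = TRUE)
  writeBin(bytes, zf)
  listing <- tryCatch(utils::unzip(zf, list = TRUE),
                      error = function(e) stop("not a readable ZIP archive: ",
                                               conditionMessage(e),
                                               call. = FALSE))
  names_ <- listing$Name
  for (nm in names_) check_member_path(nm)
  exdir <- tempfile("mvsx")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(zf, exdir = exdir)
  out <- list()
  for (nm in names_) {
    if (endsWith(nm, "/")) next  # directory entry
    f <- file.path(exdir, nm)
    out[[nm]] <- readBin(f, "raw", n = file.size(f))
  }
  out
}
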