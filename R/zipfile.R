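## A tiny ZIP writer producing canonical archives: stored (uncompressed)
## entries, fixed 1980-01-01 timestamps, entries sorted by name. Reading
## uses R's built-in unzip. Canonical output makes manifest round-trip
## tests byte-exact.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
          else bitwShiftR(bitwAnd(c, -2L), 1)
        }
        t[i + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(tab[idx + 1], bitwShiftR(bitwAnd(c, -256L), 8))
  }
  bitwXor(c, -1L)
}

u16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
u32 <- function(v) {
  v <- as.numeric(v)
  writeBin(as.integer(ifelse(v >= 2^31, v - 2^32, v)), raw(), size = 4,
           endian = "little")
}

#' Write a canonical ZIP archive
#'
#' @param files named list: entry name -> raw vector (or character, taken
#'   as UTF-8 text)
#' @param path output .zip path
#' @return `path`, invisibly
#' @export
zip_write <- function(files, path) {
  nm <- sort(names(files))
  locals <- raw(); centrals <- raw(); offset <- 0
  for (f in nm) {
    data <- files[[f]]
    if (is.character(data)) data <- charToRaw(enc2utf8(paste(data, collapse = "\n")))
    name <- charToRaw(enc2utf8(f))
    crc <- crc32(data)
    lh <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16(20), u16(0), u16(0),
            u16(0), u16(0x21), u32(crc), u32(length(data)),
            u32(length(data)), u16(length(name)), u16(0), name, data)
    ch <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20), u16(20), u16(0),
            u16(0), u16(0), u16(0x21), u32(crc), u32(length(data)),
            u32(length(data)), u16(length(name)), u16(0), u16(0), u16(0),
            u16(0), u32(0), u32(offset), name)
    locals <- c(locals, lh)
    centrals <- c(centrals, ch)
    offset <- offset + length(lh)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0), u16(0),
            u16(length(nm)), u16(length(nm)), u32(length(centrals)),
            u32(length(locals)), u16(0))
  writeBin(c(locals, centrals, eocd), path)
  invisible(path)
}

#' Read all entries of a ZIP archive
#'
#' @param path .zip file
#' @return named list: entry name -> raw vector
#' @export
zip_read <- function(path) {
  if (!file.exists(path)) stop("no such archive: '", path, "'")
  exdir <- tempfile("zipread")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  entries <- utils::unzip(path, exdir = exdir)
  if (length(entries) == 0) stop("'", path, "' is empty or not a ZIP archive")
  rel <- substring(entries, nchar(exdir) + 2)
  out <- lapply(entries, function(p) readBin(p, "raw", file.size(p)))
  names(out) <- rel
  out
}
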