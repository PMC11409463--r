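## Minimal msgpack codec — the subset the BinaryCIF container uses: nil,
## booleans, integers, float64, strings, raw binaries, arrays and maps.
## No installed R package provides msgpack, and the format is small
## enough to state exactly; everything here round-trips through the
## reference Python implementation used as a test oracle.

mp_uint <- function(v, size) {
  writeBin(as.integer(v), raw(), size = size, endian = "big")
}

mp_pack_one <- function(x) {
  if (is.null(x)) return(as.raw(0xc0))
  if (is.logical(x) && length(x) == 1)
    return(as.raw(if (isTRUE(x)) 0xc3 else 0xc2))
  if (is.raw(x)) {
    n <- length(x)
    hdr <- if (n < 256) c(as.raw(0xc4), mp_uint(n, 1))
           else if (n < 65536) c(as.raw(0xc5), mp_uint(n, 2))
           else c(as.raw(0xc6), mp_uint(n, 4))
    return(c(hdr, x))
  }
  if (is.character(x) && length(x) == 1) {
    b <- charToRaw(enc2utf8(x))
    n <- length(b)
    hdr <- if (n < 32) as.raw(bitwOr(0xa0L, n))
           else if (n < 256) c(as.raw(0xd9), mp_uint(n, 1))
           else if (n < 65536) c(as.raw(0xda), mp_uint(n, 2))
           else c(as.raw(0xdb), mp_uint(n, 4))
    return(c(hdr, b))
  }
  if (is.numeric(x) && length(x) == 1) {
    if (is.integer(x) || (is.finite(x) && x == trunc(x) && abs(x) < 2^31)) {
      v <- as.integer(x)
      if (v >= 0 && v < 128) return(as.raw(v))
      if (v < 0 && v >= -32) return(as.raw(256 + v))
      if (v >= 0 && v < 256) return(c(as.raw(0xcc), mp_uint(v, 1)))
      if (v >= 0 && v < 65536) return(c(as.raw(0xcd), mp_uint(v, 2)))
      if (v >= -128 && v < 128) return(c(as.raw(0xd0), writeBin(v, raw(), size = 1, endian = "big")))
      if (v >= -32768 && v < 32768) return(c(as.raw(0xd1), writeBin(v, raw(), size = 2, endian = "big")))
      return(c(as.raw(0xd2), writeBin(v, raw(), size = 4, endian = "big")))
    }
    return(c(as.raw(0xcb), writeBin(as.numeric(x), raw(), size = 8, endian = "big")))
  }
  if (is.list(x)) {
    nms <- names(x)
    body <- do.call(c, c(list(raw()), unlist(lapply(seq_along(x), function(i) {
      if (is.null(nms)) list(mp_pack_one(x[[i]]))
      else list(mp_pack_one(nms[i]), mp_pack_one(x[[i]]))
    }), recursive = FALSE)))
    n <- length(x)
    hdr <- if (is.null(nms)) {
      if (n < 16) as.raw(bitwOr(0x90L, n))
      else if (n < 65536) c(as.raw(0xdc), mp_uint(n, 2))
      else c(as.raw(0xdd), mp_uint(n, 4))
    } else {
      if (n < 16) as.raw(bitwOr(0x80L, n))
      else if (n < 65536) c(as.raw(0xde), mp_uint(n, 2))
      else c(as.raw(0xdf), mp_uint(n, 4))
    }
    return(c(hdr, body))
  }
  stop("msgpack: cannot encode object of class ", paste(class(x), collapse = "/"))
}

#' Encode an R object as msgpack bytes
#'
#' Unnamed lists become arrays, named lists become maps (keys in list
#' order), raw vectors become bin, length-1 character/numeric/logical
#' become scalars.
#' @param x object
#' @return raw vector
#' @export
msgpack_pack <- function(x) mp_pack_one(x)

mp_read_uint <- function(raw, pos, size) {
  v <- 0
  for (i in seq_len(size)) v <- v * 256 + as.integer(raw[pos + i - 1])
  v
}

mp_unpack_one <- function(raw, pos) {
  b <- as.integer(raw[pos])
  if (b < 0x80) return(list(value = b, pos = pos + 1))
  if (b >= 0xe0) return(list(value = b - 256L, pos = pos + 1))
  if (b >= 0xa0 && b < 0xc0) {                 # fixstr
    n <- b - 0xa0L
    s <- rawToChar(raw[seq_len(n) + pos])
    Encoding(s) <- "UTF-8"
    return(list(value = s, pos = pos + 1 + n))
  }
  if (b >= 0x90 && b < 0xa0) return(mp_read_seq(raw, pos + 1, b - 0x90L, FALSE))
  if (b >= 0x80 && b < 0x90) return(mp_read_seq(raw, pos + 1, b - 0x80L, TRUE))
  switch(sprintf("%02x", b),
    "c0" = list(value = NULL, pos = pos + 1),
    "c2" = list(value = FALSE, pos = pos + 1),
    "c3" = list(value = TRUE, pos = pos + 1),
    "c4" = { n <- mp_read_uint(raw, pos + 1, 1)
             list(value = raw[seq_len(n) + pos + 1], pos = pos + 2 + n) },
    "c5" = { n <- mp_read_uint(raw, pos + 1, 2)
             list(value = raw[seq_len(n) + pos + 2], pos = pos + 3 + n) },
    "c6" = { n <- mp_read_uint(raw, pos + 1, 4)
             list(value = raw[seq_len(n) + pos + 4], pos = pos + 5 + n) },
    "ca" = list(value = readBin(raw[pos + 1:4], "double", size = 4, endian = "big"),
                pos = pos + 5),
    "cb" = list(value = readBin(raw[pos + 1:8], "double", size = 8, endian = "big"),
                pos = pos + 9),
    "cc" = list(value = mp_read_uint(raw, pos + 1, 1), pos = pos + 2),
    "cd" = list(value = mp_read_uint(raw, pos + 1, 2), pos = pos + 3),
    "ce" = list(value = mp_read_uint(raw, pos + 1, 4), pos = pos + 5),
    "d0" = list(value = readBin(raw[pos + 1], "integer", size = 1, signed = TRUE),
                pos = pos + 2),
    "d1" = list(value = readBin(raw[pos + 1:2], "integer", size = 2,
                                signed = TRUE, endian = "big"), pos = pos + 3),
    "d2" = list(value = readBin(raw[pos + 1:4], "integer", size = 4,
                                endian = "big"), pos = pos + 5),
    "d9" = { n <- mp_read_uint(raw, pos + 1, 1)
             s <- rawToChar(raw[seq_len(n) + pos + 1]); Encoding(s) <- "UTF-8"
             list(value = s, pos = pos + 2 + n) },
    "da" = { n <- mp_read_uint(raw, pos + 1, 2)
             s <- rawToChar(raw[seq_len(n) + pos + 2]); Encoding(s) <- "UTF-8"
             list(value = s, pos = pos + 3 + n) },
    "db" = { n <- mp_read_uint(raw, pos + 1, 4)
             s <- rawToChar(raw[seq_len(n) + pos + 4]); Encoding(s) <- "UTF-8"
             list(value = s, pos = pos + 5 + n) },
    "dc" = mp_read_seq(raw, pos + 3, mp_read_uint(raw, pos + 1, 2), FALSE),
    "dd" = mp_read_seq(raw, pos + 5, mp_read_uint(raw, pos + 1, 4), FALSE),
    "de" = mp_read_seq(raw, pos + 3, mp_read_uint(raw, pos + 1, 2), TRUE),
    "df" = mp_read_seq(raw, pos + 5, mp_read_uint(raw, pos + 1, 4), TRUE),
    stop(sprintf("msgpack: unsupported type byte 0x%02x", b)))
}

mp_read_seq <- function(raw, pos, n, is_map) {
  out <- vector("list", n)
  keys <- if (is_map) character(n)
  for (i in seq_len(n)) {
    if (is_map) {
      k <- mp_unpack_one(raw, pos); pos <- k$pos
      keys[i] <- as.character(k$value)
    }
    v <- mp_unpack_one(raw, pos); pos <- v$pos
    out[i] <- list(v$value)      # keeps NULL values as elements
  }
  if (is_map) names(out) <- keys
  list(value = out, pos = pos)
}

#' Decode msgpack bytes into R objects
#' @param raw raw vector produced by a msgpack encoder
#' @return decoded object (maps become named lists)
#' @export
msgpack_unpack <- function(raw) {
  res <- mp_unpack_one(raw, 1)
  if (res$pos != length(raw) + 1)
    warning("msgpack: ", length(raw) + 1 - res$pos, " trailing bytes ignored")
  res$value
}
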