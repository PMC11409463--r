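## BinaryCIF: mmCIF categories serialized as msgpack with per-column
## encoding chains. Seven standard encodings are supported — ByteArray,
## FixedPoint, IntervalQuantization, RunLength, Delta, IntegerPacking,
## StringArray — with a matching encoder used by the manifest writer and
## the test fixtures. Chains are listed in ENCODING order; decoding
## applies them in reverse starting from the raw bytes. Anything else is
## rejected loudly.

## ByteArray type codes (BinaryCIF convention)
BA_INT8 <- 1L; BA_INT16 <- 2L; BA_INT32 <- 3L
BA_UINT8 <- 4L; BA_UINT16 <- 5L; BA_UINT32 <- 6L
BA_FLOAT32 <- 32L; BA_FLOAT64 <- 33L

ba_bytes <- function(type) switch(as.character(type),
  "1" = 1L, "2" = 2L, "3" = 4L, "4" = 1L, "5" = 2L, "6" = 4L,
  "32" = 4L, "33" = 8L,
  stop("ByteArray: unknown type code ", type))

byte_array_decode <- function(bytes, type) {
  n <- length(bytes) / ba_bytes(type)
  switch(as.character(type),
    "1" = readBin(bytes, "integer", n, size = 1, signed = TRUE),
    "2" = readBin(bytes, "integer", n, size = 2, signed = TRUE,
                  endian = "little"),
    "3" = readBin(bytes, "integer", n, size = 4, endian = "little"),
    "4" = readBin(bytes, "integer", n, size = 1, signed = FALSE),
    "5" = readBin(bytes, "integer", n, size = 2, signed = FALSE,
                  endian = "little"),
    "6" = { v <- readBin(bytes, "integer", n, size = 4, endian = "little")
            ifelse(v < 0, v + 2^32, as.numeric(v)) },
    "32" = readBin(bytes, "double", n, size = 4, endian = "little"),
    "33" = readBin(bytes, "double", n, size = 8, endian = "little"))
}

byte_array_encode <- function(values, type) {
  switch(as.character(type),
    "1" = , "2" = , "3" = , "4" = , "5" =
      writeBin(as.integer(values), raw(), size = ba_bytes(type),
               endian = "little"),
    "6" = { v <- as.numeric(values)
            writeBin(as.integer(ifelse(v >= 2^31, v - 2^32, v)), raw(),
                     size = 4, endian = "little") },
    "32" = writeBin(as.numeric(values), raw(), size = 4, endian = "little"),
    "33" = writeBin(as.numeric(values), raw(), size = 8, endian = "little"))
}

integer_packing_decode <- function(packed, enc) {
  bc <- enc$byteCount; uns <- isTRUE(enc$isUnsigned)
  upper <- if (uns) 2^(8 * bc) - 1 else 2^(8 * bc - 1) - 1
  lower <- if (uns) 0 else -2^(8 * bc - 1)
  out <- numeric(enc$srcSize); j <- 0; i <- 1; n <- length(packed)
  while (i <= n) {
    v <- 0
    while (i <= n && (packed[i] == upper || (!uns && packed[i] == lower))) {
      v <- v + packed[i]; i <- i + 1
    }
    if (i <= n) { v <- v + packed[i]; i <- i + 1 }
    j <- j + 1; out[j] <- v
  }
  if (j != enc$srcSize)
    stop("IntegerPacking: decoded ", j, " values, expected ", enc$srcSize)
  out
}

integer_packing_encode <- function(values, byteCount, isUnsigned) {
  upper <- if (isUnsigned) 2^(8 * byteCount) - 1 else 2^(8 * byteCount - 1) - 1
  lower <- if (isUnsigned) 0 else -2^(8 * byteCount - 1)
  out <- numeric(0)
  for (v in values) {
    if (v >= 0) {
      while (v >= upper) { out <- c(out, upper); v <- v - upper }
    } else {
      if (isUnsigned) stop("IntegerPacking: negative value in unsigned packing")
      while (v <= lower) { out <- c(out, lower); v <- v - lower }
    }
    out <- c(out, v)
  }
  out
}

run_length_decode <- function(x, enc) {
  v <- x[seq(1, length(x), by = 2)]
  k <- x[seq(2, length(x), by = 2)]
  rep(v, k)
}

run_length_encode <- function(values) {
  r <- rle(values)
  as.numeric(rbind(r$values, r$lengths))
}

#' Decode one BinaryCIF column
#'
#' Applies the column's encoding chain in reverse, starting from the raw
#' bytes.
#' @param data raw vector (the encoded bytes)
#' @param encodings list of encoding descriptor maps, encoding order
#' @return numeric or character vector
#' @export
bcif_decode_column <- function(data, encodings) {
  x <- data
  for (enc in rev(encodings)) {
    x <- switch(enc$kind,
      ByteArray = byte_array_decode(x, enc$type),
      FixedPoint = x / enc$factor,
      IntervalQuantization =
        enc$min + x * (enc$max - enc$min) / (enc$numSteps - 1),
      RunLength = run_length_decode(x, enc),
      Delta = { v <- cumsum(x); v + enc$origin },
      IntegerPacking = integer_packing_decode(x, enc),
      StringArray = {
        offsets <- bcif_decode_column(enc$offsets, enc$offsetEncoding)
        idx <- bcif_decode_column(x, enc$dataEncoding)
        strs <- substring(enc$stringData, offsets[-length(offsets)] + 1,
                          offsets[-1])
        out <- rep(NA_character_, length(idx))
        ok <- idx >= 0
        out[ok] <- strs[idx[ok] + 1]
        out
      },
      stop("unsupported BinaryCIF encoding kind '", enc$kind, "'"))
  }
  x
}

#' Encode one BinaryCIF column
#'
#' @param values numeric or character vector
#' @param chain character vector naming the transform chain, e.g.
#'   `c("FixedPoint", "Delta", "IntegerPacking")`; character input always
#'   uses `"StringArray"`. A terminal `"ByteArray"` is appended
#'   automatically when the chain does not already end in bytes.
#' @param factor fixed-point factor (for `"FixedPoint"`)
#' @param byteCount integer packing width (1 or 2)
#' @return list with `data` (raw) and `encoding` (list), the column form
#'   stored in a BinaryCIF file
#' @export
bcif_encode_column <- function(values, chain = NULL, factor = 1000,
                               byteCount = 2L) {
  if (is.character(values)) {
    uniq <- unique(values)
    idx <- match(values, uniq) - 1
    sd <- paste(uniq, collapse = "")
    offsets <- c(0, cumsum(nchar(uniq, type = "chars")))
    idx_col <- bcif_encode_column(idx, chain = c("Delta", "IntegerPacking"))
    off_col <- bcif_encode_column(offsets, chain = c("Delta", "IntegerPacking"))
    return(list(data = idx_col$data, encoding = list(list(
      kind = "StringArray", dataEncoding = idx_col$encoding,
      stringData = sd, offsetEncoding = off_col$encoding,
      offsets = off_col$data))))
  }
  if (is.null(chain)) {
    chain <- if (is.integer(values) || all(values == trunc(values)))
      c("Delta", "IntegerPacking") else "FixedPoint-Delta-IntegerPacking"
    chain <- unlist(strsplit(chain, "-", fixed = TRUE))
  }
  x <- as.numeric(values)
  encoding <- list()
  for (kind in chain) {
    if (kind == "FixedPoint") {
      encoding <- c(encoding, list(list(kind = "FixedPoint", factor = factor,
                                        srcType = BA_FLOAT64)))
      x <- round(x * factor)
    } else if (kind == "Delta") {
      origin <- if (length(x)) x[1] else 0
      d <- if (length(x)) c(0, diff(x)) else numeric(0)
      encoding <- c(encoding, list(list(kind = "Delta", origin = origin,
                                        srcType = BA_INT32)))
      x <- d
      if (length(x)) x[1] <- 0   # origin carries the first value
    } else if (kind == "IntegerPacking") {
      encoding <- c(encoding, list(list(kind = "IntegerPacking",
                                        byteCount = as.integer(byteCount),
                                        isUnsigned = FALSE,
                                        srcSize = length(x))))
      x <- integer_packing_encode(x, byteCount, FALSE)
    } else if (kind == "RunLength") {
      encoding <- c(encoding, list(list(kind = "RunLength",
                                        srcType = BA_INT32,
                                        srcSize = length(x))))
      x <- run_length_encode(x)
    } else if (kind == "IntervalQuantization") {
      mn <- min(x); mx <- max(x); steps <- 255
      encoding <- c(encoding, list(list(kind = "IntervalQuantization",
                                        min = mn, max = mx,
                                        numSteps = steps,
                                        srcType = BA_UINT8)))
      x <- if (mx > mn) round((x - mn) * (steps - 1) / (mx - mn)) else 0 * x
    } else if (kind == "ByteArray") {
      ## terminal, handled below
    } else stop("unsupported BinaryCIF encoding kind '", kind, "'")
  }
  ## terminal byte conversion
  type <- if (all(x == trunc(x))) {
    last <- if (length(encoding)) encoding[[length(encoding)]]
            else list(kind = "none")
    if (last$kind == "IntegerPacking") {
      if (last$byteCount == 1) BA_INT8 else BA_INT16
    } else if (max(abs(x), 0) < 128) BA_INT8
    else if (max(abs(x), 0) < 32768) BA_INT16 else BA_INT32
  } else BA_FLOAT64
  encoding <- c(encoding, list(list(kind = "ByteArray", type = type)))
  list(data = byte_array_encode(x, type), encoding = encoding)
}

#' Write categories to a BinaryCIF file
#'
#' @param categories named list: category name -> named list of columns
#'   (numeric or character vectors, equal length)
#' @param path output file
#' @param header data block header text
#' @return `path`, invisibly
#' @export
write_bcif <- function(categories, path, header = "mesoscene") {
  cat_list <- lapply(names(categories), function(nm) {
    cols <- categories[[nm]]
    rc <- if (length(cols)) length(cols[[1]]) else 0L
    list(name = paste0("_", nm), rowCount = rc,
         columns = lapply(names(cols), function(cn) {
           enc <- bcif_encode_column(cols[[cn]])
           list(name = cn, data = list(data = enc$data,
                                       encoding = enc$encoding),
                mask = NULL)
         }))
  })
  doc <- list(encoder = "mesoscene", version = "0.3.0",
              dataBlocks = list(list(header = header,
                                     categories = cat_list)))
  writeBin(msgpack_pack(doc), path)
  invisible(path)
}

#' Read a BinaryCIF file
#'
#' @param path BinaryCIF (msgpack) file
#' @return named list: category name (leading underscore stripped) ->
#'   named list of decoded column vectors
#' @export
read_bcif <- function(path) {
  doc <- msgpack_unpack(readBin(path, "raw", file.size(path)))
  if (is.null(doc$dataBlocks)) stop("'", path, "' is not a BinaryCIF file")
  out <- list()
  for (blk in doc$dataBlocks) {
    for (cat in blk$categories) {
      cols <- list()
      for (col in cat$columns) {
        cols[[col$name]] <- bcif_decode_column(col$data$data,
                                               col$data$encoding)
      }
      out[[sub("^_", "", cat$name)]] <- cols
    }
  }
  out
}
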