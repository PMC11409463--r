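## Minimal mmCIF reader/writer working at the category level: every
## category becomes a data frame of character columns, whether it came
## from a loop_ or from key-value pairs. This covers the standard
## assembly categories, the PetWorld pdbx_model extension and our entity
## description category. Not a full CIF grammar: one data block, simple
## quoting ('...', "...", multi-line ;-blocks), # comments.

cif_tokenize_line <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^\\s]+", line, perl = TRUE)
  toks <- regmatches(line, m)[[1]]
  ## drop from the first comment token on
  iscom <- startsWith(toks, "#")
  if (any(iscom)) toks <- toks[seq_len(which(iscom)[1] - 1)]
  ## strip quotes
  q <- (startsWith(toks, "'") & endsWith(toks, "'") & nchar(toks) >= 2) |
       (startsWith(toks, "\"") & endsWith(toks, "\"") & nchar(toks) >= 2)
  toks[q] <- substr(toks[q], 2, nchar(toks[q]) - 1)
  toks
}

## Full-file token stream; multi-line ;-delimited values become single
## tokens.
cif_tokenize <- function(lines) {
  toks <- list(); k <- 0
  i <- 1; n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (startsWith(ln, ";")) {
      buf <- substring(ln, 2)
      i <- i + 1
      while (i <= n && !startsWith(lines[i], ";")) {
        buf <- paste(buf, lines[i], sep = "\n")
        i <- i + 1
      }
      k <- k + 1; toks[[k]] <- buf
      i <- i + 1
      next
    }
    tl <- cif_tokenize_line(ln)
    if (length(tl)) { k <- k + 1; toks[[k]] <- tl }
    i <- i + 1
  }
  unlist(toks, use.names = FALSE)
}

#' Parse an mmCIF file into category tables
#'
#' @param path mmCIF file
#' @return named list: category name (without leading underscore) ->
#'   data frame of character columns named by item keyword
#' @export
cif_parse <- function(path) {
  toks <- cif_tokenize(readLines(path, warn = FALSE))
  cats <- list()
  i <- 1; n <- length(toks)
  is_kw <- function(t) grepl("^(data_|loop_$|_)", t)
  while (i <= n) {
    t <- toks[i]
    if (startsWith(t, "data_")) { i <- i + 1; next }
    if (t == "loop_") {
      i <- i + 1
      tags <- character()
      while (i <= n && startsWith(toks[i], "_")) {
        tags <- c(tags, toks[i]); i <- i + 1
      }
      vals <- character()
      while (i <= n && !is_kw(toks[i])) {
        vals <- c(vals, toks[i]); i <- i + 1
      }
      if (length(tags) == 0) next
      ncol <- length(tags)
      if (length(vals) %% ncol != 0)
        stop("malformed loop_ in '", path, "': ", length(vals),
             " values for ", ncol, " tags")
      mat <- matrix(vals, ncol = ncol, byrow = TRUE)
      parts <- strsplit(sub("^_", "", tags), ".", fixed = TRUE)
      cat_name <- parts[[1]][1]
      cols <- vapply(parts, function(p) paste(p[-1], collapse = "."), "")
      df <- as.data.frame(mat, stringsAsFactors = FALSE)
      names(df) <- cols
      cats[[cat_name]] <- if (is.null(cats[[cat_name]])) df
                          else rbind(cats[[cat_name]], df)
    } else if (startsWith(t, "_")) {
      ## key-value item
      if (i + 1 > n) stop("dangling item '", t, "' in '", path, "'")
      parts <- strsplit(sub("^_", "", t), ".", fixed = TRUE)[[1]]
      cat_name <- parts[1]; col <- paste(parts[-1], collapse = ".")
      val <- toks[i + 1]
      if (is.null(cats[[cat_name]]))
        cats[[cat_name]] <- data.frame(row.names = 1)
      cats[[cat_name]][[col]] <- val
      i <- i + 2
      next
    } else {
      stop("unexpected token '", t, "' in '", path, "'")
    }
  }
  cats
}

cif_quote <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "?"
  needs <- grepl("[\\s'\"#]", x, perl = TRUE) | x == ""
  multi <- grepl("\n", x, fixed = TRUE)
  x[needs & !multi] <- paste0("'", x[needs & !multi], "'")
  x[multi] <- paste0("\n;", x[multi], "\n;")
  x
}

#' Write category tables as an mmCIF file
#'
#' Every category is emitted as a loop_ (valid mmCIF even for one row).
#'
#' @param cats named list of data frames (character columns)
#' @param path output file
#' @param block data block name
#' @return `path`, invisibly
#' @export
cif_write <- function(cats, path, block = "mesoscene") {
  con <- file(path, "wb")            # LF endings everywhere
  on.exit(close(con))
  out <- c(sprintf("data_%s", block), "#")
  for (nm in names(cats)) {
    df <- cats[[nm]]
    out <- c(out, "loop_",
             sprintf("_%s.%s", nm, names(df)))
    rows <- do.call(paste, c(lapply(df, cif_quote), sep = " "))
    out <- c(out, rows, "#")
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}
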