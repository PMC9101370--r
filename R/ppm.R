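#' Read and write Portable Pixmap images
#'
#' Binary P6 pixmaps with maxval 255 are the thermal camera's snapshot
#' format; the reader also accepts the ASCII P3 dialect. Comments (`#`) and
#' arbitrary whitespace in the header are handled per the format definition.
#' `write_ppm` always emits binary P6; writing then reading is the identity.
#'
#' @param path file path.
#' @param img `H x W x 3` array of integer channel values 0..255.
#' @return `read_ppm` returns an `H x W x 3` integer array.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P6", "P3"))
    stop("not a PPM file (magic '", magic, "'): ", path)
  tokens <- ppm_header_tokens(con, 3)
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (is.na(w) || is.na(h) || w < 1 || h < 1)
    stop("malformed PPM header in ", path)
  if (is.na(maxval) || maxval != 255)
    stop("unsupported PPM maxval ", maxval, " (must be 255): ", path)
  n <- w * h * 3
  if (magic == "P6") {
    payload <- readBin(con, "raw", n)
    if (length(payload) < n) stop("truncated PPM payload in ", path)
    vals <- as.integer(payload)
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(vals) < n || anyNA(vals[seq_len(n)]))
      stop("truncated or malformed P3 payload in ", path)
    vals <- vals[seq_len(n)]
  }
  # PPM stores pixels row-major, channels interleaved
  a <- aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
  storage.mode(a) <- "integer"
  a
}

# read whitespace/comment-separated integer tokens after the magic
ppm_header_tokens <- function(con, n) {
  tokens <- integer(0)
  buf <- ""
  in_comment <- FALSE
  while (length(tokens) < n) {
    ch <- readBin(con, "raw", 1)
    if (length(ch) == 0) stop("unexpected end of PPM header")
    c <- rawToChar(ch)
    if (in_comment) {
      if (c == "\n") in_comment <- FALSE
      next
    }
    if (c == "#") { in_comment <- TRUE; next }
    if (grepl("[0-9]", c)) {
      buf <- paste0(buf, c)
    } else if (nzchar(buf)) {
      tokens <- c(tokens, as.integer(buf))
      buf <- ""
      # single whitespace after maxval terminates the header
    }
  }
  tokens
}

#' @rdname read_ppm
#' @export
write_ppm <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3,
            all(img >= 0 & img <= 255))
  h <- dim(img)[1]; w <- dim(img)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P6\n%d %d\n255\n", w, h)), con)
  interleaved <- aperm(img, c(3, 2, 1))  # channel fastest, then col, then row
  writeBin(as.raw(as.integer(interleaved)), con)
  invisible(path)
}
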