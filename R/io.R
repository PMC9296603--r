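#' Read a grayscale image
#'
#' Reads PNG/TIFF (via EBImage) or PGM (P2/P5, parsed directly).  Color
#' images are converted to luminance with weights 0.299/0.587/0.114.
#' Values are rescaled to \[0, 1] (8/16-bit integer formats divided by
#' their maximum).
#'
#' @param path file path; extension selects the reader.
#' @return numeric matrix (rows x cols) in \[0, 1].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pgm", "ppm")) return(read_pgm(path))
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    a <- if (nch >= 3) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a[, , 1]
    }
  }
  # EBImage stores x (columns) in the first dimension
  m <- t(a)
  if (max(m) > 1) m <- m / max(m)
  m
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  vals <- integer(0)
  # header tokens: width height maxval (comments stripped)
  tokens <- integer(0)
  buf <- character(0)
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1L)
      if (length(ch) == 0 || ch == "") stop("truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L)
          if (ch %in% c("\n", "\r")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(buf)) break else next
      }
      buf <<- c(buf, ch)
    }
    tok <- paste(buf, collapse = "")
    buf <<- character(0)
    tok
  }
  w <- as.integer(read_token()); h <- as.integer(read_token())
  mx <- as.integer(read_token())
  n <- w * h
  if (magic == "P5") {
    raw_sz <- if (mx > 255) 2L else 1L
    vals <- readBin(con, "integer", n = n, size = raw_sz, signed = FALSE,
                    endian = "big")
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  matrix(vals / mx, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a binary edge map
#'
#' PGM (P2, plain text) or PNG depending on the file extension.
#'
#' @param map logical/0-1 matrix, or a [canny_cep()] candidate set.
#' @param path output path (`.pgm` or `.png`).
#' @export
write_edge_map <- function(map, path) {
  if (inherits(map, "cep_set")) map <- cep_to_map(map)
  m <- (map != 0) * 1L
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), "1"), con)
    write.table(m, con, row.names = FALSE, col.names = FALSE)
  } else {
    EBImage::writeImage(EBImage::Image(t(m)), path)
  }
  invisible(path)
}

#' Read a binary edge map
#'
#' @param path `.pgm` or `.png` file; any nonzero pixel is an edge.
#' @return logical matrix.
#' @export
read_edge_map <- function(path) read_gray_image(path) > 0
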