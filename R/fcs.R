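#' Write an FCS 3.1 event file
#'
#' Minimal FCS 3.1 codec for cytometry event matrices: a single dataset,
#' list-mode, 32-bit little-endian floats. This covers the subset of the
#' standard needed to exchange per-well event tables with other cytometry
#' software; no analysis segment or supplemental text is written.
#'
#' @param events numeric matrix or data.frame of events (rows) by channels
#'   (columns); all values must be finite.
#' @param path output file path.
#' @param channels channel (parameter) names, defaulting to the column names
#'   of `events`.
#' @return `path`, invisibly.
#' @seealso [read_fcs()]
#' @export
write_fcs <- function(events, path, channels = colnames(events)) {
  m <- as.matrix(events)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("events must be finite to write FCS")
  if (is.null(channels)) channels <- paste0("P", seq_len(ncol(m)))
  if (length(channels) != ncol(m)) stop("one channel name per column required")
  if (any(grepl("/", channels, fixed = TRUE)))
    stop("channel names must not contain the delimiter '/'")

  n <- nrow(m)
  p <- ncol(m)
  data_len <- 4L * n * p

  text_start <- 256L
  kv <- c(
    "$BEGINDATA", "%BEGIN%", "$ENDDATA", "%END%",
    "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
    "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n)
  )
  for (j in seq_len(p)) {
    kv <- c(kv,
      sprintf("$P%dN", j), channels[j],
      sprintf("$P%dB", j), "32",
      sprintf("$P%dE", j), "0,0",
      sprintf("$P%dR", j), format(ceiling(max(m[, j], 1)), scientific = FALSE))
  }
  # fixed-width offsets keep the TEXT length independent of their value
  template <- paste0("/", paste(kv, collapse = "/"), "/")
  text_len <- nchar(sub("%BEGIN%", "00000000",
                        sub("%END%", "00000000", template, fixed = TRUE),
                        fixed = TRUE))
  text_end <- text_start + text_len - 1L
  data_start <- text_end + 1L
  data_end <- data_start + data_len - 1L
  text <- sub("%BEGIN%", sprintf("%08d", data_start),
              sub("%END%", sprintf("%08d", data_end), template, fixed = TRUE),
              fixed = TRUE)
  stopifnot(nchar(text) == text_len)

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(raw(text_start - nchar(header)), con)
  writeBin(charToRaw(text), con)
  # list mode: parameters vary fastest within each event
  writeBin(as.vector(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS 3.x event file
#'
#' Reads single-dataset list-mode FCS files with float (`$DATATYPE F`) data,
#' as written by [write_fcs()] and by common acquisition software. Values are
#' returned at 32-bit float precision.
#'
#' @param path FCS file path.
#' @return numeric matrix of events by channels, with channel names taken
#'   from the `$PnN` keywords.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  header <- rawToChar(raw[1:58])
  if (!startsWith(header, "FCS3")) stop("not an FCS 3.x file: ", path)
  off <- function(i) {
    s <- substr(header, 11 + 8 * (i - 1), 10 + 8 * i)
    as.integer(trimws(s))
  }
  text_start <- off(1); text_end <- off(2)
  text <- rawToChar(raw[(text_start + 1L):(text_end + 1L)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L != 0L) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  vals <- trimws(parts[seq(2, length(parts), 2)])
  kw <- setNames(vals, keys)

  if (!identical(kw[["$DATATYPE"]], "F"))
    stop("unsupported $DATATYPE (only 'F' is supported): ", kw[["$DATATYPE"]])
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  p <- as.integer(kw[["$PAR"]])
  n <- as.integer(kw[["$TOT"]])
  data_start <- as.integer(kw[["$BEGINDATA"]] %||% off(3))
  values <- readBin(raw[(data_start + 1L):length(raw)], what = "numeric",
                    n = n * p, size = 4L, endian = endian)
  m <- matrix(values, nrow = n, ncol = p, byrow = TRUE)
  colnames(m) <- vapply(seq_len(p),
                        function(j) kw[[sprintf("$P%dN", j)]] %||% paste0("P", j),
                        character(1))
  m
}
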