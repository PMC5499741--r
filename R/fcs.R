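# Minimal FCS3.0 support: single dataset, list mode, 32-bit little-endian
# floats, $PnR annotated at 2^18 (the acquisition resolution of the
# cytometer exports this package emulates). Covers exactly what the
# package's own pipeline needs; it is not a general-purpose FCS library.

FCS_RANGE <- 2^18

# iteratively lay out HEADER + TEXT so that the $BEGINDATA/$ENDDATA values
# quoted inside TEXT agree with the actual byte offsets
fcs3_text <- function(keys) {
  delim <- "/"
  paste0(delim, paste0(names(keys), delim, unlist(keys), delim,
                       collapse = ""))
}

write_fcs3 <- function(events, path, clip = FALSE) {
  stopifnot(is.data.frame(events))
  m <- as.matrix(events)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite event values", call. = FALSE)
  if (any(m >= FCS_RANGE)) {
    if (!clip)
      stop("channel value >= 2^18 exceeds the FCS3.0 parameter range; ",
           "use clip = TRUE to clip", call. = FALSE)
    m[m >= FCS_RANGE] <- FCS_RANGE - 1
  }
  n_par <- ncol(m)
  n_tot <- nrow(m)
  data_len <- 4L * n_par * n_tot

  keys <- c(
    list("$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
         "$PAR" = n_par, "$TOT" = n_tot, "$NEXTDATA" = 0,
         "$BEGINANALYSIS" = 0, "$ENDANALYSIS" = 0,
         "$BEGINSTEXT" = 0, "$ENDSTEXT" = 0),
    stats::setNames(as.list(colnames(m)), sprintf("$P%dN", seq_len(n_par))),
    stats::setNames(as.list(rep(32, n_par)), sprintf("$P%dB", seq_len(n_par))),
    stats::setNames(as.list(rep("0,0", n_par)), sprintf("$P%dE", seq_len(n_par))),
    stats::setNames(as.list(rep(FCS_RANGE, n_par)), sprintf("$P%dR", seq_len(n_par)))
  )

  text_start <- 58L
  begin_data <- 0L
  for (i in 1:3) {  # converges once offset digit counts stabilise
    k <- c(keys, list("$BEGINDATA" = begin_data,
                      "$ENDDATA" = begin_data + data_len - 1L))
    txt <- fcs3_text(k)
    new_begin <- text_start + nchar(txt, type = "bytes")
    if (new_begin == begin_data) break
    begin_data <- new_begin
  }
  text_end <- begin_data - 1L
  data_end <- begin_data + data_len - 1L

  off <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.0    ", off(text_start), off(text_end),
                   if (data_end <= 99999999) off(begin_data) else off(0),
                   if (data_end <= 99999999) off(data_end) else off(0),
                   off(0), off(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.vector(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

read_fcs3 <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.0")
    stop("not an FCS3.0 file: ", path, call. = FALSE)
  offs <- as.integer(trimws(substring(header,
                                      seq(11, by = 8, length.out = 6),
                                      seq(18, by = 8, length.out = 6))))
  text_start <- offs[1]; text_end <- offs[2]
  seek(con, text_start)
  txt <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- stats::setNames(parts[seq(2, length(parts), 2)],
                          parts[seq(1, length(parts), 2)])

  if (toupper(keys[["$DATATYPE"]]) != "F")
    stop("unsupported $DATATYPE (only F is handled)", call. = FALSE)
  endian <- if (identical(keys[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  n_par <- as.integer(keys[["$PAR"]])
  n_tot <- as.integer(keys[["$TOT"]])
  begin_data <- as.integer(keys[["$BEGINDATA"]])
  if (is.na(begin_data) || begin_data == 0) begin_data <- offs[3]
  if (begin_data <= 0 || begin_data >= sz)
    stop("cannot locate the FCS DATA segment", call. = FALSE)
  seek(con, begin_data)
  vals <- readBin(con, "numeric", n = n_par * n_tot, size = 4,
                  endian = endian)
  m <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(m) <- vapply(seq_len(n_par), function(j) {
    nm <- keys[[sprintf("$P%dN", j)]]
    if (is.null(nm) || !nzchar(nm)) sprintf("P%d", j) else nm
  }, character(1))
  as.data.frame(m)
}
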