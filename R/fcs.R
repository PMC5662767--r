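#' Write an event table as an FCS 3.0 file
#'
#' Minimal, standards-conforming FCS 3.0 writer: list-mode (`$MODE L`),
#' single-precision float data (`$DATATYPE F`, `$PnB 32`, linear `$PnE 0,0`),
#' little-endian (`$BYTEORD 1,2,3,4`), channels named `FSC-A`, `SSC-A`,
#' `FL1-A`. Single-precision storage preserves about 7 significant digits, so
#' values round-trip to at least 6 significant figures. Ground-truth labels
#' are not representable in FCS; use [write_events_csv()] to keep them.
#'
#' @param events An [event_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_fcs()], [read_events()]
#' @export
write_fcs <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  n <- nrow(events)
  if (n == 0L) stop("cannot write an empty event table", call. = FALSE)
  dat <- t(as.matrix(events[, c("fsc", "ssc", "fl")]))
  rng <- function(v) format(2^ceiling(log2(max(v) + 1)), scientific = FALSE)
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "@BD@", "$ENDDATA", "@ED@",
          "$NEXTDATA", "0",
          "$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$PAR", "3", "$TOT", format(n, scientific = FALSE),
          "$P1N", "FSC-A", "$P1B", "32", "$P1E", "0,0", "$P1R",
          rng(events$fsc),
          "$P2N", "SSC-A", "$P2B", "32", "$P2E", "0,0", "$P2R",
          rng(events$ssc),
          "$P3N", "FL1-A", "$P3B", "32", "$P3E", "0,0", "$P3R",
          rng(events$fl),
          "$WELLID", well_id(events),
          "$SRC", "smoscreen simulator")
  delim <- "/"
  text_body <- paste0(delim, paste(kw, collapse = delim), delim)
  # offsets padded to fixed width so the TEXT length is known before filling
  text_start <- 58L
  text_len <- nchar(text_body) + 2L * (10L - 4L) # both @XX@ become 10 chars
  data_start <- text_start + text_len
  data_end <- data_start + 4L * length(dat) - 1L
  text_body <- sub("@BD@", sprintf("%010d", data_start), text_body,
                   fixed = TRUE)
  text_body <- sub("@ED@", sprintf("%010d", data_end), text_body,
                   fixed = TRUE)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + nchar(text_body) - 1L,
                    data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text_body), con)
  writeBin(as.numeric(dat), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS file
#'
#' Reads FCS 3.0/3.1 list-mode files with float (`$DATATYPE F`, 32-bit) or
#' double (`D`) data — i.e. everything [write_fcs()] emits plus the common
#' float variants. Channels are mapped to `fsc`/`ssc`/`fl` by name patterns.
#'
#' @param path FCS file path.
#' @param channel_patterns Named list of regular expressions (case
#'   insensitive) locating the three channels among the `$PnN` names.
#' @return An [event_table()].
#' @export
read_fcs <- function(path,
                     channel_patterns = list(fsc = "^FSC", ssc = "^SSC",
                                             fl = "^FL|GFP|FITC")) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 58L)
    stop("file too short to be an FCS file: ", path, call. = FALSE)
  magic <- rawToChar(raw[1:6])
  if (!startsWith(magic, "FCS3"))
    stop("not an FCS 3.x file: ", path, call. = FALSE)
  off <- function(i) as.integer(trimws(rawToChar(raw[(11 + 8 * (i - 1)):(10 + 8 * i)])))
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)
  # FCS offsets are 0-based byte positions; R raw indexing is 1-based
  text <- rawToChar(raw[(text_start + 1L):(text_end + 1L)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substr(text, 2, nchar(text)), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  names(vals) <- toupper(trimws(keys))
  need <- function(k) {
    if (is.na(vals[k])) stop("FCS keyword ", k, " missing in ", path,
                             call. = FALSE)
    vals[[k]]
  }
  if (data_start == 0L || is.na(data_start)) {
    data_start <- as.integer(need("$BEGINDATA"))
    data_end <- as.integer(need("$ENDDATA"))
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("F", "D"))
    stop("unsupported FCS $DATATYPE '", dtype, "' (only F and D)",
         call. = FALSE)
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"
  size <- if (dtype == "F") 4L else 8L
  vals_num <- readBin(raw[(data_start + 1L):(data_start + size * npar * ntot)],
                      "numeric", n = npar * ntot, size = size,
                      endian = endian)
  mat <- matrix(vals_num, ncol = npar, byrow = TRUE)
  pn <- vapply(seq_len(npar),
               function(i) {
                 v <- vals[paste0("$P", i, "N")]
                 if (is.na(v)) paste0("P", i) else v
               }, character(1))
  find <- function(pat, what) {
    hit <- grep(pat, pn, ignore.case = TRUE)
    if (length(hit) == 0L)
      stop("no channel matching '", pat, "' (", what, ") among: ",
           paste(pn, collapse = ", "), call. = FALSE)
    hit[1]
  }
  wid <- vals["$WELLID"]
  if (is.na(wid)) wid <- sub("\\.fcs$", "", basename(path), ignore.case = TRUE)
  event_table(fsc = mat[, find(channel_patterns$fsc, "fsc")],
              ssc = mat[, find(channel_patterns$ssc, "ssc")],
              fl = mat[, find(channel_patterns$fl, "fl")],
              well_id = wid)
}
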