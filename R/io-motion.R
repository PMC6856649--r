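# Readers/writers for the marker (TRC) and motion/storage (MOT/STO)
# tab-delimited text formats of the OpenSim ecosystem.

#' Read a TRC marker-trajectory file
#'
#' Parses the standard TRC layout (PathFileType line, header-key line,
#' header-value line, marker-name line, X/Y/Z component line, data rows).
#' Positions declared in mm are converted to m. Missing samples (empty
#' cells) become `NA`. Time must be strictly increasing.
#'
#' @param path file path.
#' @return object of class `trc_data`: list with `time` (s), `rate` (Hz),
#'   `units` (always `"m"` after conversion), `marker_names`, and
#'   `positions`, an `n_frames x n_markers x 3` array.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5) stop("TRC format error: truncated header")
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(vals), keys)
  rate <- as.numeric(hdr[["DataRate"]])
  n_markers <- as.numeric(hdr[["NumMarkers"]])
  units <- hdr[["Units"]]
  if (is.null(units) || !nzchar(units)) stop("TRC format error: no Units in header")
  name_row <- strsplit(lines[4], "\t")[[1]]
  marker_names <- name_row[-(1:2)]
  marker_names <- marker_names[nzchar(marker_names)]
  if (length(marker_names) != n_markers)
    stop(sprintf("TRC format error: header declares %d markers, found %d names",
                 n_markers, length(marker_names)))
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (!length(data_lines)) stop("TRC format error: empty data block")
  ncol_expect <- 2 + 3 * n_markers
  rows <- lapply(data_lines, function(l) {
    x <- strsplit(l, "\t")[[1]]
    # trailing empty cells of wholly-missing markers may be dropped by
    # writers; anything else is a malformed row
    if (length(x) > ncol_expect ||
        (ncol_expect - length(x)) %% 3 != 0)
      stop("TRC format error: inconsistent column count")
    length(x) <- ncol_expect
    suppressWarnings(as.numeric(x))
  })
  bad <- which(vapply(rows, length, integer(1)) != ncol_expect)
  if (length(bad)) stop("TRC format error: inconsistent column count at data row ", bad[1])
  mat <- do.call(rbind, rows)
  time <- mat[, 2]
  if (any(diff(time) <= 0)) stop("TRC format error: time not strictly increasing")
  pos <- array(NA_real_, c(nrow(mat), n_markers, 3),
               dimnames = list(NULL, marker_names, c("x", "y", "z")))
  for (m in seq_len(n_markers))
    pos[, m, ] <- mat[, 2 + (m - 1) * 3 + 1:3]
  scale <- if (tolower(units) == "mm") 1 / 1000 else 1
  structure(list(time = time, rate = rate, units = "m",
                 marker_names = marker_names, positions = pos * scale),
            class = "trc_data")
}

#' Write a TRC marker-trajectory file
#'
#' @param trc a `trc_data` object (positions in m).
#' @param path output path.
#' @param units `"m"` or `"mm"` for the written file.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trc, path, units = "mm") {
  scale <- if (units == "mm") 1000 else 1
  nm <- length(trc$marker_names); nf <- length(trc$time)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines("DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames", con)
  writeLines(sprintf("%g\t%g\t%d\t%d\t%s\t%g\t1\t%d",
                     trc$rate, trc$rate, nf, nm, units, trc$rate, nf), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(trc$marker_names, "", ""))),
                   collapse = "\t"), con)
  comp <- as.vector(vapply(seq_len(nm), function(i)
    paste0(c("X", "Y", "Z"), i), character(3)))
  writeLines(paste(c("", "", comp), collapse = "\t"), con)
  fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.8f", x))
  for (f in seq_len(nf)) {
    xyz <- as.vector(t(trc$positions[f, , ])) * scale
    writeLines(paste(c(sprintf("%d", f), sprintf("%.6f", trc$time[f]),
                       fmt_num(xyz)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a MOT/STO motion or storage file
#'
#' Tab-delimited with a `name`/`nRows`/`nColumns`/`inDegrees` header closed
#' by `endheader`, a column-name row and numeric data. No unit conversion is
#' applied; the header's `inDegrees` flag is returned as an attribute.
#'
#' @param path file path.
#' @return data.frame (first column `time`) with attributes `in_degrees`
#'   (as stored on disk) and `name`.
#' @export
read_mot <- function(path) {
  if (!file.exists(path)) stop("MOT/STO file not found: ", path)
  lines <- readLines(path)
  end <- which(trimws(tolower(lines)) == "endheader")
  if (!length(end)) stop("MOT/STO format error: no endheader line")
  hdr <- lines[seq_len(end[1] - 1)]
  in_deg <- any(grepl("^\\s*inDegrees\\s*=\\s*yes", hdr, ignore.case = TRUE))
  nm_line <- grep("^\\s*name\\s*=", hdr, value = TRUE)
  name <- if (length(nm_line)) sub("^\\s*name\\s*=\\s*", "", nm_line[1]) else ""
  cols <- strsplit(lines[end[1] + 1], "\t")[[1]]
  cols <- trimws(cols); cols <- cols[nzchar(cols)]
  body <- lines[-(1:(end[1] + 1))]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("MOT/STO format error: empty data block")
  rows <- lapply(body, function(l) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(l), "\t|\\s+")[[1]]))
    if (length(x) != length(cols))
      stop("MOT/STO format error: inconsistent column count")
    x
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- cols
  attr(df, "in_degrees") <- in_deg
  attr(df, "name") <- name
  df
}

#' @rdname read_mot
#' @export
read_sto <- read_mot

#' Write a MOT/STO motion or storage file
#'
#' @param df data.frame whose first column is `time`.
#' @param path output path.
#' @param name storage name written into the header.
#' @param in_degrees whether the non-time columns are in degrees (header
#'   flag only; no conversion is applied).
#' @return `path`, invisibly.
#' @export
write_sto <- function(df, path, name = "scapsim", in_degrees = FALSE) {
  stopifnot(names(df)[1] == "time")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("name=", name),
               paste0("datacolumns=", ncol(df)),
               paste0("datarows=", nrow(df)),
               paste0("nRows=", nrow(df)),
               paste0("nColumns=", ncol(df)),
               paste0("inDegrees=", if (in_degrees) "yes" else "no"),
               "endheader"), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df)))
    writeLines(paste(sprintf("%.10g", as.numeric(df[i, ])), collapse = "\t"), con)
  invisible(path)
}
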