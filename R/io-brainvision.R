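# BrainVision triplet (.vhdr / .vmrk / .eeg) writer and reader:
# multiplexed IEEE float32 binary data, INI-style header and marker files.

#' Write a recording as a BrainVision triplet
#'
#' Writes \code{<base>.vhdr}, \code{<base>.vmrk} and \code{<base>.eeg}
#' (multiplexed IEEE float32).  Events become Stimulus markers.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param path Path to the \code{.vhdr} member (siblings are derived).
#' @return \code{path}, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  base <- sub("\\.vhdr$", "", path)
  name <- basename(base)
  vhdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", name),
    sprintf("MarkerFile=%s.vmrk", name),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(rec$samples)),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$srate),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_along(rec$channel_names),
            rec$channel_names),
    "[Comment]",
    sprintf("Reference=%s", rec$reference))
  writeLines(vhdr, paste0(base, ".vhdr"))

  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          "Codepage=UTF-8",
          sprintf("DataFile=%s.eeg", name),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,20000101000000000000")
  if (nrow(rec$events))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$events)) + 1L,
                        rec$events$label, rec$events$sample))
  writeLines(mk, paste0(base, ".vmrk"))

  con <- file(paste0(base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$samples), con, size = 4, endian = "little")
  invisible(path)
}

.ini_value <- function(lines, key) {
  hit <- grep(sprintf("^%s=", key), lines, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(sprintf("^%s=", key), "", hit[1])
}

#' Read a BrainVision triplet
#'
#' @param path Path to the \code{.vhdr} member.
#' @return An \code{\link{eeg_recording}}.
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  dir <- dirname(path)
  data_file <- file.path(dir, .ini_value(lines, "DataFile"))
  marker_file <- file.path(dir, .ini_value(lines, "MarkerFile"))
  if (!file.exists(marker_file))
    stop_input("missing BrainVision member: %s", basename(marker_file))
  if (!file.exists(data_file))
    stop_input("missing BrainVision member: %s", basename(data_file))
  if (!identical(.ini_value(lines, "DataOrientation"), "MULTIPLEXED") ||
      !identical(.ini_value(lines, "BinaryFormat"), "IEEE_FLOAT_32"))
    stop_input("unsupported BrainVision dialect (need MULTIPLEXED IEEE_FLOAT_32)")
  nch <- as.integer(.ini_value(lines, "NumberOfChannels"))
  srate <- 1e6 / as.numeric(.ini_value(lines, "SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[`, "", 1)
  reference <- .ini_value(lines, "Reference") %||% "unknown"

  sz <- file.info(data_file)$size
  con <- file(data_file, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  x <- matrix(vals, nrow = nch)

  mlines <- readLines(marker_file, warn = FALSE)
  mk <- grep("^Mk[0-9]+=Stimulus,", mlines, value = TRUE)
  events <- if (length(mk)) {
    parts <- strsplit(sub("^Mk[0-9]+=Stimulus,", "", mk), ",")
    data.frame(sample = as.integer(vapply(parts, `[`, "", 2)),
               label = vapply(parts, `[`, "", 1),
               stringsAsFactors = FALSE)
  } else data.frame(sample = integer(), label = character())
  events <- events[order(events$sample), , drop = FALSE]
  rownames(events) <- NULL
  eeg_recording(x, srate, ch_names, reference = reference, events = events)
}

#' Read or write a recording, dispatching on the file extension
#'
#' \code{.edf} files use the EDF+ dialect, \code{.vhdr} the BrainVision
#' triplet.
#'
#' @param path File path.
#' @param rec Recording to write (for \code{write_recording}).
#' @return \code{read_recording}: an \code{\link{eeg_recording}}.
#' @export
read_recording <- function(path) {
  switch(tolower(tools::file_ext(path)),
         edf = read_edf(path),
         vhdr = read_brainvision(path),
         stop_input("unsupported recording format: %s", path))
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  switch(tolower(tools::file_ext(path)),
         edf = write_edf(rec, path),
         vhdr = write_brainvision(rec, path),
         stop_input("unsupported recording format: %s", path))
}
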