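# Minimal EDF+ (continuous) writer/reader: 16-bit samples, 1 s data
# records, one "EDF Annotations" signal carrying the EO/EC event markers as
# time-stamped annotation lists.  Written here because no installed R
# package reads or writes EDF.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop_input("EDF field too long: '%s'", x)
  formatC(x, width = -width)
}

.edf_num <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= width) return(.edf_pad(s, width))
  }
  stop_input("cannot format %g in %d chars", x, width)
}

#' Write a recording as EDF+
#'
#' Stores the recording as a continuous EDF+ file with 16-bit samples,
#' per-channel physical scaling, and EO/EC events in an EDF Annotations
#' signal.  Samples are quantized to the 16-bit grid of the per-channel
#' physical range.
#'
#' @param rec An \code{\link{eeg_recording}} (integer sampling rate).
#' @param path Output file path (conventionally \code{.edf}).
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  x <- rec$samples
  nch <- nrow(x)
  srate <- rec$srate
  if (abs(srate - round(srate)) > 1e-9) stop_input("EDF writer needs an integer sampling rate")
  srate <- as.integer(round(srate))
  nrec <- ceiling(ncol(x) / srate)
  npad <- nrec * srate - ncol(x)
  if (npad > 0) x <- cbind(x, matrix(0, nch, npad))

  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  span <- pmax(pmax_ - pmin_, 1e-6)
  pmin_ <- pmin_ - 0.001 * span; pmax_ <- pmax_ + 0.001 * span

  # annotation TALs (NUL-terminated): record onset stamps plus all events
  # packed into the first record
  tal_raw <- function(strings) {
    out <- raw(0)
    for (s in strings) out <- c(out, charToRaw(s), as.raw(0))
    out
  }
  onsets <- sprintf("+%d\x14\x14", seq_len(nrec) - 1L)
  ev <- rec$events
  ev_tals <- if (nrow(ev))
    sprintf("+%.4f\x14%s\x14", (ev$sample - 1) / srate, ev$label) else character()
  ref_tal <- sprintf("+0\x14REF %s\x14", rec$reference)
  first_rec_raw <- tal_raw(c(onsets[1], ref_tal, ev_tals))
  ann_n <- ceiling(max(length(first_rec_raw) + 2, 60) / 2)  # 2 bytes/"sample"

  ns <- nch + 1L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(.edf_pad(s, w)), con)
  wr("0", 8)
  wr("X X X X", 80)
  wr(sprintf("Startdate 01-JAN-2000 X X X"), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8)
  wr("EDF+C", 44)
  wr(nrec, 8)
  wr("1", 8)
  wr(ns, 4)
  labels <- c(substr(rec$channel_names, 1, 16), "EDF Annotations")
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr(if (i <= nch) "uV" else "", 8)
  for (i in seq_len(ns)) if (i <= nch) writeBin(charToRaw(.edf_num(pmin_[i])), con) else wr("-1", 8)
  for (i in seq_len(ns)) if (i <= nch) writeBin(charToRaw(.edf_num(pmax_[i])), con) else wr("1", 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefilter
  for (i in seq_len(ns)) wr(if (i <= nch) srate else ann_n, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * srate + 1):(r * srate)
    for (ch in seq_len(nch)) {
      dig <- as.integer(round((x[ch, cols] - pmin_[ch]) / scale[ch]) - 32768)
      writeBin(dig, con, size = 2, endian = "little")
    }
    rt <- if (r == 1) first_rec_raw else tal_raw(onsets[r])
    writeBin(c(rt, raw(2 * ann_n - length(rt))), con)
  }
  invisible(path)
}

#' Read an EDF+ recording
#'
#' @param path Path to an EDF/EDF+ file.
#' @return An \code{\link{eeg_recording}}.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  version <- rd(8)
  if (version != "0") stop_input("malformed EDF header (version field '%s')", version)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop_input("malformed EDF header (signal count)")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  nch <- sum(!is_ann)
  srate <- nsamp[which(!is_ann)[1]] / rec_dur
  x <- matrix(0, nch, nrec * max(nsamp[!is_ann]))
  ann_raw <- list()
  for (r in seq_len(nrec)) {
    ci <- 0
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw[[length(ann_raw) + 1]] <- readBin(con, "raw", 2 * nsamp[i])
      } else {
        ci <- ci + 1
        dig <- readBin(con, "integer", nsamp[i], size = 2, endian = "little")
        phys <- pmin_[ci] + (dig - dmin[i]) * (pmax_[ci] - pmin_[ci]) /
          (dmax[i] - dmin[i])
        x[ci, ((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <- phys
      }
    }
  }

  reference <- "unknown"
  events <- data.frame(sample = integer(), label = character())
  rr <- unlist(ann_raw)
  grp <- cumsum(rr == as.raw(0))
  keep <- rr != as.raw(0)
  tals <- vapply(split(rr[keep], grp[keep]), rawToChar, "")
  for (tal in tals) {
    parts <- strsplit(tal, "\x14")[[1]]
    if (length(parts) < 2 || parts[2] == "") next
    onset <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(onset)) next
    for (lab in parts[-1]) {
      if (lab == "") next
      if (startsWith(lab, "REF ")) reference <- sub("^REF ", "", lab)
      else events <- rbind(events,
                           data.frame(sample = as.integer(round(onset * srate)) + 1L,
                                      label = lab))
    }
  }
  events <- events[order(events$sample), , drop = FALSE]
  rownames(events) <- NULL
  eeg_recording(x, srate, labels[!is_ann], reference = reference,
                events = events)
}
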