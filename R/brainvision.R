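#' Write a recording as a BrainVision triplet
#'
#' Writes the standard three files: `<base>.vhdr` (text header),
#' `<base>.vmrk` (text marker list) and `<base>.eeg` (32-bit IEEE float,
#' multiplexed channel order, microvolts, resolution 1). Marker descriptions
#' carry the event type and trial id as `<type>:<trial_id>` so that trial
#' identity round-trips.
#'
#' @param recording an `sk_recording` (see [generate_recording()]).
#' @param base path without extension.
#' @return `base`, invisibly.
#' @export
write_brainvision <- function(recording, base) {
  name <- basename(base)
  vhdr <- paste0(base, ".vhdr"); vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  k <- length(recording$channels)
  samp_int_us <- 1e6 / recording$fs
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", name, ".eeg"),
    paste0("MarkerFile=", name, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", k),
    paste0("SamplingInterval=", format(samp_int_us, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(k), recording$channels))
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- recording$markers
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", name, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    sprintf("Mk%d=Stimulus,%s:%d,%d,1,0",
            seq_len(nrow(mk)) + 1L, mk$type, mk$trial_id, mk$sample))
  writeLines(mrk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$samples)), con, size = 4L,
           endian = "little")
  invisible(base)
}

#' Read a BrainVision triplet
#'
#' Parses the header for channel count/labels and sampling interval, the
#' marker file for stimulus markers, and the binary data file (IEEE float
#' 32, multiplexed). A data file whose byte length is not a whole number of
#' multiplexed samples raises a parse error reporting the offending byte
#' offset rather than truncating silently.
#'
#' @param base path of the triplet without extension, or the `.vhdr` path.
#' @return An `sk_recording`.
#' @export
read_brainvision <- function(base) {
  base <- sub("\\.vhdr$", "", base)
  vhdr <- paste0(base, ".vhdr")
  if (!file.exists(vhdr)) stop("header not found: ", vhdr, call. = FALSE)
  hdr <- readLines(vhdr, encoding = "UTF-8", warn = FALSE)
  get_field <- function(key) {
    ln <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop("parse error in .vhdr: missing ", key,
                          call. = FALSE)
    sub(paste0("^", key, "="), "", ln[1])
  }
  fmt <- get_field("BinaryFormat")
  if (fmt != "IEEE_FLOAT_32")
    stop("parse error: unsupported BinaryFormat ", fmt, call. = FALSE)
  orient <- get_field("DataOrientation")
  if (orient != "MULTIPLEXED")
    stop("parse error: unsupported DataOrientation ", orient, call. = FALSE)
  k <- as.integer(get_field("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_field("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  channels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[[`, "", 1)
  if (length(channels) != k)
    stop("parse error: channel list does not match NumberOfChannels",
         call. = FALSE)
  eeg <- paste0(base, ".eeg")
  nbytes <- file.size(eeg)
  if (is.na(nbytes)) stop("data file not found: ", eeg, call. = FALSE)
  frame_bytes <- 4L * k
  if (nbytes %% frame_bytes != 0)
    stop(sprintf(paste0("parse error in %s: %d bytes is not a whole number",
                        " of %d-byte frames (stray data at byte offset %d)"),
                 eeg, nbytes, frame_bytes,
                 (nbytes %/% frame_bytes) * frame_bytes), call. = FALSE)
  n <- nbytes %/% frame_bytes
  con <- file(eeg, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n * k, size = 4L, endian = "little")
  samples <- matrix(vals, nrow = n, ncol = k, byrow = TRUE)
  colnames(samples) <- channels
  vmrk <- paste0(base, ".vmrk")
  mk_lines <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk, warn = FALSE),
                   value = TRUE)
  markers <- if (length(mk_lines)) {
    parts <- strsplit(sub("^Mk[0-9]+=Stimulus,", "", mk_lines), ",")
    desc <- vapply(parts, `[[`, "", 1)
    pos <- as.integer(vapply(parts, `[[`, "", 2))
    dsplit <- strsplit(desc, ":", fixed = TRUE)
    data.frame(type = vapply(dsplit, `[[`, "", 1),
               trial_id = as.integer(vapply(dsplit, function(x)
                 if (length(x) > 1) x[[2]] else NA_character_, "")),
               sample = pos)
  } else {
    data.frame(type = character(), trial_id = integer(), sample = integer())
  }
  structure(list(samples = samples, channels = channels, fs = fs,
                 markers = markers, participant_id = NA_integer_,
                 condition = NA_character_),
            class = "sk_recording")
}

#' @export
print.sk_recording <- function(x, ...) {
  cat(sprintf("<sk_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$samples), length(x$channels), x$fs,
              nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  cat(sprintf("  markers: %d (%s)\n", nrow(x$markers),
              paste(unique(x$markers$type), collapse = " ")))
  invisible(x)
}
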