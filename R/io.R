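#' Read and write BIDS-style iEEG sidecar tables
#'
#' Tab-separated, UTF-8, LF line endings. `electrodes.tsv` carries contact
#' name and scanner-space mm coordinates (plus optional `soz` column);
#' `channels.tsv` carries per-channel `status` (`good`/`bad`);
#' `events.tsv` carries stimulus onsets and `electrical_stimulation_site`
#' labels of the form `"A-B"`.
#'
#' @param electrodes,channels,events,path,file File paths / tibbles as
#'   appropriate.
#' @param extra_bad Additional status values to treat as excluded.
#' @name bids_io
NULL

write_tsv_lf <- function(df, file) {
  readr::write_tsv(df, file, na = "n/a", eol = "\n")
  invisible(file)
}

#' @rdname bids_io
#' @export
write_electrodes_tsv <- function(electrodes, file) {
  df <- tibble::tibble(name = electrodes$label,
                       x = electrodes$x, y = electrodes$y, z = electrodes$z,
                       size = NA_real_)
  if ("soz" %in% names(electrodes)) df$soz <- ifelse(electrodes$soz, "yes", "no")
  write_tsv_lf(df, file)
}

#' @rdname bids_io
#' @export
read_electrodes_tsv <- function(file) {
  df <- readr::read_tsv(file, show_col_types = FALSE, na = c("n/a", "NA"))
  req <- c("name", "x", "y", "z")
  if (!all(req %in% names(df))) {
    stop(sprintf("%s: missing required column(s) %s", file,
                 paste(setdiff(req, names(df)), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$name)) stop(sprintf("%s: duplicated electrode names", file), call. = FALSE)
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-finite coordinates in row(s) %s", file,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(label = df$name, x = df$x, y = df$y, z = df$z)
  out$soz <- if ("soz" %in% names(df)) df$soz == "yes" else FALSE
  out
}

#' @rdname bids_io
#' @export
write_channels_tsv <- function(channels, file) {
  write_tsv_lf(tibble::tibble(name = channels$label, type = "ECOG",
                              status = ifelse(channels$included, "good", "bad")),
               file)
}

#' @rdname bids_io
#' @export
read_channels_tsv <- function(file, extra_bad = character(0)) {
  df <- readr::read_tsv(file, show_col_types = FALSE, na = c("n/a", "NA"))
  if (!all(c("name", "status") %in% names(df))) {
    stop(sprintf("%s: needs columns name, status", file), call. = FALSE)
  }
  tibble::tibble(label = df$name,
                 included = !(tolower(df$status) %in% c("bad", tolower(extra_bad))))
}

#' @rdname bids_io
#' @export
write_events_tsv <- function(events, file) {
  write_tsv_lf(tibble::tibble(
    onset = events$onset_s,
    duration = 0.001,
    sample = events$sample,
    trial_type = "electrical_stimulation",
    electrical_stimulation_site = events$site,
    electrical_stimulation_current = events$current_ma
  ), file)
}

#' @rdname bids_io
#' @param known_labels Channel labels used to validate stimulation sites.
#' @export
read_events_tsv <- function(file, known_labels = NULL) {
  df <- readr::read_tsv(file, show_col_types = FALSE, na = c("n/a", "NA"))
  req <- c("onset", "electrical_stimulation_site")
  if (!all(req %in% names(df))) {
    stop(sprintf("%s: missing required column(s) %s", file,
                 paste(setdiff(req, names(df)), collapse = ", ")), call. = FALSE)
  }
  parts <- strsplit(df$electrical_stimulation_site, "-", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop(sprintf("%s: malformed stimulation site in row(s) %s", file,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  anode <- vapply(parts, `[`, character(1), 1)
  cathode <- vapply(parts, `[`, character(1), 2)
  if (!is.null(known_labels)) {
    unk <- which(!(anode %in% known_labels) | !(cathode %in% known_labels))
    if (length(unk) > 0) {
      stop(sprintf("%s: unknown stimulation site label in row(s) %s", file,
                   paste(unk, collapse = ", ")), call. = FALSE)
    }
  }
  tibble::tibble(
    onset_s = df$onset,
    sample = if ("sample" %in% names(df)) df$sample else NA_integer_,
    site = df$electrical_stimulation_site,
    anode = anode, cathode = cathode,
    current_ma = if ("electrical_stimulation_current" %in% names(df)) {
      df$electrical_stimulation_current
    } else NA_real_
  )
}

#' Read or write a symmetric adjacency / count matrix as TSV
#'
#' First column `label`, remaining columns one per contact (header = labels).
#'
#' @param m Matrix (adjacency or counts) with dimnames, or a
#'   [binary_network()].
#' @param file Path.
#' @name matrix_io
#' @export
write_adjacency_tsv <- function(m, file) {
  if (inherits(m, "binary_network")) m <- as.matrix(m)
  df <- tibble::as_tibble(as.data.frame(m), rownames = "label")
  write_tsv_lf(df, file)
}

#' @rdname matrix_io
#' @param binary Return a [binary_network()] (default) or a plain matrix.
#' @export
read_adjacency_tsv <- function(file, binary = TRUE) {
  df <- readr::read_tsv(file, show_col_types = FALSE)
  labels <- df$label
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), labels)) {
    stop(sprintf("%s: header labels do not match the label column", file), call. = FALSE)
  }
  rownames(m) <- labels
  if (binary) binary_network(m) else m
}

#' Read or write a binary NIfTI boundary mask
#'
#' @param mask A [voxel_mask()].
#' @param file Path to a `.nii` or `.nii.gz` file.
#' @name nifti_io
#' @export
write_mask_nifti <- function(mask, file) {
  stopifnot(inherits(mask, "voxel_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  RNifti::sform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  voxel_mask(array(as.vector(img) != 0, dim = dim(img)), aff)
}

#' Read or write a BrainVision recording
#'
#' Minimal BrainVision Core support: a text `.vhdr` header, text `.vmrk`
#' stimulus markers, and multiplexed IEEE float32 binary data in `.eeg`,
#' which is sufficient to round-trip the simulated SPES recordings. Marker
#' descriptions carry the stimulation site label.
#'
#' @param recording A `spes_recording`.
#' @param stem Output path without extension.
#' @name brainvision_io
#' @export
write_brainvision <- function(recording, stem) {
  stopifnot(inherits(recording, "spes_recording"))
  vhdr <- paste0(stem, ".vhdr"); vmrk <- paste0(stem, ".vmrk"); eeg <- paste0(stem, ".eeg")
  base <- basename(stem)
  n_ch <- length(recording$channels)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", n_ch),
    sprintf("SamplingInterval=%.6f", 1e6 / recording$fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), recording$channels)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    sprintf("Mk%d=Stimulus,%s,%d,1,0",
            seq_len(nrow(recording$events)) + 1,
            recording$events$site, recording$events$sample)
  )
  writeLines(mk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(recording$signal)), con, size = 4, endian = "little")
  invisible(stem)
}

#' @rdname brainvision_io
#' @param vhdr Path to the `.vhdr` header.
#' @param modality Modality tag to stamp on the recording.
#' @param events Optional events tibble (e.g. from [read_events_tsv()]);
#'   when NULL, stimulus markers from the `.vmrk` file are used.
#' @export
read_brainvision <- function(vhdr, modality = "ECoG", events = NULL) {
  lines <- readLines(vhdr, encoding = "UTF-8")
  get1 <- function(key) {
    v <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(v) != 1) stop(sprintf("%s: missing header key %s", vhdr, key), call. = FALSE)
    sub(paste0("^", key, "="), "", v)
  }
  if (!any(grepl("^BinaryFormat=IEEE_FLOAT_32", lines))) {
    stop(sprintf("%s: unsupported binary format (need IEEE_FLOAT_32)", vhdr), call. = FALSE)
  }
  if (!any(grepl("^DataOrientation=MULTIPLEXED", lines))) {
    stop(sprintf("%s: unsupported data orientation", vhdr), call. = FALSE)
  }
  n_ch <- as.integer(get1("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get1("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  channels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",", fixed = TRUE),
                     `[`, character(1), 1)
  if (length(channels) != n_ch) {
    stop(sprintf("%s: channel list does not match NumberOfChannels", vhdr), call. = FALSE)
  }
  eeg <- file.path(dirname(vhdr), get1("DataFile"))
  raw <- readBin(eeg, "numeric", n = file.size(eeg) / 4, size = 4, endian = "little")
  sig <- matrix(raw, ncol = n_ch, byrow = TRUE, dimnames = list(NULL, channels))
  if (is.null(events)) {
    vmrk <- file.path(dirname(vhdr), get1("MarkerFile"))
    mk <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk, encoding = "UTF-8"), value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",", fixed = TRUE)
    site <- vapply(parts, `[`, character(1), 2)
    sample <- as.integer(vapply(parts, `[`, character(1), 3))
    ab <- strsplit(site, "-", fixed = TRUE)
    events <- tibble::tibble(
      onset_s = (sample - 1) / fs, sample = sample, site = site,
      anode = vapply(ab, `[`, character(1), 1),
      cathode = vapply(ab, `[`, character(1), 2),
      current_ma = NA_real_
    )
  }
  structure(list(signal = sig, fs = fs, channels = channels,
                 events = events, modality = modality),
            class = "spes_recording")
}

#' Read or write MRtrix TCK streamline files
#'
#' Minimal MRtrix tracks format: a text header terminated by `END`, then
#' float32 triplets in scanner mm space with NaN-triplet separators between
#' streamlines and an Inf-triplet terminator.
#'
#' @param streamlines List of n x 3 mm coordinate matrices.
#' @param file Path to a `.tck` file.
#' @name tck_io
#' @export
write_tck <- function(streamlines, file) {
  n <- length(streamlines)
  hdr_stub <- c("mrtrix tracks", "datatype: Float32LE", sprintf("count: %d", n))
  # file offset must account for its own digits; two passes settle it
  offset <- 0
  for (i in 1:3) {
    hdr <- c(hdr_stub, sprintf("file: . %d", offset), "END")
    new_offset <- sum(nchar(hdr, type = "bytes")) + length(hdr)  # LF per line
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(hdr, con, useBytes = TRUE)
  for (s in streamlines) {
    writeBin(as.vector(t(coord_matrix(s))), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(file)
}

#' @rdname tck_io
#' @export
read_tck <- function(file) {
  raw <- readBin(file, "raw", n = file.size(file))
  nl <- which(raw == as.raw(10))
  hdr_lines <- character(0)
  start <- 1
  end_at <- NA
  for (pos in nl) {
    line <- rawToChar(raw[start:(pos - 1)])
    hdr_lines <- c(hdr_lines, line)
    start <- pos + 1
    if (line == "END") { end_at <- pos; break }
  }
  if (is.na(end_at)) stop(sprintf("%s: no END in TCK header", file), call. = FALSE)
  if (hdr_lines[1] != "mrtrix tracks") {
    stop(sprintf("%s: not an MRtrix tracks file", file), call. = FALSE)
  }
  if (!any(grepl("^datatype:\\s*Float32LE$", hdr_lines))) {
    stop(sprintf("%s: unsupported TCK datatype", file), call. = FALSE)
  }
  off_line <- grep("^file:", hdr_lines, value = TRUE)
  offset <- as.integer(sub("^file:\\s*\\.\\s*", "", off_line))
  vals <- readBin(raw[(offset + 1):length(raw)], "numeric",
                  n = (length(raw) - offset) / 4, size = 4, endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  out <- list()
  cur <- integer(0)
  for (i in seq_len(nrow(m))) {
    if (all(is.infinite(m[i, ]))) break
    if (all(is.nan(m[i, ]))) {
      if (length(cur) > 0) out[[length(out) + 1]] <- m[cur, , drop = FALSE]
      cur <- integer(0)
    } else {
      cur <- c(cur, i)
    }
  }
  if (length(cur) > 0) out[[length(out) + 1]] <- m[cur, , drop = FALSE]
  structure(out, class = "streamline_set")
}

#' Write a similarity result as JSON
#'
#' @param similarity A `network_similarity` from [compare_networks()].
#' @param file Path.
#' @export
write_similarity_json <- function(similarity, file) {
  x <- unclass(similarity)
  x$ratio_sc_delta_ec <- as.character(x$ratio_sc_delta_ec)  # may be +/-Inf
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
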