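pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Read a multichannel EEG recording
#'
#' Dispatches on file format (EDF or BrainVision header) and returns the
#' continuous representation with amplitudes normalized to microvolts.
#'
#' @param path path to an `.edf` file or a BrainVision `.vhdr` header.
#' @param format `"auto"` (by extension), `"edf"` or `"brainvision"`.
#' @return an `eeg_continuous` in uV.
#' @export
read_eeg <- function(path, format = c("auto", "edf", "brainvision")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", vhdr = "brainvision",
                     stop("cannot infer format from extension: ", path))
  switch(format, edf = read_edf(path), brainvision = read_brainvision(path))
}

unit_to_uv <- function(unit) {
  u <- trimws(unit)
  if (u %in% c("uV", "µV", "μV")) return(1)
  if (u == "mV") return(1e3)
  if (u == "V") return(1e6)
  if (!nzchar(u)) {
    warning("channel unit missing; assuming uV")
    return(1)
  }
  warning("unknown unit '", u, "'; assuming uV")
  1
}

#' Read a continuous EDF recording
#'
#' Minimal reader for standard 16-bit EDF: parses the fixed header and
#' per-signal headers, reads the data records, rescales digital values to
#' physical units and normalizes them to microvolts. All signals must share
#' one sampling rate.
#'
#' @param path path to the `.edf` file.
#' @return an `eeg_continuous` in uV.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readChar(con, n, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < n) stop("truncated EDF header")
    trimws(raw)
  }
  version <- rd(8)
  rd(80); rd(80); rd(8); rd(8)                # patient, recording, date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: number of signals")
  if (is.na(n_records) || n_records < 1) stop("malformed EDF header: number of records")
  if (is.na(record_dur) || record_dur <= 0) stop("malformed EDF header: record duration")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)               # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)               # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (any(is.na(spr)) || length(unique(spr)) != 1)
    stop("malformed EDF header: samples per record (mixed rates unsupported)")
  expected <- 256L + ns * 256L
  if (!is.na(header_bytes) && header_bytes != expected)
    stop("malformed EDF header: header byte count")
  fs <- spr[1] / record_dur
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- matrix(0, ns, n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      if (length(v) < spr[ch]) stop("truncated EDF data at record ", r)
      phys <- pmin_[ch] + (v - dmin_[ch]) * gain[ch]
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  for (ch in seq_len(ns)) data[ch, ] <- data[ch, ] * unit_to_uv(units[ch])
  eeg_continuous(data, fs, labels)
}

#' Write a continuous recording to EDF (16-bit)
#'
#' Companion writer used for fixtures and round-trip checks. Uses one-second
#' data records; trailing samples that do not fill a record are dropped.
#'
#' @param x an `eeg_continuous` in uV.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_edf <- function(x, path) {
  stopifnot(inherits(x, "eeg_continuous"))
  fs <- x$fs_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer sampling rate")
  spr <- as.integer(round(fs))
  n_rec <- floor(ncol(x$data) / spr)
  if (n_rec < 1) stop("recording shorter than one data record")
  ns <- nrow(x$data)
  pmin_ <- apply(x$data, 1, min); pmax_ <- apply(x$data, 1, max)
  pad <- pmax(1e-6, (pmax_ - pmin_) * 0.01)
  pmin_ <- floor(pmin_ - pad); pmax_ <- ceiling(pmax_ + pad)
  dmin_ <- -32768; dmax_ <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad_field(x, w), con, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("synthetic", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (ch in seq_len(ns)) wr(x$channel_names[ch], 16)
  for (ch in seq_len(ns)) wr("", 80)
  for (ch in seq_len(ns)) wr("uV", 8)
  for (ch in seq_len(ns)) wr(pmin_[ch], 8)
  for (ch in seq_len(ns)) wr(pmax_[ch], 8)
  for (ch in seq_len(ns)) wr(dmin_, 8)
  for (ch in seq_len(ns)) wr(dmax_, 8)
  for (ch in seq_len(ns)) wr("", 80)
  for (ch in seq_len(ns)) wr(spr, 8)
  for (ch in seq_len(ns)) wr("", 32)
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      phys <- x$data[ch, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((phys - pmin_[ch]) / gain[ch] + dmin_))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

parse_vhdr <- function(path) {
  txt <- readLines(path, warn = FALSE)
  section <- ""
  out <- list()
  for (line in txt) {
    line <- sub(";.*$", "", line)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      out[[section]] <- list()
    } else if (grepl("=", line, fixed = TRUE) && nzchar(section)) {
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording (.vhdr/.vmrk/.eeg triplet)
#'
#' Supports binary multiplexed data in IEEE_FLOAT_32 or INT_16 format.
#' Channel resolutions and units are applied and amplitudes normalized to
#' microvolts.
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @return an `eeg_continuous` in uV; stimulus marker positions (samples)
#'   are attached as attribute `"markers"` when a marker file is present.
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("file not found: ", vhdr_path)
  hdr <- parse_vhdr(vhdr_path)
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("malformed BrainVision header: missing [Common Infos]")
  for (fld in c("DataFile", "NumberOfChannels", "SamplingInterval"))
    if (is.null(ci[[fld]]))
      stop("malformed BrainVision header: missing field ", fld)
  if (!is.null(ci$DataOrientation) &&
      toupper(ci$DataOrientation) != "MULTIPLEXED")
    stop("only MULTIPLEXED orientation is supported")
  n_ch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  fmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  chin <- hdr[["Channel Infos"]]
  names_ <- paste0("ch", seq_len(n_ch))
  res <- rep(1, n_ch); units <- rep("uV", n_ch)
  for (k in seq_len(n_ch)) {
    entry <- chin[[paste0("Ch", k)]]
    if (!is.null(entry)) {
      parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
      if (length(parts) >= 1 && nzchar(parts[1])) names_[k] <- parts[1]
      if (length(parts) >= 3 && nzchar(parts[3])) res[k] <- as.numeric(parts[3])
      if (length(parts) >= 4 && nzchar(parts[4])) units[k] <- parts[4]
    }
  }
  data_path <- file.path(dirname(vhdr_path), ci$DataFile)
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  sz <- file.info(data_path)$size
  bytes <- if (fmt == "IEEE_FLOAT_32") 4L
  else if (fmt == "INT_16") 2L
  else stop("unsupported BinaryFormat: ", fmt)
  n_samp <- floor(sz / (bytes * n_ch))
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw <- if (bytes == 4L)
    readBin(con, "numeric", n = n_samp * n_ch, size = 4, endian = "little")
  else
    readBin(con, "integer", n = n_samp * n_ch, size = 2, endian = "little")
  if (length(raw) < n_samp * n_ch) stop("truncated BrainVision data file")
  data <- matrix(raw, nrow = n_ch)           # multiplexed: channels vary fastest
  for (k in seq_len(n_ch))
    data[k, ] <- data[k, ] * res[k] * unit_to_uv(units[k])
  out <- eeg_continuous(data, fs, names_)
  if (!is.null(ci$MarkerFile)) {
    mp <- file.path(dirname(vhdr_path), ci$MarkerFile)
    if (file.exists(mp)) {
      mh <- parse_vhdr(mp)
      mi <- mh[["Marker Infos"]]
      pos <- integer(0)
      for (nm in names(mi)) {
        parts <- strsplit(mi[[nm]], ",", fixed = TRUE)[[1]]
        if (length(parts) >= 3 && grepl("Stimulus", parts[1]))
          pos <- c(pos, as.integer(parts[3]))
      }
      attr(out, "markers") <- sort(pos)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a BrainVision triplet (IEEE_FLOAT_32, multiplexed)
#'
#' @param x an `eeg_continuous` in uV.
#' @param base_path output path without extension.
#' @param markers optional stimulus onset sample indices.
#' @return invisibly, the `.vhdr` path.
#' @export
write_brainvision <- function(x, base_path, markers = NULL) {
  stopifnot(inherits(x, "eeg_continuous"))
  vhdr <- paste0(base_path, ".vhdr")
  eegf <- paste0(base_path, ".eeg")
  vmrk <- paste0(base_path, ".vmrk")
  n_ch <- nrow(x$data)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", basename(eegf)),
           paste0("MarkerFile=", basename(vmrk)),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", n_ch),
           paste0("SamplingInterval=", format(1e6 / x$fs_hz, scientific = FALSE)),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           vapply(seq_len(n_ch), function(k)
             sprintf("Ch%d=%s,,1,uV", k, x$channel_names[k]), character(1)))
  writeLines(hdr, vhdr)
  con <- file(eegf, "wb")
  writeBin(as.numeric(x$data), con, size = 4, endian = "little")
  close(con)
  mk <- c("Brain Vision Data Exchange Marker File Version 1.0",
          "[Common Infos]", paste0("DataFile=", basename(eegf)),
          "[Marker Infos]")
  if (!is.null(markers))
    mk <- c(mk, vapply(seq_along(markers), function(i)
      sprintf("Mk%d=Stimulus,S  1,%d,1,0", i, markers[i]), character(1)))
  writeLines(mk, vmrk)
  invisible(vhdr)
}

#' Persist epochs in an HDF5 container
#'
#' Layout: `/data` (trials x channels x samples), `/fs`, `/t0_ms`,
#' `/channels`, `/trials`.
#'
#' @param epochs an `eeg_epochs`.
#' @param path output `.h5` path (overwritten).
#' @return invisibly, `path`.
#' @export
write_epochs_h5 <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(epochs$fs_hz, path, "fs")
  rhdf5::h5write(epochs$t0_ms, path, "t0_ms")
  rhdf5::h5write(epochs$channel_names, path, "channels")
  rhdf5::h5write(epochs$trial_indices, path, "trials")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_epochs_h5
#' @export
read_epochs_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  eeg_epochs(rhdf5::h5read(path, "data"),
             as.numeric(rhdf5::h5read(path, "fs")),
             as.numeric(rhdf5::h5read(path, "t0_ms")),
             as.character(rhdf5::h5read(path, "channels")),
             as.integer(rhdf5::h5read(path, "trials")))
}

#' Export pipeline results as a CSV/JSON/SVG bundle
#'
#' Writes the standard interchange bundle: long-format connectivity CSV, a
#' cluster table CSV, the behavioral records CSV, a machine-readable summary
#' JSON, and connectivity graphs as SVG. Missing components are written as
#' empty-but-valid files with headers.
#'
#' @param results list with any of `connectivity` (named list of
#'   `connectivity_result`), `clusters` (a `voxel_clusters`), `behavior`
#'   (`behavioral_records`), `accuracy` (accuracy table), `summary` (list),
#'   `nodes` (node table for rendering).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  conn_rows <- list()
  for (nm in names(results$connectivity %||% list())) {
    cr <- results$connectivity[[nm]]
    ann <- strsplit(nm, "_", fixed = TRUE)[[1]]
    conn_rows[[nm]] <- connectivity_table(cr,
      band = ann[1] %||% NA, condition = paste(ann[-1], collapse = "_"))
  }
  conn_df <- if (length(conn_rows)) do.call(rbind, conn_rows)
  else data.frame(source = character(), target = character(),
                  band = character(), condition = character(),
                  LC = numeric(), NC = numeric(),
                  p_LC = numeric(), p_NC = numeric())
  p <- file.path(out_dir, "connectivity.csv")
  utils::write.csv(conn_df, p, row.names = FALSE); paths <- c(paths, p)

  cl_df <- data.frame(cluster = integer(), label = character(),
                      n_voxels = integer(), x = numeric(), y = numeric(),
                      z = numeric())
  if (!is.null(results$clusters)) {
    cls <- results$clusters$clusters
    if (length(cls))
      cl_df <- do.call(rbind, lapply(seq_along(cls), function(k)
        data.frame(cluster = k, label = cls[[k]]$label,
                   n_voxels = cls[[k]]$size,
                   x = cls[[k]]$centroid[1], y = cls[[k]]$centroid[2],
                   z = cls[[k]]$centroid[3])))
  }
  p <- file.path(out_dir, "clusters.csv")
  utils::write.csv(cl_df, p, row.names = FALSE); paths <- c(paths, p)

  beh <- results$behavior %||%
    data.frame(trial_index = integer(), response = character(),
               rt_ms = numeric(), outcome = character())
  p <- file.path(out_dir, "behavior.csv")
  utils::write.csv(as.data.frame(beh), p, row.names = FALSE); paths <- c(paths, p)

  if (!is.null(results$accuracy)) {
    p <- file.path(out_dir, "accuracy.csv")
    utils::write.csv(results$accuracy, p, row.names = FALSE); paths <- c(paths, p)
  }

  if (!is.null(results$nodes) && length(results$connectivity %||% list())) {
    for (nm in names(results$connectivity)) {
      cr <- results$connectivity[[nm]]
      for (kind in c("LC", "NC")) {
        p <- file.path(out_dir, sprintf("graph_%s_%s.svg", nm, kind))
        mask <- cr[[paste0("significant_", kind)]]
        render_connectivity_graph(results$nodes, cr[[kind]],
                                  mask = if (!is.null(mask)) !is.na(mask) & mask,
                                  out_path = p,
                                  title = paste(nm, kind))
        paths <- c(paths, p)
      }
    }
  }

  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(results$summary %||% list(), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  paths <- c(paths, p)
  invisible(paths)
}
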