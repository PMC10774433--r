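# Record input/output: the simulator CSV convention (two files,
# <prefix>_clean.csv / <prefix>_noisy.csv, columns = channels, '#' metadata
# comments) and a minimal WFDB format-16 reader/writer. Peak lists are plain
# CSV with a 0-based sample_index column; all in-memory indices are 1-based
# R convention, converted at the file boundary.

write_signal_csv <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s=%s", nm, format(meta[[nm]], scientific = FALSE)),
               con)
  df <- as.data.frame(t(x))
  names(df) <- paste0("ch", seq_len(nrow(x)))
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_signal_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    k <- sub("=.*$", "", kv)
    v <- sub("^[^=]*=", "", kv)
    meta[[k]] <- if (grepl("^-?[0-9.eE+-]+$", v)) as.numeric(v) else v
  }
  df <- utils::read.csv(path, comment.char = "#")
  list(values = t(as.matrix(df)), meta = meta)
}

#' Write a paired record as CSV
#'
#' Writes `<prefix>_clean.csv` and `<prefix>_noisy.csv` (columns = channels,
#' metadata as `#` comments) plus `<prefix>_fetal_peaks.csv` and
#' `<prefix>_maternal_peaks.csv` (0-based `sample_index` column).
#'
#' @param record A [simulate_case()] record.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_record_csv <- function(record, prefix) {
  stopifnot(inherits(record, "paired_record"))
  meta <- list(fs = record$fs, case = record$case$case_id,
               snr_db = record$case$snr_db, seed = record$case$seed,
               duration_s = record$case$duration_s)
  write_signal_csv(record$clean, paste0(prefix, "_clean.csv"), meta)
  write_signal_csv(record$noisy, paste0(prefix, "_noisy.csv"), meta)
  utils::write.csv(data.frame(sample_index = record$fetal_peaks - 1L),
                   paste0(prefix, "_fetal_peaks.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_index = record$maternal_peaks - 1L),
                   paste0(prefix, "_maternal_peaks.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read a paired record written by [write_record_csv()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `paired_record` (peak lists restored to 1-based indices).
#' @export
read_record_csv <- function(prefix) {
  cl <- read_signal_csv(paste0(prefix, "_clean.csv"))
  no <- read_signal_csv(paste0(prefix, "_noisy.csv"))
  fp_file <- paste0(prefix, "_fetal_peaks.csv")
  mp_file <- paste0(prefix, "_maternal_peaks.csv")
  fp <- if (file.exists(fp_file)) utils::read.csv(fp_file)$sample_index + 1L
        else integer(0)
  mp <- if (file.exists(mp_file)) utils::read.csv(mp_file)$sample_index + 1L
        else integer(0)
  m <- cl$meta
  cs <- simulation_case(if (is.null(m$case)) "baseline" else m$case,
                        snr_db = if (is.null(m$snr_db)) 0 else m$snr_db,
                        duration_s = if (is.null(m$duration_s))
                          ncol(cl$values) / m$fs else m$duration_s,
                        fs = m$fs,
                        seed = if (is.null(m$seed)) 0L else m$seed)
  structure(list(clean = unname(cl$values), noisy = unname(no$values),
                 fs = m$fs, case = cs, fetal_peaks = fp, fetal_ectopic = NULL,
                 maternal_peaks = mp, components = NULL),
            class = "paired_record")
}

# ---- WFDB format 16 --------------------------------------------------------

#' Write a signal matrix as a WFDB format-16 record
#'
#' Minimal WFDB writer: a `.hea` header and an interleaved 16-bit
#' little-endian `.dat` payload. Values are quantized as
#' `round(value * gain)`, so the round-trip error is bounded by `0.5/gain`.
#'
#' @param x Channels x samples matrix.
#' @param fs Sampling rate, Hz.
#' @param record_name Record name (file stem).
#' @param dir Output directory.
#' @param gain ADC units per physical unit (default 200/mV, the WFDB default).
#' @return Path to the `.hea` file, invisibly.
#' @export
write_wfdb <- function(x, fs, record_name, dir = ".", gain = 200) {
  stopifnot(is.matrix(x))
  nsig <- nrow(x); nsamp <- ncol(x)
  adc <- round(x * gain)
  adc <- pmin(pmax(adc, -32767), 32767)
  hea <- c(sprintf("%s %d %g %d", record_name, nsig, fs, nsamp),
           sprintf("%s.dat 16 %g/mV 16 0 %d 0 0 ch%d",
                   record_name, gain, as.integer(adc[seq_len(nsig), 1L]),
                   seq_len(nsig)))
  writeLines(hea, file.path(dir, paste0(record_name, ".hea")))
  con <- file(file.path(dir, paste0(record_name, ".dat")), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(adc)), con, size = 2L, endian = "little")
  invisible(file.path(dir, paste0(record_name, ".hea")))
}

#' Read a WFDB format-16 record
#'
#' @param hea_path Path to the `.hea` header.
#' @return List with `values` (channels x samples matrix in physical units)
#'   and `meta` (`fs`, `gain`, signal names).
#' @export
read_wfdb <- function(hea_path) {
  if (!file.exists(hea_path)) stop("file not found: ", hea_path, call. = FALSE)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) < 4L)
    stop("malformed WFDB header (line 1): ", hea_path, call. = FALSE)
  nsig <- as.integer(hdr[2L]); fs <- as.numeric(hdr[3L])
  nsamp <- as.integer(hdr[4L])
  gains <- numeric(nsig); files <- character(nsig); names_ <- character(nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1L + i]), "\\s+")[[1L]]
    if (length(f) < 3L || f[2L] != "16")
      stop("unsupported WFDB signal spec (only format 16): ", hea_path,
           " line ", i + 1L, call. = FALSE)
    files[i] <- f[1L]
    g <- sub("\\(.*\\)", "", sub("/.*$", "", f[3L]))
    gains[i] <- as.numeric(g)
    names_[i] <- if (length(f) >= 9L) f[length(f)] else paste0("ch", i)
  }
  if (length(unique(files)) != 1L)
    stop("multi-file WFDB records not supported", call. = FALSE)
  dat_path <- file.path(dirname(hea_path), files[1L])
  if (!file.exists(dat_path)) stop("file not found: ", dat_path, call. = FALSE)
  raw <- readBin(dat_path, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  adc <- matrix(raw, nrow = nsig)
  gains[gains == 0] <- 200  # WFDB convention: 0 means the default gain
  list(values = adc / gains, meta = list(fs = fs, gain = gains,
                                         signal_names = names_))
}

#' Read a signal record of any supported format
#'
#' Dispatches on the file extension: `.hea` to the WFDB reader, `.csv` to
#' the CSV reader.
#'
#' @param path Path to a `.hea` or `.csv` file.
#' @return List with `values` (channels x samples) and `meta`.
#' @export
read_record <- function(path) {
  if (grepl("\\.hea$", path)) read_wfdb(path)
  else if (grepl("\\.csv$", path)) read_signal_csv(path)
  else stop("unsupported record format: ", path, call. = FALSE)
}
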