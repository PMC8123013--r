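#' Read a non-uniform ECG record (NU-CSV)
#'
#' The NU-CSV dialect is the package's canonical on-disk format for
#' non-uniform records: `#`-prefixed header lines carrying `key=value` pairs
#' (`version`, `leads`, `gain_uV_per_lsb`, `model`), followed by data rows
#' `t_ms,v_lead1[,v_lead2,...]`.  Times are real-valued ms at full decimal
#' precision, values integer counts.
#'
#' @param path file path
#' @return an [nu_signal()]
#' @export
read_nu <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- parse_nu_header(lines[hdr])
  data_lines <- lines[!hdr & nzchar(lines)]
  gain <- if (!is.null(meta$gain_uV_per_lsb)) as.numeric(meta$gain_uV_per_lsb) else 2.5
  leads <- if (!is.null(meta$leads)) strsplit(meta$leads, ";", fixed = TRUE)[[1]] else NULL
  if (!length(data_lines)) {
    nlead <- max(length(leads), 1L)
    return(nu_signal(numeric(0), rep(list(integer(0)), nlead), gain = gain,
                     lead_names = leads, model = meta$model))
  }
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1L)
    stop("NU-CSV format error: inconsistent column count")
  m <- matrix(as.numeric(unlist(parts)), ncol = ncol, byrow = TRUE)
  times <- m[, 1]
  if (length(times) > 1 && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("NU-CSV format error: non-monotonic time at data row %d", bad))
  }
  nlead <- ncol - 1L
  if (!is.null(leads) && length(leads) != nlead)
    stop(sprintf("NU-CSV format error: header declares %d leads, rows have %d",
                 length(leads), nlead))
  values <- lapply(seq_len(nlead), function(j) m[, j + 1])
  nu_signal(times, values, gain = gain, lead_names = leads, model = meta$model)
}

parse_nu_header <- function(hlines) {
  out <- list()
  for (h in hlines) {
    h <- sub("^#\\s*", "", h)
    kv <- regmatches(h, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) out[[kv[2]]] <- trimws(kv[3])
  }
  out
}

#' Write a non-uniform ECG record (NU-CSV)
#'
#' Writes the canonical form: times with fixed 6-decimal precision, values as
#' integers.  `write_nu(read_nu(f))` is byte-identical to `f` for canonical
#' files.
#'
#' @param signal an [nu_signal()]
#' @param path file path
#' @export
write_nu <- function(signal, path) {
  stopifnot(inherits(signal, "nu_signal"))
  hdr <- c("# version=1",
           paste0("# leads=", paste(signal$lead_names, collapse = ";")),
           paste0("# gain_uV_per_lsb=", format(signal$gain)),
           paste0("# model=", if (is.null(signal$model)) "none" else signal$model))
  if (length(signal$times)) {
    vals <- do.call(cbind, lapply(signal$values, function(v)
      formatC(v, format = "d")))
    rows <- paste(sprintf("%.6f", signal$times),
                  apply(vals, 1, paste, collapse = ","), sep = ",")
  } else rows <- character(0)
  writeLines(c(hdr, rows), path)
  invisible(NULL)
}

#' Read a uniform ECG record
#'
#' CSV files hold one column per lead (optional header row of lead names);
#' the sampling frequency must be supplied.  WFDB records (`.hea`/`.dat`)
#' are read through the package's minimal parser (formats 212 and 16).
#' When `target_fs` differs from the declared frequency the record is
#' resampled with cubic splines.
#'
#' @param path file path (for WFDB: the `.hea` file or record base name)
#' @param format `"csv"` or `"wfdb"`
#' @param fs declared sampling frequency (Hz, CSV only)
#' @param gain quantization step, uV/LSB (CSV only)
#' @param target_fs optional resampling target (Hz)
#' @return a [uniform_signal()]
#' @export
read_uniform <- function(path, format = c("csv", "wfdb"), fs = NULL,
                         gain = 2.5, target_fs = NULL) {
  format <- match.arg(format)
  x <- switch(format,
    csv = {
      if (is.null(fs)) stop("fs is required for CSV input")
      first <- readLines(path, n = 1)
      has_header <- !grepl("^[-0-9]", trimws(strsplit(first, ",")[[1]][1]))
      tab <- utils::read.csv(path, header = has_header)
      uniform_signal(as.list(tab), fs = fs, gain = gain,
                     lead_names = if (has_header) names(tab) else NULL)
    },
    wfdb = read_wfdb(path))
  if (!is.null(target_fs) && target_fs != x$fs)
    x <- resample_uniform(x, target_fs)
  x
}

#' Resample a uniform record with cubic splines
#'
#' Used to bring the 360 Hz arrhythmia-database records to the 500 Hz working
#' rate; annotation times of a resampled record scale by `target_fs/fs` only
#' when expressed in samples -- in ms they are unchanged, which is why all
#' package times are ms.
#'
#' @param x a [uniform_signal()]
#' @param target_fs new sampling frequency in Hz
#' @export
resample_uniform <- function(x, target_fs) {
  stopifnot(inherits(x, "uniform_signal"))
  t_old <- uniform_times(x)
  n_new <- floor((length(x$values[[1]]) - 1) * target_fs / x$fs) + 1
  t_new <- x$t0 + (seq_len(n_new) - 1) * 1000 / target_fs
  vals <- lapply(x$values, function(v)
    stats::spline(t_old, v, xout = t_new, method = "fmm")$y)
  uniform_signal(vals, fs = target_fs, gain = x$gain,
                 lead_names = x$lead_names, t0 = x$t0)
}

#' Read and write beat annotation CSVs
#'
#' Plain CSV with header `time_ms,label`.
#' @param path file path
#' @export
read_annotations <- function(path) {
  tab <- utils::read.csv(path, colClasses = c("numeric", "character"))
  annotation_set(tab$time_ms, tab$label)
}

#' @rdname read_annotations
#' @param ann an [annotation_set()]
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(data.frame(time_ms = ann$times, label = ann$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read and write wave-border CSVs
#'
#' Plain CSV with header
#' `beat_time_ms,p_on,p_end,qrs_on,qrs_end,t_end`; empty fields mark absent
#' waves.
#' @param path file path
#' @export
read_borders <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' @rdname read_borders
#' @param tab a borders table ([borders_table()])
#' @export
write_borders <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(NULL)
}
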