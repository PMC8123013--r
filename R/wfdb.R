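#' Minimal WFDB record reader
#'
#' Reads the header/signal pair of a WFDB record (`.hea` plus one `.dat`),
#' supporting the two formats the reference arrhythmia material uses:
#' format 212 (two 12-bit samples packed in 3 bytes) and format 16
#' (little-endian 16-bit).  Only single-segment, single-`.dat` records are
#' handled; this is deliberately a small read-only convenience so that
#' user-supplied database records can enter the chain -- CSV remains the
#' canonical interchange format.
#'
#' @param path path to the `.hea` file or the record base name
#' @return a [uniform_signal()]; amplitudes are ADC counts minus baseline,
#'   gain converted to uV/LSB assuming the header gain is in counts per mV
#' @export
read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)] # comments
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lapply(lines[1 + seq_len(nsig)], function(l)
    strsplit(trimws(l), "\\s+")[[1]])
  dat_files <- vapply(sig, `[`, character(1), 1)
  if (length(unique(dat_files)) != 1L)
    stop("unsupported WFDB layout: multiple .dat files")
  fmt <- as.integer(sub("x.*", "", vapply(sig, `[`, character(1), 2)))
  if (length(unique(fmt)) != 1L || !unique(fmt) %in% c(212L, 16L))
    stop("unsupported WFDB signal format: ", paste(unique(fmt), collapse = ","))
  fmt <- unique(fmt)
  gain_field <- vapply(sig, function(s) if (length(s) >= 3) s[3] else "200", "")
  gain_cnt_per_mv <- as.numeric(sub("[(/].*", "", gain_field))
  gain_cnt_per_mv[is.na(gain_cnt_per_mv) | gain_cnt_per_mv == 0] <- 200
  baseline <- ifelse(grepl("\\(", gain_field),
                     as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field)), 0)
  adc_zero <- vapply(sig, function(s)
    if (length(s) >= 5) as.numeric(s[5]) else 0, numeric(1))
  base <- ifelse(grepl("\\(", gain_field), baseline, adc_zero)
  dat <- file.path(dirname(hea), dat_files[1])
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat)
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  samples <- if (fmt == 212L) decode_fmt212(raw) else decode_fmt16(raw)
  nfrm <- length(samples) %/% nsig
  if (!is.na(nsamp)) nfrm <- min(nfrm, nsamp)
  m <- matrix(samples[seq_len(nfrm * nsig)], nrow = nsig)
  values <- lapply(seq_len(nsig), function(i) m[i, ] - base[i])
  names <- vapply(seq_len(nsig), function(i) {
    s <- sig[[i]]
    if (length(s) >= 9) paste(s[9:length(s)], collapse = " ")
    else paste0("sig", i)
  }, "")
  # counts/mV -> uV per count
  uniform_signal(values, fs = fs, gain = 1000 / gain_cnt_per_mv[1],
                 lead_names = names)
}

decode_fmt212 <- function(raw) {
  n3 <- (length(raw) %/% 3) * 3
  b <- as.integer(raw[seq_len(n3)])
  b1 <- b[seq(1, n3, 3)]; b2 <- b[seq(2, n3, 3)]; b3 <- b[seq(3, n3, 3)]
  s1 <- bitwAnd(b2, 0x0F) * 256L + b1
  s2 <- bitwAnd(b2, 0xF0L) %/% 16L * 256L + b3
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.vector(rbind(s1, s2))
}

decode_fmt16 <- function(raw) {
  readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
          signed = TRUE, endian = "little")
}
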