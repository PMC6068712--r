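#' Construct a single-lead ECG record
#'
#' The basic container for a uniformly sampled single-lead ECG trace. All
#' preprocessing functions ([resample_ecg()], [bandpass_ecg()],
#' [segment_ecg()]) take and return `ecg_record` objects.
#'
#' @param samples Numeric vector of amplitudes (mV for raw recordings;
#'   unitless after normalization).
#' @param fs Sampling rate in Hz (> 0).
#' @param record_id Optional identifier string.
#' @param annotations Optional data frame of beat/rhythm marks with columns
#'   `sample` (0-based or 1-based index into `samples`, stored as given) and
#'   `label`.
#' @return An object of class `ecg_record`: a list with elements `samples`,
#'   `fs`, `record_id`, `annotations`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 10, by = 1 / 250)), fs = 250)
#' rec
#' @export
ecg_record <- function(samples, fs, record_id = "record", annotations = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) ecg_abort("`samples` must be non-empty.", "format")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    ecg_abort("`fs` must be a single positive number.", "config")
  }
  if (!is.null(annotations)) {
    annotations <- as_tibble(annotations)
    if (!all(c("sample", "label") %in% names(annotations))) {
      ecg_abort("`annotations` needs columns `sample` and `label`.", "format")
    }
    if (any(annotations$sample < 0 | annotations$sample >= length(samples))) {
      ecg_abort("annotation indices fall outside the record.", "format")
    }
  }
  structure(
    list(samples = samples, fs = fs, record_id = record_id,
         annotations = annotations),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
#' @method as_tibble ecg_record
as_tibble.ecg_record <- function(x, ...) {
  tibble(time_s = (seq_along(x$samples) - 1) / x$fs, mv = x$samples)
}

#' Read an ECG record from CSV or WFDB files
#'
#' CSV input is either two columns (`time_s`, `mv`; header optional) or a
#' single amplitude column with `fs` supplied. Two-column timestamps must be
#' uniform: any gap deviating by more than 1% of the nominal period is
#' rejected. WFDB input is the classic PhysioNet pair of `<record>.hea` +
#' `<record>.dat` with signal formats 16 or 212; the first channel is
#' returned (lead II in the standard databases).
#'
#' @param path Path to the `.csv` file or to the WFDB record (with or
#'   without the `.hea` extension).
#' @param format `"auto"` (by extension), `"csv"`, or `"wfdb"`.
#' @param fs Sampling rate in Hz, required for single-column CSV.
#' @param channel Channel to extract from multi-channel WFDB records.
#' @return An [ecg_record()].
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb"), fs = NULL,
                     channel = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") read_ecg_csv(path, fs = fs) else
    read_ecg_wfdb(path, channel = channel)
}

read_ecg_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) ecg_abort(paste0("file not found: ", path), "io")
  first <- readLines(path, n = 1L)
  header <- !grepl("^[-+0-9.eE,[:space:]]+$", first)
  d <- utils::read.csv(path, header = header)
  if (ncol(d) >= 2L) {
    t <- as.numeric(d[[1]]); mv <- as.numeric(d[[2]])
    dt <- diff(t)
    nominal <- median(dt)
    if (nominal <= 0 || any(abs(dt - nominal) > 0.01 * nominal)) {
      ecg_abort("CSV timestamps are not uniform (gap deviation > 1% of the nominal period).",
                "format")
    }
    ecg_record(mv, fs = 1 / nominal,
               record_id = sub("\\.csv$", "", basename(path), ignore.case = TRUE))
  } else {
    if (is.null(fs)) {
      ecg_abort("single-column CSV needs an explicit `fs`.", "config")
    }
    ecg_record(as.numeric(d[[1]]), fs = fs,
               record_id = sub("\\.csv$", "", basename(path), ignore.case = TRUE))
  }
}

#' Write an ECG record to a two-column CSV
#'
#' @param record An [ecg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  utils::write.csv(as_tibble(record), path, row.names = FALSE)
  invisible(path)
}

# Minimal WFDB reader: header line "name nsig fs nsamp", one line per signal
# "file format gain(baseline)/units adcres adczero ...". Formats 16
# (little-endian int16) and 212 (packed 12-bit pairs) cover the MITDB-family
# databases. Physical value = (adu - baseline) / gain.
read_ecg_wfdb <- function(path, channel = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) ecg_abort(paste0("file not found: ", hea), "io")
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  nsig <- as.integer(head_tok[2])
  fs <- if (length(head_tok) >= 3) as.numeric(strsplit(head_tok[3], "/")[[1]][1]) else 250
  nsamp <- if (length(head_tok) >= 4) as.integer(head_tok[4]) else NA_integer_
  if (is.na(nsig) || nsig < 1L) ecg_abort("malformed WFDB header.", "format")
  if (channel > nsig) ecg_abort("requested channel not present.", "config")
  sig <- strsplit(trimws(lines[1 + seq_len(nsig)]), "[[:space:]]+")
  datfile <- file.path(dirname(hea), sig[[1]][1])
  # strip any "x"/":"/"+" suffixes (sample skew etc.) from the format field
  fmt <- as.integer(sub("[^0-9].*$", "", sig[[1]][2]))
  gain_field <- function(s) {
    g <- sub("/.*$", "", s[3] %||% "200")
    baseline <- 0
    if (grepl("\\(", g)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", g))
      g <- sub("\\(.*$", "", g)
    }
    gain <- as.numeric(g)
    if (!is.finite(gain) || gain == 0) gain <- 200
    c(gain = gain, baseline = baseline)
  }
  gb <- gain_field(sig[[channel]])
  raw <- readBin(datfile, "raw", n = file.size(datfile))
  adus <- switch(as.character(fmt),
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
      matrix(v, nrow = nsig)[channel, ]
    },
    "212" = {
      v <- wfdb_unpack_212(raw)
      matrix(v[seq_len((length(v) %/% nsig) * nsig)], nrow = nsig)[channel, ]
    },
    ecg_abort(sprintf("unsupported WFDB signal format %s.", fmt), "format")
  )
  if (!is.na(nsamp) && length(adus) > nsamp) adus <- adus[seq_len(nsamp)]
  if (nsig > 1L) message(sprintf("WFDB record has %d channels; returning channel %d.",
                                 nsig, channel))
  ecg_record((adus - gb["baseline"]) / gb["gain"], fs = fs,
             record_id = sub("\\.hea$", "", basename(hea)))
}

# format 212: 3 bytes hold two 12-bit two's-complement samples
wfdb_unpack_212 <- function(raw) {
  n3 <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(n3)])
  b1 <- b[seq(1, n3, 3)]; b2 <- b[seq(2, n3, 3)]; b3 <- b[seq(3, n3, 3)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0F), 8)
  s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4), 0x0F), 8)
  s1 <- ifelse(s1 > 2047, s1 - 4096, s1)
  s2 <- ifelse(s2 > 2047, s2 - 4096, s2)
  as.vector(rbind(s1, s2))
}
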