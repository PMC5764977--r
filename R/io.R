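## File interfaces: Touchstone .s2p (2-port, RI) for spectra, CSV for scan
## traces and field maps. No general-purpose Touchstone reader ships with
## the installed R stack, so the (simple, line-oriented) format is handled
## here directly for the restricted 2-port RI case this package writes.

#' Write a spectrum as a Touchstone .s2p file
#'
#' Two-port, frequency in Hz, real/imaginary (RI) format, 50-ohm
#' reference. The device is reciprocal, so S12 = S21; S22 = S11 for the
#' symmetric model.
#'
#' @param spectrum An [s21_spectrum()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_s2p <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "s21_spectrum"))
  s11 <- if (is.null(spectrum$s11)) rep(0i, length(spectrum$frequency))
         else spectrum$s11
  lines <- c(
    sprintf("! %s; IFBW %g Hz", spectrum$metadata$medium,
            spectrum$metadata$ifbw_hz),
    "# HZ S RI R 50",
    sprintf("%.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g",
            spectrum$frequency,
            Re(s11), Im(s11), Re(spectrum$s21), Im(spectrum$s21),
            Re(spectrum$s21), Im(spectrum$s21), Re(s11), Im(s11)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Touchstone .s2p file (Hz, RI)
#'
#' @param path File path.
#' @return An \code{s21_spectrum}.
#' @export
read_s2p <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  opt <- lines[startsWith(lines, "#")][1]
  if (is.na(opt)) stop("missing Touchstone option line")
  toks <- toupper(strsplit(opt, "\\s+")[[1]])
  if (!("HZ" %in% toks) || !("RI" %in% toks))
    stop("only HZ/RI Touchstone files are supported")
  dat <- lines[!startsWith(lines, "!") & !startsWith(lines, "#") &
                 nzchar(lines)]
  m <- do.call(rbind, lapply(strsplit(dat, "\\s+"), as.numeric))
  if (ncol(m) != 9) stop("expected 9 columns of 2-port RI data")
  structure(list(frequency = m[, 1],
                 s21 = complex(real = m[, 4], imaginary = m[, 5]),
                 s11 = complex(real = m[, 2], imaginary = m[, 3]),
                 metadata = list(ifbw_hz = NA, medium = NA)),
            class = "s21_spectrum")
}

#' Write a scan trace as CSV
#'
#' Columns \code{time_s}, \code{re_s21}, \code{im_s21} with a header row;
#' a JSON sidecar (\code{<path>.json}) records frequency, sample rate,
#' theta0 and generator provenance.
#'
#' @param trace A [scan_trace()].
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "scan_trace"))
  utils::write.csv(data.frame(time_s = trace$time,
                              re_s21 = Re(trace$s21),
                              im_s21 = Im(trace$s21)),
                   path, row.names = FALSE)
  if (sidecar)
    jsonlite::write_json(
      list(frequency_hz = trace$frequency,
           sample_rate_hz = trace$sample_rate,
           theta0_deg = trace$theta0, metadata = trace$metadata),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a scan trace from CSV
#'
#' @param path CSV path (columns \code{time_s}, \code{re_s21},
#'   \code{im_s21}; header required).
#' @param frequency Measurement frequency, Hz; read from the JSON sidecar
#'   when present and not given.
#' @return A [scan_trace()].
#' @export
read_trace_csv <- function(path, frequency = NULL) {
  d <- utils::read.csv(path)
  need <- c("time_s", "re_s21", "im_s21")
  if (!all(need %in% names(d)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  theta0 <- NULL; sr <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    if (is.null(frequency)) frequency <- meta$frequency_hz
    theta0 <- meta$theta0_deg
    sr <- meta$sample_rate_hz
  }
  if (is.null(frequency)) stop("frequency not given and no sidecar found")
  scan_trace(d$time_s, complex(real = d$re_s21, imaginary = d$im_s21),
             frequency = frequency, sample_rate = sr, theta0 = theta0)
}

#' Export a solved field map as CSV
#'
#' Node-centred grid with columns \code{x}, \code{y}, \code{phi_re},
#' \code{phi_im}, \code{Ex_re}, \code{Ex_im}, \code{Ey_re}, \code{Ey_im}.
#'
#' @param map A solved \code{field_map}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_field_map <- function(map, path) {
  stopifnot(inherits(map, "field_map"))
  g <- expand.grid(x = map$x, y = map$y)
  utils::write.csv(data.frame(
    x = g$x, y = g$y,
    phi_re = Re(as.vector(map$phi)), phi_im = Im(as.vector(map$phi)),
    Ex_re = Re(as.vector(map$Ex)), Ex_im = Im(as.vector(map$Ex)),
    Ey_re = Re(as.vector(map$Ey)), Ey_im = Im(as.vector(map$Ey))),
    path, row.names = FALSE)
  invisible(path)
}
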