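#' Read and write force-displacement records
#'
#' Delimited text with a one-line header: columns `time_s`,
#' `displacement_mm`, `force_N`. Internally the package uses SI (metres).
#'
#' @param record An [fd_record].
#' @param path File path.
#' @param mode Test mode of the record being read.
#' @return `write_record` returns `path` invisibly; `read_record` returns an
#'   [fd_record].
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "fd_record"))
  df <- data.frame(time_s = record$time,
                   displacement_mm = 1e3 * record$displacement,
                   force_N = record$force)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path, mode = c("ring_tensile", "compression")) {
  mode <- match.arg(mode)
  df <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_s", "displacement_mm", "force_N") %in% names(df)))
  fd_record(df$time_s, df$displacement_mm * 1e-3, df$force_N, mode = mode)
}

#' Read and write oscillation waveforms
#'
#' Delimited text with header `time_s`, `strain`, `stress_Pa`.
#'
#' @param wave An [oscillation_waveform].
#' @param path File path.
#' @param frequency Oscillation frequency (Hz); required when reading
#'   because the text format does not carry it.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns an [oscillation_waveform].
#' @export
write_waveform <- function(wave, path) {
  stopifnot(inherits(wave, "oscillation_waveform"))
  df <- data.frame(time_s = wave$time, strain = wave$strain,
                   stress_Pa = wave$stress)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path, frequency) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_s", "strain", "stress_Pa") %in% names(df)))
  oscillation_waveform(df$time_s, df$strain, df$stress_Pa,
                       frequency = frequency)
}

#' Read and write stress-strain curves
#'
#' Delimited text with header `strain`, `stress_Pa`, `kind`.
#'
#' @param curve A [stress_strain_curve].
#' @param path File path.
#' @return `write_curve` returns `path` invisibly; `read_curve` returns a
#'   [stress_strain_curve].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  df <- data.frame(strain = curve$strain, stress_Pa = curve$stress,
                   kind = attr(curve, "kind"))
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stress_strain_curve(df$strain, df$stress_Pa, kind = df$kind[1])
}

#' Read and write grayscale images
#'
#' 8-bit grayscale PNG. Matrices are in image convention (rows = y from the
#' top, columns = x), values in \[0, 1\].
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param path File path (.png).
#' @return `write_gray_png` returns `path` invisibly; `read_gray_png`
#'   returns a matrix.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]   # collapse RGB(A) grayscale
  img
}

#' Write a displacement or strain field as delimited text
#'
#' Columns are the data-frame columns of the field
#' (`x y u v score masked` or `x y exx eyy exy masked`).
#'
#' @param field A `"displacement_field"` or `"strain_field"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(is.data.frame(field))
  write.table(field, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
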