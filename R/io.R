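#' @title Image and record I/O
#' @description
#' Grayscale image reading/writing (8-bit PNG via the \pkg{png}
#' package, plus plain-text PGM \samp{P2} for text-only workflows) and
#' the benchmark CSV writer.  Images are carried internally on the
#' normalized `[0, 1]` scale with `dynamic_range = 1`; writing
#' quantizes to 8 bits, so an 8-bit image round-trips losslessly.
#' @name image-io
NULL

io_error <- function(msg) {
  stop(errorCondition(msg, class = c("lpwave_io_error", "error", "condition")))
}

#' @describeIn image-io Read a grayscale image.  RGB(A) input is
#'   converted to luminance (Rec. 601 weights) with a warning.
#' @param path File path; format chosen by extension (`.png`, `.pgm`).
#' @return `read_image()` returns an `image_grid` on the `[0, 1]` scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) {
      warning(sprintf("RGB input '%s' converted to luminance", path),
              call. = FALSE)
      if (dim(px)[3] >= 3L) {
        px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
      } else {
        px <- px[, , 1]
      }
    }
    return(image_grid(px, dynamic_range = 1))
  }
  if (ext == "pgm") {
    tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    if (tok[1] != "P2") io_error(sprintf("unsupported PGM flavor '%s' (only plain P2)", tok[1]))
    w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.numeric(tok[4])
    vals <- as.numeric(tok[-(1:4)])
    if (length(vals) != w * h) io_error(sprintf("corrupt PGM: expected %d pixels, got %d", w * h, length(vals)))
    m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
    return(image_grid(m, dynamic_range = 1))
  }
  io_error(sprintf("unsupported image format '.%s' (supported: png, pgm)", ext))
}

#' @describeIn image-io Write a grayscale image, quantized to 8 bits
#'   and clamped into the valid range.
#' @param image `image_grid` or matrix (interpreted on its dynamic
#'   range, or `[0, 1]` for a bare matrix).
#' @export
write_image <- function(image, path) {
  img <- as_image_grid(image)
  px <- pmin(pmax(img$pixels / img$L, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    q <- round(px * 255) / 255
    png::writePNG(q, path)
    return(invisible(path))
  }
  if (ext == "pgm") {
    q <- round(px * 255)
    lines <- c("P2", sprintf("%d %d", ncol(q), nrow(q)), "255",
               apply(q, 1, paste, collapse = " "))
    writeLines(lines, path)
    return(invisible(path))
  }
  io_error(sprintf("unsupported image format '.%s' (supported: png, pgm)", ext))
}

benchmark_csv_header <- c("image_id", "method", "noise_variance",
                          "replicate", "seed", "mse", "psnr_db", "ssim")

#' @describeIn image-io Write benchmark records to CSV with the fixed
#'   documented header; infinite PSNR is serialized as `"inf"`.  Output
#'   is byte-deterministic for identical records.
#' @param records Output of [run_benchmark()].
#' @export
write_records_csv <- function(records, path) {
  if (!all(benchmark_csv_header %in% names(records))) {
    io_error("records are missing required benchmark columns")
  }
  fmt_num <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) "NA"
      else if (is.infinite(v)) if (v > 0) "inf" else "-inf"
      else sprintf("%.10g", v)
    }, character(1))
  }
  lines <- c(
    paste(benchmark_csv_header, collapse = ","),
    sprintf("%s,%s,%s,%d,%s,%s,%s,%s",
            records$image_id, records$method, fmt_num(records$noise_variance),
            records$replicate, fmt_num(records$seed), fmt_num(records$mse),
            fmt_num(records$psnr_db), fmt_num(records$ssim))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @describeIn image-io Read a benchmark CSV back into a data frame.
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("mse", "psnr_db", "ssim")) {
    if (is.character(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(v) {
        if (v == "inf") Inf else if (v == "-inf") -Inf else as.numeric(v)
      }, numeric(1))
    }
  }
  df
}
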