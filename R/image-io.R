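# Raster images travel as numeric arrays [height, width, 3] of 8-bit sRGB
# values in [0, 255]. PNG is read/written with the `png` package; plain-text
# PPM (P3) is supported so test fixtures can be text files.

.check_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("image must be a [height, width, 3] array")
  if (any(!is.finite(img)) || any(img < 0) || any(img > 255))
    stop("image values must be finite and within [0, 255]")
  invisible(img)
}

#' Read an image file
#'
#' Supports 8-bit RGB PNG (via the `png` package) and plain-text PPM (P3).
#' Grayscale or RGBA PNGs are expanded / flattened to RGB.
#'
#' @param path Image file path; format chosen by extension (`.png`, `.ppm`).
#' @return Numeric array `[height, width, 3]` with values in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3))
    if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
    return(round(x * 255))
  }
  if (ext %in% c("ppm", "pnm")) return(.read_ppm(path))
  stop("unsupported image format: .", ext)
}

#' Write an image file
#'
#' @param img `[height, width, 3]` array in \[0, 255\].
#' @param path Output path; `.png` or `.ppm` (plain text P3).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  .check_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext %in% c("ppm", "pnm")) {
    .write_ppm(img, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

.read_ppm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P3") stop("only plain-text (P3) PPM is supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxv <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != 3 * w * h) stop("corrupt PPM: wrong pixel count")
  px <- matrix(vals, ncol = 3, byrow = TRUE) / maxv * 255
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- matrix(px[, ch], h, w, byrow = TRUE)
  round(img)
}

.write_ppm <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- round(cbind(as.vector(t(img[, , 1])),
                    as.vector(t(img[, , 2])),
                    as.vector(t(img[, , 3]))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(px[, 1], px[, 2], px[, 3]), con)
  invisible(path)
}

#' Grayscale luma of an RGB image
#'
#' Rec. 709 weights on the gamma-encoded channels; adequate for edge
#' detection (only gradients are used downstream).
#'
#' @param img `[height, width, 3]` array.
#' @return `[height, width]` matrix in \[0, 255\].
#' @export
image_gray <- function(img) {
  .check_image(img)
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}
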