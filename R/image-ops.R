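# Thin wrappers around EBImage / png for the image primitives used by the
# generators and the augmentation pipeline. Images are numeric arrays of
# dimension (height, width, 3) with values in [0, 1].

#' Read an 8-bit RGB PNG as a numeric array
#' @param path File path.
#' @return H x W x 3 array in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a numeric RGB array as an 8-bit PNG
#' @param img H x W x 3 array in \[0, 1\].
#' @param path Output path.
#' @export
write_image <- function(img, path) {
  stopifnot_rgb(img)
  png::writePNG(clip01(img), target = path)
  invisible(path)
}

resize_image <- function(img, size) {
  if (dim(img)[1] == size && dim(img)[2] == size) return(img)
  out <- EBImage::resize(img, w = size, h = size)
  clip01(as.numeric_array(out))
}

rotate_image <- function(img, angle_deg) {
  d <- dim(img)
  out <- EBImage::rotate(img, angle_deg, output.dim = c(d[1], d[2]), bg.col = "black")
  clip01(as.numeric_array(out))
}

blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  # gblur's kernel (2*ceiling(3*sigma)+1 wide) may not exceed the image
  sigma <- min(sigma, (floor((min(dim(img)[1:2]) - 1) / 2) - 1) / 3)
  out <- EBImage::gblur(img, sigma = sigma)
  clip01(as.numeric_array(out))
}

# EBImage ops return Image objects; strip back to a plain array.
as.numeric_array <- function(x) {
  a <- as.array(x)
  dim(a) <- utils::head(c(dim(a), 1L, 1L), 3L)
  a
}
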