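## Distorted pinhole camera model defining the image plane of annotation.
## Radial-tangential (Brown-Conrady) distortion, the same convention as
## OpenCV: normalize (x/z, y/z), distort, then map u = fx x' + cx,
## v = fy y' + cy.  Image origin top-left, u right, v down, pixel centres at
## integer coordinates.

Z_NEAR <- 0.1  # mm; points with z <= z_near are "behind the camera"

#' Construct a camera model
#'
#' @param fx,fy focal lengths, pixels.
#' @param cx,cy principal point, pixels.
#' @param width,height image size, pixels.
#' @param k1,k2,k3 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @export
camera_model <- function(fx, fy, cx, cy, width, height,
                         k1 = 0, k2 = 0, p1 = 0, p2 = 0, k3 = 0) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 k1 = k1, k2 = k2, p1 = p1, p2 = p2, k3 = k3,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_model")
}

is_camera_model <- function(x) inherits(x, "camera_model")

camera_param_vector <- function(camera)
  c(camera$fx, camera$fy, camera$cx, camera$cy,
    camera$k1, camera$k2, camera$p1, camera$p2, camera$k3)

#' Project camera-frame points to pixels
#'
#' @param camera a `camera_model`.
#' @param p numeric(3) point or N x 3 matrix in the camera optical frame, mm.
#' @return A data.frame with columns `u`, `v` (pixels) and `behind`
#'   (TRUE when `z <= z_near` = 0.1 mm; `u`, `v` are NA there).
#' @export
project_point <- function(camera, p) {
  stopifnot(is_camera_model(camera))
  pm <- if (is.matrix(p)) as.matrix(p) else matrix(as.numeric(p), 1, 3)
  z <- pm[, 3]
  behind <- z <= Z_NEAR
  xn <- pm[, 1] / z; yn <- pm[, 2] / z
  r2 <- xn^2 + yn^2
  rad <- 1 + r2 * (camera$k1 + r2 * (camera$k2 + r2 * camera$k3))
  xd <- xn * rad + 2 * camera$p1 * xn * yn + camera$p2 * (r2 + 2 * xn^2)
  yd <- yn * rad + camera$p1 * (r2 + 2 * yn^2) + 2 * camera$p2 * xn * yn
  u <- camera$fx * xd + camera$cx
  v <- camera$fy * yd + camera$cy
  u[behind] <- NA_real_; v[behind] <- NA_real_
  data.frame(u = u, v = v, behind = behind)
}

## ------------------------------------------------------------------ PNG IO

#' Write / read grayscale PNG rasters
#'
#' 8-bit for label maps and masks, 16-bit for depth maps.  Written files are
#' byte-deterministic for identical input.
#'
#' @param img height x width matrix of non-negative integers.
#' @param path file path.
#' @param bitdepth 8 or 16.
#' @export
write_png_gray <- function(img, path, bitdepth = 8) {
  stopifnot(bitdepth %in% c(8, 16))
  m <- as.matrix(img); storage.mode(m) <- "integer"
  maxv <- if (bitdepth == 8) 255L else 65535L
  if (any(m < 0L | m > maxv)) stop("write_png_gray: values out of range")
  cpp_write_png_gray(path, m, as.integer(bitdepth))
  invisible(path)
}

#' @rdname write_png_gray
#' @return `read_png()`: for grayscale, a height x width integer matrix;
#'   for RGB, a height x width x 3 integer array.
#' @export
read_png <- function(path) {
  res <- cpp_read_png(path)
  if (res$channels == 1L) return(res$data)
  a <- array(0L, c(res$height, res$width, 3L))
  for (k in 1:3) a[, , k] <- res$data[[k]]
  a
}

#' Write an RGB PNG
#' @param img height x width x 3 integer array (0-255).
#' @param path file path.
#' @export
write_png_rgb <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  storage.mode(r) <- "integer"; storage.mode(g) <- "integer"
  storage.mode(b) <- "integer"
  cpp_write_png_rgb(path, r, g, b)
  invisible(path)
}

#' Encode / decode depth maps as 16-bit PNG
#'
#' Depth is stored in 0.1 mm units (value = round(10 * depth_mm), clamped to
#' 65535); 0 encodes empty.
#'
#' @param depth height x width numeric matrix, mm.
#' @param path file path.
#' @export
write_depth_png <- function(depth, path) {
  q <- round(pmin(pmax(depth * 10, 0), 65535))
  write_png_gray(q, path, bitdepth = 16)
}

#' @rdname write_depth_png
#' @export
read_depth_png <- function(path) read_png(path) / 10
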