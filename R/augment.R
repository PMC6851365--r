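#' Training-time image augmentation
#'
#' The stochastic preprocessing applied to each training image to prevent
#' over-fitting: rotation, horizontal/vertical shift, shear, scaling,
#' per-channel intensity shift, flips, and random erasing (blanking a random
#' rectangle with noise). Each transform is applied independently with
#' probability 0.5 per image; parameters are drawn uniformly up to the
#' configured maxima.
#'
#' Defaults are the operating maxima this pipeline was designed around:
#' rotation up to 90 degrees, shifts up to 20% of the image size, shear up
#' to 5 degrees, scaling up to 10%, channel shift up to 100 intensity steps
#' (on the 0-255 scale, i.e. 100/255 after normalization), both flips, and
#' erasing up to 25% of the image area.
#'
#' @param rotation_deg_max maximum absolute rotation, degrees (<= 90).
#' @param shift_frac_max maximum shift as a fraction of width/height (<= 0.2).
#' @param shear_deg_max maximum shear, degrees (<= 5).
#' @param zoom_frac_max maximum scaling deviation from 1 (<= 0.1).
#' @param channel_shift_max maximum per-channel additive shift on the 0-255
#'   scale (<= 100); applied as a uniform draw in `[-max, max]`, clipped.
#' @param flip_h,flip_v enable horizontal / vertical flips.
#' @param erase_frac_max maximum erased area fraction (<= 0.25); the erased
#'   rectangle is filled with uniform noise.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_deg_max = 90, shift_frac_max = 0.20,
                                shear_deg_max = 5, zoom_frac_max = 0.10,
                                channel_shift_max = 100, flip_h = TRUE,
                                flip_v = TRUE, erase_frac_max = 0.25) {
  caps <- c(rotation_deg_max = 90, shift_frac_max = 0.20, shear_deg_max = 5,
            zoom_frac_max = 0.10, channel_shift_max = 100,
            erase_frac_max = 0.25)
  vals <- c(rotation_deg_max = rotation_deg_max,
            shift_frac_max = shift_frac_max, shear_deg_max = shear_deg_max,
            zoom_frac_max = zoom_frac_max,
            channel_shift_max = channel_shift_max,
            erase_frac_max = erase_frac_max)
  if (any(vals < 0)) stop("augmentation maxima must be non-negative",
                          call. = FALSE)
  over <- vals > caps + 1e-12
  if (any(over))
    stop("augmentation maxima exceed supported caps: ",
         paste(names(vals)[over], collapse = ", "), call. = FALSE)
  structure(list(rotation_deg_max = rotation_deg_max,
                 shift_frac_max = shift_frac_max,
                 shear_deg_max = shear_deg_max,
                 zoom_frac_max = zoom_frac_max,
                 channel_shift_max = channel_shift_max,
                 flip_h = isTRUE(flip_h), flip_v = isTRUE(flip_v),
                 erase_frac_max = erase_frac_max),
            class = "augmentation_config")
}

#' @rdname augmentation_config
#' @export
no_augmentation <- function()
  augmentation_config(0, 0, 0, 0, 0, flip_h = FALSE, flip_v = FALSE,
                      erase_frac_max = 0)

#' Apply the augmentation pipeline to one image
#'
#' @param img H x W x 3 array on the `[0,1]` scale.
#' @param cfg an [augmentation_config()].
#' @return Augmented image, same shape, values in `[0,1]`. With all maxima
#'   zero and flips disabled the image is returned unchanged.
#' @export
augment_frame <- function(img, cfg = augmentation_config()) {
  stopifnot(inherits(cfg, "augmentation_config"), length(dim(img)) == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  coin <- function() stats::runif(1) < 0.5

  theta <- shear <- 0; zoom <- 1; dx <- dy <- 0
  any_affine <- FALSE
  if (cfg$rotation_deg_max > 0 && coin()) {
    theta <- stats::runif(1, -cfg$rotation_deg_max, cfg$rotation_deg_max)
    any_affine <- TRUE
  }
  if (cfg$shift_frac_max > 0 && coin()) {
    dy <- stats::runif(1, -cfg$shift_frac_max, cfg$shift_frac_max) * h
    any_affine <- TRUE
  }
  if (cfg$shift_frac_max > 0 && coin()) {
    dx <- stats::runif(1, -cfg$shift_frac_max, cfg$shift_frac_max) * w
    any_affine <- TRUE
  }
  if (cfg$shear_deg_max > 0 && coin()) {
    shear <- stats::runif(1, -cfg$shear_deg_max, cfg$shear_deg_max)
    any_affine <- TRUE
  }
  if (cfg$zoom_frac_max > 0 && coin()) {
    zoom <- stats::runif(1, 1 - cfg$zoom_frac_max, 1 + cfg$zoom_frac_max)
    any_affine <- TRUE
  }
  if (any_affine) {
    th <- theta * pi / 180; sh <- tan(shear * pi / 180)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    shm <- matrix(c(1, 0, sh, 1), 2, 2)
    Tm <- rot %*% shm * zoom                       # output <- Tm input
    A2 <- solve(Tm)                                # inverse map
    ctr <- c((h - 1) / 2, (w - 1) / 2)
    off <- ctr - A2 %*% (ctr + c(dy, dx))
    A <- cbind(A2, off)
    img <- affine_warp_cpp(img, A, 0)
  }
  if (cfg$flip_h && coin()) img <- img[, w:1, , drop = FALSE]
  if (cfg$flip_v && coin()) img <- img[h:1, , , drop = FALSE]
  if (cfg$channel_shift_max > 0 && coin()) {
    shift <- stats::runif(3, -cfg$channel_shift_max, cfg$channel_shift_max) / 255
    for (ch in 1:3) img[, , ch] <- img[, , ch] + shift[ch]
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  if (cfg$erase_frac_max > 0 && coin()) {
    area <- stats::runif(1, 0, cfg$erase_frac_max) * h * w
    aspect <- stats::runif(1, 0.3, 1 / 0.3)
    eh <- max(1L, min(h, as.integer(round(sqrt(area * aspect)))))
    ew <- max(1L, min(w, as.integer(round(sqrt(area / aspect)))))
    r0 <- sample.int(h - eh + 1L, 1L)
    c0 <- sample.int(w - ew + 1L, 1L)
    img[r0:(r0 + eh - 1L), c0:(c0 + ew - 1L), ] <-
      stats::runif(eh * ew * 3L)
  }
  img
}
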