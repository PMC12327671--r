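# RGB composition of extracted components: fixed palette colours for
# skull, matter and CSF; adaptive red for hemorrhage.

#' Adaptive red channel for hemorrhage pixels
#'
#' Maps the HU of each in-mask hemorrhage pixel to a red intensity
#' \deqn{r = H'(i,j)\,\bigl|\,255 - \tfrac{200}{cap - \min(\hat H)}
#'       (P(i,j) - \min(\hat H))\,\bigr|}
#' so that fresh, low-HU blood at the region minimum renders at full red
#' (255) and the densest admissible blood at the 110-HU cap renders at 55
#' -- dark red kept separated from black. Off-mask pixels are 0.
#'
#' @param P HU matrix.
#' @param Hp Hemorrhage mask \eqn{H'}.
#' @param min_hu Minimum HU of the suspect hemorrhage region.
#' @param hu_cap Upper HU bound for hemorrhage, default 110.
#' @param check_range Assert that in-mask HU lies in
#'   \code{[min_hu, hu_cap]} (always true when the extraction thresholds
#'   are enabled). Set \code{FALSE} for ablation runs, where the raw
#'   absolute-value formula is used and the result is clamped to
#'   \eqn{[0, 255]} only for display validity.
#' @return Integer matrix of red intensities; in-mask values lie in
#'   \eqn{[55, 255]} for HU within \code{[min_hu, hu_cap]}.
#' @export
adaptive_red <- function(P, Hp, min_hu, hu_cap = 110, check_range = TRUE) {
  if (!all(dim(P) == dim(Hp)))
    stop("shape mismatch between image and mask", call. = FALSE)
  if (!is.finite(min_hu) || min_hu >= hu_cap)
    stop("degenerate red scale: min_hu must be below the HU cap",
         call. = FALSE)
  inmask <- Hp > 0
  if (check_range && any(inmask) &&
      (any(P[inmask] < min_hu) || any(P[inmask] > hu_cap)))
    stop("in-mask HU outside [min_hu, hu_cap]; this cannot occur when the ",
         "extraction thresholds are enabled", call. = FALSE)
  r <- round_half_up(abs(255 - (200 / (hu_cap - min_hu)) * (P - min_hu)))
  r <- r * (Hp > 0)
  if (!check_range) r <- pmin(pmax(r, 0), 255)
  storage.mode(r) <- "integer"
  dim(r) <- dim(P)
  r
}

paint <- function(chan, mask, value) {
  chan[mask] <- value
  chan
}

new_rgb <- function(nr, nc, bg) {
  array(rep(as.integer(bg), each = nr * nc), dim = c(nr, nc, 3L))
}

#' Full multi-component view
#'
#' Renders every extracted component on black: skull/calcification in
#' gray, white and gray matter in green, CSF in blue-violet, hemorrhage
#' in adaptive red. Overlapping assignments resolve as
#' hemorrhage > skull > CSF > gray matter > white matter, so blood is
#' never occluded.
#'
#' @param comp An \code{\link{extract_components}} result.
#' @param palette An \code{\link{hrt_palette}}; defaults to the one in
#'   \code{comp$config}.
#' @return Integer array \code{(rows, cols, 3)} with channels in
#'   \eqn{[0, 255]}.
#' @export
compose_full_view <- function(comp, palette = NULL) {
  stopifnot(inherits(comp, "hrt_components"))
  pal <- palette %||% comp$config$palette
  nr <- nrow(comp$P); nc <- ncol(comp$P)
  img <- new_rgb(nr, nc, pal$background)
  gm_col <- if (pal$distinct_matter) pal$matter_gm else pal$matter
  # paint lowest precedence first; later layers overwrite
  layers <- list(list(comp$Mhat != 0, pal$matter),
                 list(comp$Ghat != 0, gm_col),
                 list(comp$Chat != 0, pal$csf),
                 list(comp$K > 0,     pal$skull))
  for (ly in layers)
    for (ch in 1:3)
      img[, , ch] <- paint(img[, , ch], ly[[1]], as.integer(ly[[2]][ch]))
  img <- paint_hemorrhage(img, comp)
  img
}

paint_hemorrhage <- function(img, comp) {
  hp <- comp$Hp > 0
  if (!any(hp)) return(img)
  r <- adaptive_red(comp$P, comp$Hp, comp$min_hu,
                    comp$config$caps$hemorrhage_hu,
                    check_range = comp$config$thresholds_enabled)
  img[, , 1] <- paint(img[, , 1], hp, r[hp])
  img[, , 2] <- paint(img[, , 2], hp, 0L)
  img[, , 3] <- paint(img[, , 3], hp, 0L)
  img
}

#' Skull-plus-hemorrhage view for classifier input
#'
#' Renders only the skull (gray) and the adaptive-red hemorrhage on
#' black, giving a classifier the bleeding location relative to the
#' skull without parenchymal clutter.
#'
#' @inheritParams compose_full_view
#' @return Integer array \code{(rows, cols, 3)}.
#' @export
compose_dnn_view <- function(comp, palette = NULL) {
  stopifnot(inherits(comp, "hrt_components"))
  pal <- palette %||% comp$config$palette
  nr <- nrow(comp$P); nc <- ncol(comp$P)
  img <- new_rgb(nr, nc, pal$background)
  for (ch in 1:3)
    img[, , ch] <- paint(img[, , ch], comp$K > 0, as.integer(pal$skull[ch]))
  paint_hemorrhage(img, comp)
}

#' Hemorrhage overlay on the brain-window grayscale
#'
#' Renders the slice through the standard brain window as a grayscale
#' base (replicated to three channels) and replaces hemorrhage pixels
#' with adaptive red, so a reader sees the bleed in its native anatomical
#' context.
#'
#' @inheritParams compose_full_view
#' @param brain_setting \code{\link{window_setting}} for the base image,
#'   default \code{(80, 40)}.
#' @param tp \code{\link{transfer_params}} for the base image; defaults to
#'   the config's.
#' @return Integer array \code{(rows, cols, 3)}.
#' @export
compose_overlay_view <- function(comp, brain_setting = window_setting(80, 40),
                                 tp = NULL) {
  stopifnot(inherits(comp, "hrt_components"))
  tp <- tp %||% transfer_params(comp$config$transfer$U,
                                comp$config$transfer$eps)
  base <- transform_image(comp$P, brain_setting,
                          comp$config$transfer$method, tp)
  nr <- nrow(base); nc <- ncol(base)
  img <- array(rep(as.integer(base), 3L), dim = c(nr, nc, 3L))
  paint_hemorrhage(img, comp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
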