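# HU-to-intensity transfer functions (windowing).
#
# A window setting (ww, wl) defines the HU range of interest
# [wl - ww/2, wl + ww/2]; a transfer function maps HU values onto display
# intensities. Two transfers are provided: the traditional clamped linear
# map and a sigmoid map that compresses, rather than truncates,
# out-of-range values.

#' Window setting
#'
#' A CT display window: a width/level pair defining the Hounsfield-unit
#' range of interest \code{[wl - ww/2, wl + ww/2]}.
#'
#' @param ww Window width in HU; must be a single finite value > 0.
#' @param wl Window level (centre of the range) in HU; single finite value.
#' @return An object of class \code{"window_setting"}, a list with elements
#'   \code{ww} and \code{wl}.
#' @examples
#' window_setting(80, 40)   # the standard brain window
#' @export
window_setting <- function(ww, wl) {
  if (!is.numeric(ww) || length(ww) != 1L || !is.finite(ww) || ww <= 0)
    stop("`ww` must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(wl) || length(wl) != 1L || !is.finite(wl))
    stop("`wl` must be a single finite number", call. = FALSE)
  structure(list(ww = as.numeric(ww), wl = as.numeric(wl)),
            class = "window_setting")
}

#' @export
print.window_setting <- function(x, ...) {
  cat(sprintf("<window_setting> ww = %g HU, wl = %g HU (range [%g, %g])\n",
              x$ww, x$wl, x$wl - x$ww / 2, x$wl + x$ww / 2))
  invisible(x)
}

#' Sigmoid transfer parameters
#'
#' Parameters of the sigmoid intensity transfer: the upper intensity limit
#' \code{U} and the margin \code{eps} by which the sigmoid approaches its
#' limits at the window edges (the transfer maps \code{wl - ww/2} to
#' \code{eps} and \code{wl + ww/2} to \code{U - eps}).
#'
#' @param U Upper intensity limit; default 255 (8-bit display).
#' @param eps Margin between the curve and its limits at the window edges,
#'   in intensity units; must satisfy \code{0 < eps < U/2}. Default 1.
#' @return An object of class \code{"transfer_params"}.
#' @export
transfer_params <- function(U = 255, eps = 1.0) {
  if (!is.numeric(U) || length(U) != 1L || !is.finite(U) || U <= 0)
    stop("`U` must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) ||
      eps <= 0 || eps >= U / 2)
    stop("`eps` must satisfy 0 < eps < U/2", call. = FALSE)
  structure(list(U = as.numeric(U), eps = as.numeric(eps)),
            class = "transfer_params")
}

#' Hounsfield-unit image
#'
#' Validates a numeric matrix of CT numbers as a single-slice HU image.
#' Values must be finite and within the plausible CT range
#' \eqn{[-1100, 3100]}; anything else is rejected at ingest.
#'
#' @param values Numeric matrix of HU values.
#' @return The validated matrix (storage mode double), invisibly classed as
#'   a plain matrix.
#' @export
hu_image <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("HU image must be a numeric matrix", call. = FALSE)
  if (length(values) == 0L)
    stop("HU image is empty", call. = FALSE)
  if (any(!is.finite(values)))
    stop("HU image contains non-finite values", call. = FALSE)
  if (any(values < -1100 | values > 3100))
    stop("HU values outside the plausible CT range [-1100, 3100]",
         call. = FALSE)
  storage.mode(values) <- "double"
  values
}

# round-half-up, fixed for reproducibility (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Traditional windowing transform
#'
#' Clamped linear map of HU onto \eqn{[0, 255]}: values below the window
#' range map to 0, values above to 255, and values inside are interpolated
#' linearly (rounded half-up).
#'
#' @param h HU value(s); numeric vector or matrix, all finite.
#' @param s A \code{\link{window_setting}}.
#' @return Integer intensities in \eqn{[0, 255]}, same shape as \code{h}.
#' @examples
#' s <- window_setting(80, 40)
#' traditional_transform(c(-50, 40, 200), s)  # 0 128 255
#' @export
traditional_transform <- function(h, s) {
  stopifnot(inherits(s, "window_setting"))
  if (!is.numeric(h) || length(h) == 0L)
    stop("`h` must be numeric", call. = FALSE)
  if (any(!is.finite(h)))
    stop("non-finite HU value: corrupt input", call. = FALSE)
  lo <- s$wl - s$ww / 2
  v <- round_half_up(255 * (h - lo) / s$ww)
  v <- pmin(pmax(v, 0), 255)
  storage.mode(v) <- "integer"
  if (is.matrix(h)) dim(v) <- dim(h)
  v
}

#' Sigmoid windowing transform
#'
#' Continuous sigmoid map of HU onto \eqn{(0, U)}:
#' \deqn{f(h) = U / (1 + \exp(-(2(h - l)/w)\,\ln(U/\epsilon - 1)))}
#' so that \eqn{f(l - w/2) = \epsilon}, \eqn{f(l) = U/2} and
#' \eqn{f(l + w/2) = U - \epsilon}. Unlike the traditional transform,
#' out-of-range HU values keep a small, strictly monotone response rather
#' than being truncated, which preserves subtle contrast for downstream
#' consumers.
#'
#' @inheritParams traditional_transform
#' @param p A \code{\link{transfer_params}} object.
#' @return Continuous intensities in \eqn{(0, U)}, same shape as \code{h}.
#'   No quantization is applied here; see \code{\link{transform_image}}.
#' @export
sigmoid_transform <- function(h, s, p = transfer_params()) {
  stopifnot(inherits(s, "window_setting"), inherits(p, "transfer_params"))
  if (!is.numeric(h) || length(h) == 0L)
    stop("`h` must be numeric", call. = FALSE)
  if (any(!is.finite(h)))
    stop("non-finite HU value: corrupt input", call. = FALSE)
  k <- log(p$U / p$eps - 1)
  p$U / (1 + exp(-(2 * (h - s$wl) / s$ww) * k))
}

#' Transform a whole HU slice to an 8-bit grayscale image
#'
#' Applies the chosen transfer function elementwise. Sigmoid output is
#' quantized by round-half-up and clamped to \eqn{[0, 255]}; the
#' traditional transform is already integer-valued.
#'
#' @param P HU matrix (validated via \code{\link{hu_image}}).
#' @param s A \code{\link{window_setting}}.
#' @param method \code{"sigmoid"} (default) or \code{"traditional"}.
#' @param p A \code{\link{transfer_params}} (used by the sigmoid).
#' @return Integer matrix of intensities in \eqn{[0, 255]}, same shape
#'   as \code{P}.
#' @export
transform_image <- function(P, s, method = c("sigmoid", "traditional"),
                            p = transfer_params()) {
  method <- match.arg(method)
  P <- hu_image(P)
  if (method == "traditional") {
    g <- traditional_transform(P, s)
  } else {
    g <- round_half_up(sigmoid_transform(P, s, p))
    g <- pmin(pmax(g, 0), 255)
    storage.mode(g) <- "integer"
  }
  dim(g) <- dim(P)
  g
}
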