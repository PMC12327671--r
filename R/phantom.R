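# Synthetic 2D axial head phantom with per-component ground truth, so
# every stage of the pipeline is testable without clinical data.

#' Head-phantom specification
#'
#' Describes a synthetic axial head slice: an elliptical skull ring of
#' bone-range HU, parenchyma split into a white-matter core (~25 HU) and
#' a cortical gray-matter band (~35 HU), ventricular CSF ellipses
#' (0--15 HU), one or more hemorrhage blobs, optional calcifications
#' (> 110 HU), and additive Gaussian noise. All HU defaults follow the
#' accepted ranges for these tissues on non-contrast CT.
#'
#' @param shape \code{c(rows, cols)}, default \code{c(128, 128)}.
#' @param skull List: \code{center} (defaults to the image centre),
#'   \code{axes} outer semi-axes in pixels, \code{thickness} ring width
#'   in pixels, \code{hu_range} uniform HU range, default
#'   \code{c(700, 1200)}.
#' @param wm_hu White-matter HU, default 25.
#' @param gm_hu Gray-matter HU, default 35.
#' @param gm_width Width in pixels of the cortical gray-matter band.
#' @param csf List of ellipses \code{list(center =, axes =)}; CSF pixels
#'   draw HU uniformly from \code{csf_hu_range}, default \code{c(0, 15)}.
#' @param csf_hu_range Uniform HU range for CSF pixels.
#' @param bleeds List of blobs \code{list(center =, radius =, hu =)};
#'   default one 60-HU blob of radius 8, which sits inside the window
#'   sweep \{30..75\} so that window selection is exercised non-trivially.
#' @param calcifications Optional list of blobs with HU > 110; default
#'   none.
#' @param noise_sd Standard deviation of additive zero-mean Gaussian
#'   noise in HU; default 0 (noise-free).
#' @param seed Integer seed controlling the CSF draw, skull texture and
#'   noise; default 1.
#' @return A validated list of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(shape = c(128, 128),
                         skull = list(center = NULL, axes = NULL,
                                      thickness = 6,
                                      hu_range = c(700, 1200)),
                         wm_hu = 25, gm_hu = 35, gm_width = 8,
                         csf = NULL, csf_hu_range = c(0, 15),
                         bleeds = NULL, calcifications = list(),
                         noise_sd = 0, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 32L))
  ctr <- skull$center %||% (shape + 1) / 2
  axes <- skull$axes %||% (0.44 * shape)
  skull <- list(center = ctr, axes = axes,
                thickness = skull$thickness %||% 6,
                hu_range = skull$hu_range %||% c(700, 1200))
  if (is.null(csf))
    csf <- list(
      list(center = ctr + c(-6, -11), axes = c(11, 5)),
      list(center = ctr + c(-6,  11), axes = c(11, 5)))
  if (is.null(bleeds))
    bleeds <- list(list(center = ctr + c(18, -14), radius = 8, hu = 60))
  stopifnot(noise_sd >= 0)
  structure(list(shape = shape, skull = skull, wm_hu = wm_hu,
                 gm_hu = gm_hu, gm_width = gm_width, csf = csf,
                 csf_hu_range = csf_hu_range, bleeds = bleeds,
                 calcifications = calcifications, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# centre-of-pixel inclusion test for an axis-aligned ellipse
ellipse_mask <- function(shape, center, axes) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  ((r - center[1L]) / axes[1L])^2 + ((c - center[2L]) / axes[2L])^2 <= 1
}

disk_mask <- function(shape, center, radius) {
  ellipse_mask(shape, center, c(radius, radius))
}

#' Generate a head phantom with ground truth
#'
#' Paints components in a fixed order (background, white matter, gray
#' matter, CSF, bleeds, calcifications, skull ring), each later layer
#' overwriting earlier ones, so the returned ground-truth masks are
#' pairwise disjoint by construction. Background is air at -1000 HU.
#' Deterministic given \code{spec$seed}.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return List with \code{hu} (HU matrix), \code{truth} (list of
#'   \{0, 1\} masks: \code{skull}, \code{wm}, \code{gm}, \code{csf},
#'   \code{bleed}, \code{calcification}) and \code{spec}.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  sk <- spec$skull
  outer <- ellipse_mask(shape, sk$center, sk$axes)
  inner <- ellipse_mask(shape, sk$center, sk$axes - sk$thickness)
  ring <- outer & !inner
  gm_band <- inner & !ellipse_mask(shape, sk$center,
                                   sk$axes - sk$thickness - spec$gm_width)
  wm_core <- inner & !gm_band

  # ownership raster: later paints overwrite earlier
  own <- matrix("bg", shape[1L], shape[2L])
  own[wm_core] <- "wm"
  own[gm_band] <- "gm"
  for (e in spec$csf) {
    m <- ellipse_mask(shape, e$center, e$axes)
    if (any(m & !inner))
      stop("phantom spec error: CSF region extends outside the skull",
           call. = FALSE)
    own[m] <- "csf"
  }
  # strict containment: every bleed pixel inside the inner skull boundary
  for (b in spec$bleeds) {
    m <- disk_mask(shape, b$center, b$radius)
    if (any(m & !inner))
      stop("phantom spec error: bleed extends outside the skull interior",
           call. = FALSE)
    own[m] <- "bleed"
  }
  for (cc in spec$calcifications) {
    m <- disk_mask(shape, cc$center, cc$radius)
    if (any(m & !inner))
      stop("phantom spec error: calcification outside the skull interior",
           call. = FALSE)
    own[m] <- "calc"
  }
  own[ring] <- "skull"

  hu <- matrix(-1000, shape[1L], shape[2L])
  hu[own == "wm"] <- spec$wm_hu
  hu[own == "gm"] <- spec$gm_hu
  n_csf <- sum(own == "csf")
  hu[own == "csf"] <- stats::runif(n_csf, spec$csf_hu_range[1L],
                                   spec$csf_hu_range[2L])
  for (b in spec$bleeds) {
    m <- disk_mask(shape, b$center, b$radius) & own == "bleed"
    hu[m] <- b$hu
  }
  for (cc in spec$calcifications) {
    m <- disk_mask(shape, cc$center, cc$radius) & own == "calc"
    hu[m] <- cc$hu
  }
  n_sk <- sum(own == "skull")
  hu[own == "skull"] <- stats::runif(n_sk, sk$hu_range[1L],
                                     sk$hu_range[2L])
  if (spec$noise_sd > 0)
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sd)
  hu <- pmin(pmax(hu, -1050), 3090)   # keep ingest-valid under noise

  truth <- lapply(c(skull = "skull", wm = "wm", gm = "gm", csf = "csf",
                    bleed = "bleed", calcification = "calc"),
                  function(k) (own == k) * 1L)
  list(hu = hu_image(hu), truth = truth, spec = spec)
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; defined as 1 when both masks are
#' empty.
#'
#' @param A,B \{0, 1\} matrices of equal shape.
#' @return Numeric in \eqn{[0, 1]}.
#' @export
dice <- function(A, B) {
  if (!all(dim(A) == dim(B)))
    stop("shape mismatch between masks", call. = FALSE)
  a <- A != 0; b <- B != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}
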