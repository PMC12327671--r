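# Component extraction: initial masks under predefined windows, automatic
# hemorrhage-window selection by boundary-point tracking, and the
# hemorrhage / CSF / white-matter / gray-matter suspect regions.
#
# A "suspect region" is a matrix whose nonzero entries carry the HU value
# of pixels provisionally assigned to a component; a binary mask is its
# support.

#' Binarize an 8-bit grayscale image
#'
#' Pixels with intensity strictly greater than \code{threshold} become 1,
#' all others 0. The strict inequality matters: the sigmoid transfer maps
#' the window level itself to intensity 128, which is excluded.
#'
#' @param gray Integer matrix of intensities in \eqn{[0, 255]}.
#' @param threshold Cut value, default 128.
#' @return Integer \{0, 1\} matrix of the same shape.
#' @export
binarize <- function(gray, threshold = 128) {
  stopifnot(is.matrix(gray), is.numeric(gray))
  m <- (gray > threshold) * 1L
  dim(m) <- dim(gray)
  m
}

#' Initial hemorrhage masks over the window-level sweep
#'
#' For each level \code{l} in the sweep, the slice is passed through the
#' sigmoid transfer under the narrow window \code{(ww, l)} and binarized,
#' giving the initial hemorrhage candidate mask \eqn{H_l}. Because the
#' transfer is monotone in \eqn{h - l}, the masks shrink as the level
#' rises; the sweep default \{30, 35, ..., 75\} HU with width 10 covers
#' unclotted through clotted blood.
#'
#' @param P HU matrix.
#' @param sweep_wl Ascending vector of at least two window levels (HU).
#' @param ww Common window width (HU), default 10.
#' @param tp \code{\link{transfer_params}}.
#' @param threshold Binarization cut, default 128.
#' @return List of \{0, 1\} masks, one per level, named by level.
#' @export
initial_hemorrhage_masks <- function(P, sweep_wl = seq(30, 75, by = 5),
                                     ww = 10, tp = transfer_params(),
                                     threshold = 128) {
  if (length(sweep_wl) < 2L)
    stop("window selection needs at least 2 sweep levels", call. = FALSE)
  if (is.unsorted(sweep_wl, strictly = TRUE))
    stop("sweep levels must be sorted ascending", call. = FALSE)
  P <- hu_image(P)
  masks <- lapply(sweep_wl, function(l)
    binarize(transform_image(P, window_setting(ww, l), "sigmoid", tp),
             threshold))
  names(masks) <- as.character(sweep_wl)
  masks
}

#' Skull-and-calcium mask
#'
#' Binarized sigmoid transform under the bone-ish window (default width
#' 100 at level 135, i.e. HU range \eqn{[85, 185]} and beyond via the
#' sigmoid tail), capturing skull and intracranial calcifications.
#'
#' @inheritParams initial_hemorrhage_masks
#' @param setting \code{\link{window_setting}}, default \code{(100, 135)}.
#' @return \{0, 1\} mask \eqn{K}.
#' @export
skull_mask <- function(P, setting = window_setting(100, 135),
                       tp = transfer_params(), threshold = 128) {
  binarize(transform_image(P, setting, "sigmoid", tp), threshold)
}

#' White-and-gray-matter mask
#'
#' Binarized sigmoid transform under the standard brain window (default
#' width 80 at level 40), the mask \eqn{M} used as an excluder when
#' deriving the CSF and matter suspect regions.
#'
#' @inheritParams skull_mask
#' @return \{0, 1\} mask \eqn{M}.
#' @export
matter_mask <- function(P, setting = window_setting(80, 40),
                        tp = transfer_params(), threshold = 128) {
  binarize(transform_image(P, setting, "sigmoid", tp), threshold)
}

#' Hemorrhage suspect region (per sweep level)
#'
#' \eqn{\hat H_l(i,j) = |K(i,j) - H_l(i,j)| \cdot f(P(i,j))} with
#' \eqn{f(P) = P} for \eqn{P \le} \code{hu_cap} and 0 otherwise: a pixel
#' masked in both the candidate and the skull mask is excluded, and HU
#' above the cap (not hemorrhage: bone, calcium) is zeroed.
#'
#' @param P HU matrix.
#' @param H_l Initial hemorrhage mask at one sweep level.
#' @param K Skull mask.
#' @param hu_cap Upper HU bound for hemorrhage, default 110.
#' @param strict_containment Use \code{H_l * (1 - K)} instead of the
#'   literal \code{|K - H_l|}; the two differ only on skull-only pixels,
#'   which the cap removes anyway for real bone HU.
#' @param thresholds_enabled If \code{FALSE} the cap is dropped (ablation).
#' @return Suspect-region matrix \eqn{\hat H_l} (0 = background,
#'   nonzero = the pixel's HU).
#' @export
suspect_hemorrhage <- function(P, H_l, K, hu_cap = 110,
                               strict_containment = FALSE,
                               thresholds_enabled = TRUE) {
  if (!all(dim(P) == dim(H_l)) || !all(dim(P) == dim(K)))
    stop("shape mismatch between image and masks", call. = FALSE)
  mult <- if (strict_containment) H_l * (1 - K) else abs(K - H_l)
  keep <- if (thresholds_enabled) (P <= hu_cap) else TRUE
  mult * P * keep
}

#' CSF suspect region
#'
#' \eqn{\hat C(i,j) = |M(i,j) - H'(i,j)| \cdot f(P(i,j))} with
#' \eqn{f(P) = P} for \eqn{P \le} \code{csf_cap} (default 15 HU, the upper
#' edge of cerebrospinal fluid) and 0 otherwise.
#'
#' @param P HU matrix.
#' @param M Matter mask.
#' @param Hp Selected hemorrhage mask \eqn{H'}.
#' @param csf_cap Upper HU bound for CSF, default 15.
#' @param thresholds_enabled If \code{FALSE} the cap is dropped.
#' @return Suspect-region matrix \eqn{\hat C}.
#' @export
csf_region <- function(P, M, Hp, csf_cap = 15, thresholds_enabled = TRUE) {
  if (!all(dim(P) == dim(M)) || !all(dim(P) == dim(Hp)))
    stop("shape mismatch between image and masks", call. = FALSE)
  keep <- if (thresholds_enabled) (P <= csf_cap) else TRUE
  abs(M - Hp) * P * keep
}

#' White-matter suspect region
#'
#' \eqn{\hat M(i,j) = |M(i,j) - H'(i,j)| \cdot f(P(i,j))} with
#' \eqn{f(P) = P} for \eqn{a \le P \le b/2}, where \code{a} is the matter
#' floor (15 HU) and \code{b} the minimum HU of the selected hemorrhage
#' region. If \code{b <= a} the region is empty.
#'
#' @inheritParams csf_region
#' @param a Lower HU bound, default 15.
#' @param b Upper bound anchor: minimum HU of the selected hemorrhage
#'   region (fallback 40 when no hemorrhage was found).
#' @return Suspect-region matrix \eqn{\hat M}.
#' @export
white_matter_region <- function(P, M, Hp, a = 15, b,
                                thresholds_enabled = TRUE) {
  if (!all(dim(P) == dim(M)) || !all(dim(P) == dim(Hp)))
    stop("shape mismatch between image and masks", call. = FALSE)
  if (thresholds_enabled && b <= a) return(P * 0)
  keep <- if (thresholds_enabled) (P >= a & P <= b / 2) else TRUE
  abs(M - Hp) * P * keep
}

#' Gray-matter suspect region
#'
#' As \code{\link{white_matter_region}} but over the complementary HU
#' range \eqn{b/2 < P \le b} (strict lower bound).
#'
#' @inheritParams white_matter_region
#' @return Suspect-region matrix \eqn{\hat G}.
#' @export
gray_matter_region <- function(P, M, Hp, b, thresholds_enabled = TRUE) {
  if (!all(dim(P) == dim(M)) || !all(dim(P) == dim(Hp)))
    stop("shape mismatch between image and masks", call. = FALSE)
  if (thresholds_enabled && b <= 0) return(P * 0)
  keep <- if (thresholds_enabled) (P > b / 2 & P <= b) else TRUE
  abs(M - Hp) * P * keep
}

# ---- connected components and boundary tracing --------------------------

# 8-connected labeling of a logical/0-1 matrix via graph components.
# Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  fg <- which(mask != 0)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(fg) == 0L) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% nr) + 1L
  c <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  # half the 8-neighbourhood suffices for an undirected graph
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + off[1L]; cc <- c + off[2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!any(ok)) next
    nb <- id[cbind(rr[ok], cc[ok])]
    hit <- nb > 0L
    if (any(hit))
      edges <- c(edges, rbind(id[fg][ok][hit], nb[hit]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb)
  lab
}

# pick the label of the largest component; ties by the smallest row-major
# (row-first) pixel index of the component
largest_component_label <- function(lab) {
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    rowmajor <- function(k) {
      idx <- which(lab == k)
      r <- ((idx - 1L) %% nr); c <- ((idx - 1L) %/% nr)
      min(r * nc + c)
    }
    best <- best[which.min(vapply(best, rowmajor, numeric(1)))]
  }
  best[1L]
}

# iso-contour (marching squares) vertices of a 0/1 matrix at level 0.5;
# returns the longest closed contour (the outer boundary)
trace_isocontour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- mask
  cl <- grDevices::contourLines(x = seq_len(nr + 2L), y = seq_len(nc + 2L),
                                z = z, levels = 0.5)
  if (length(cl) == 0L) return(numeric(0))
  lens <- vapply(cl, function(k) length(k$x), integer(1))
  k <- cl[[which.max(lens)]]
  cbind(row = k$x - 1, col = k$y - 1)
}

# morphological active contour (Chan-Vese flavour) refinement of the
# largest-component mask against the suspect region's HU values, followed
# by iso-contour tracing of the converged mask
dilate3 <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  z <- matrix(0, nr + 2L, nc + 2L); z[2:(nr + 1L), 2:(nc + 1L)] <- u
  out <- u
  for (dr in -1:1) for (dc in -1:1)
    out <- pmax(out, z[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  out
}
erode3 <- function(u) 1 - dilate3(1 - u)

morph_acwe <- function(img, init, iterations = 5) {
  u <- init
  for (i in seq_len(iterations)) {
    inside <- u > 0
    if (!any(inside) || all(inside)) break
    c1 <- mean(img[inside]); c0 <- mean(img[!inside])
    u <- ((img - c1)^2 < (img - c0)^2) * 1
    # alternating open/close approximates curvature smoothing
    u <- if (i %% 2 == 0) dilate3(erode3(u)) else erode3(dilate3(u))
  }
  u
}

#' Boundary-point count of a suspect region
#'
#' Binarizes the region (nonzero to 1), keeps its largest 8-connected
#' component (ties broken by the smallest row-major anchor pixel), traces
#' that component's closed outer boundary, and returns the number of
#' boundary points. The default tracer is the level-0.5 iso-contour
#' (marching squares), which is deterministic and parameter-free; a
#' morphological active-contour refinement against the region's HU values
#' is available as \code{method = "morph_acwe"}.
#'
#' @param region Suspect-region matrix (nonzero entries = HU values).
#' @param method \code{"isocontour"} (default) or \code{"morph_acwe"}.
#' @param acwe_iterations Iterations for the active-contour mode.
#' @return Non-negative integer; 0 for an empty region.
#' @export
boundary_point_count <- function(region,
                                 method = c("isocontour", "morph_acwe"),
                                 acwe_iterations = 5) {
  method <- match.arg(method)
  mask <- (region != 0) * 1L
  if (!any(mask > 0L)) return(0L)
  lab <- label_components(mask)
  keep <- (lab == largest_component_label(lab)) * 1
  if (method == "morph_acwe") {
    keep <- morph_acwe(region, keep, acwe_iterations)
    if (!any(keep > 0)) return(0L)
  }
  nrow(trace_isocontour(keep))
}

# ---- window selection ---------------------------------------------------

#' Build a hemorrhage window sweep
#'
#' Bundles the per-level window settings, suspect regions and their
#' boundary-point counts into a sweep object ready for
#' \code{\link{select_hemorrhage_window}}.
#'
#' @param settings List of \code{\link{window_setting}} objects, ascending
#'   in level.
#' @param regions List of suspect-region matrices, one per setting.
#' @param boundary_counts Integer vector of boundary-point counts.
#' @return An object of class \code{"hemorrhage_sweep"}.
#' @export
hemorrhage_sweep <- function(settings, regions, boundary_counts) {
  n <- length(settings)
  if (n < 2L || length(regions) != n || length(boundary_counts) != n)
    stop("sweep lists must share one length >= 2", call. = FALSE)
  if (any(boundary_counts < 0))
    stop("boundary counts must be non-negative", call. = FALSE)
  structure(list(settings = settings, regions = regions,
                 boundary_counts = as.integer(boundary_counts),
                 selected_index = NA_integer_, min_hu = NA_real_,
                 Hp = NULL),
            class = "hemorrhage_sweep")
}

#' Select the hemorrhage window from a sweep
#'
#' Scans consecutive pairs of the sweep from low to high level and finds
#' the largest \emph{decrease} in boundary-point count; the region after
#' that drop is the hemorrhage ROI. A large drop marks the level at which
#' a big low-HU structure falls out of the candidate mask, leaving the
#' denser blood. Ties go to the earliest pair. If no pair shows a positive
#' decrease (or every region is empty) the slice is declared
#' hemorrhage-free: no index is selected and \eqn{H'} is all-zero.
#'
#' @param sweep A \code{\link{hemorrhage_sweep}} with counts populated.
#' @return The sweep with \code{selected_index} (1-based index into the
#'   sweep, always \eqn{\ge 2}), \code{min_hu} (minimum of the selected
#'   region's positive entries, or \code{NA}) and the mask \code{Hp}
#'   (\eqn{H'}) filled in.
#' @export
select_hemorrhage_window <- function(sweep) {
  stopifnot(inherits(sweep, "hemorrhage_sweep"))
  counts <- sweep$boundary_counts
  n <- length(counts)
  drops <- counts[-n] - counts[-1L]
  shape <- dim(sweep$regions[[1L]])
  if (all(drops <= 0)) {
    sweep$selected_index <- NA_integer_
    sweep$min_hu <- NA_real_
    sweep$Hp <- matrix(0L, shape[1L], shape[2L])
    return(sweep)
  }
  s <- which.max(drops)            # first maximum = smallest pair index
  sel <- s + 1L
  region <- sweep$regions[[sel]]
  pos <- region > 0
  sweep$selected_index <- sel
  sweep$min_hu <- if (any(pos)) min(region[pos]) else NA_real_
  sweep$Hp <- pos * 1L
  sweep
}

#' @export
print.hemorrhage_sweep <- function(x, ...) {
  lv <- vapply(x$settings, function(s) s$wl, numeric(1))
  cat("<hemorrhage_sweep>\n  levels: ", paste(lv, collapse = " "),
      "\n  boundary counts: ", paste(x$boundary_counts, collapse = " "),
      "\n", sep = "")
  if (is.na(x$selected_index)) {
    cat("  no hemorrhage window selected\n")
  } else {
    cat(sprintf("  selected: index %d (wl = %g), min HU = %g\n",
                x$selected_index, lv[x$selected_index], x$min_hu))
  }
  invisible(x)
}

# ---- orchestration ------------------------------------------------------

#' Extract all brain components from one CT slice
#'
#' Runs the full component-extraction pipeline: skull and matter masks,
#' the hemorrhage window sweep with boundary-point tracking and window
#' selection, then the CSF, white-matter and gray-matter suspect regions
#' anchored at \eqn{b = \min(\hat H)} (falling back to
#' \code{config$fallback_b} when no hemorrhage is found). The pipeline is
#' fully deterministic.
#'
#' @param P HU matrix for one slice.
#' @param config An \code{\link{hrt_config}}.
#' @return An object of class \code{"hrt_components"}: a list with the
#'   slice \code{P}, masks \code{K} and \code{M}, the \code{sweep}
#'   (including \code{Hp}, i.e. \eqn{H'}), the selected suspect region
#'   \code{Hhat}, regions \code{Chat}, \code{Mhat}, \code{Ghat},
#'   \code{min_hu}, the matter anchor \code{b}, and the \code{config}.
#' @export
extract_components <- function(P, config = hrt_config()) {
  stopifnot(inherits(config, "hrt_config"))
  P <- hu_image(P)
  tp <- transfer_params(config$transfer$U, config$transfer$eps)
  thr <- config$boundary$threshold

  K <- skull_mask(P, window_setting(config$skull$ww, config$skull$wl),
                  tp, thr)
  M <- matter_mask(P, window_setting(config$matter$ww, config$matter$wl),
                   tp, thr)

  wl <- config$sweep$wl_list
  H_l <- initial_hemorrhage_masks(P, wl, config$sweep$ww, tp, thr)
  regions <- lapply(H_l, function(h)
    suspect_hemorrhage(P, h, K, config$caps$hemorrhage_hu,
                       config$strict_containment,
                       config$thresholds_enabled))
  counts <- vapply(regions, boundary_point_count,
                   integer(1), method = config$boundary$method,
                   acwe_iterations = config$boundary$acwe_iterations)
  settings <- lapply(wl, function(l) window_setting(config$sweep$ww, l))
  sweep <- select_hemorrhage_window(
    hemorrhage_sweep(settings, regions, counts))

  Hp <- sweep$Hp
  min_hu <- sweep$min_hu
  b <- if (is.na(min_hu)) config$fallback_b else min_hu
  Hhat <- if (is.na(sweep$selected_index)) P * 0
          else sweep$regions[[sweep$selected_index]]

  Chat <- csf_region(P, M, Hp, config$caps$csf_hu,
                     config$thresholds_enabled)
  Mhat <- white_matter_region(P, M, Hp, config$caps$wm_min_hu, b,
                              config$thresholds_enabled)
  Ghat <- gray_matter_region(P, M, Hp, b, config$thresholds_enabled)

  structure(list(P = P, K = K, M = M, sweep = sweep, Hp = Hp,
                 Hhat = Hhat, Chat = Chat, Mhat = Mhat, Ghat = Ghat,
                 min_hu = min_hu, b = b, config = config),
            class = "hrt_components")
}

#' @export
print.hrt_components <- function(x, ...) {
  cat(sprintf("<hrt_components> %d x %d slice\n", nrow(x$P), ncol(x$P)))
  print(x$sweep)
  cat(sprintf("  pixels: hemorrhage %d, csf %d, wm %d, gm %d, skull %d\n",
              sum(x$Hp > 0), sum(x$Chat != 0), sum(x$Mhat != 0),
              sum(x$Ghat != 0), sum(x$K > 0)))
  invisible(x)
}
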