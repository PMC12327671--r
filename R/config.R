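# Pipeline configuration: defaults, YAML loading, validation.

#' Default colour palette for rendered views
#'
#' Fixed RGB colours for the non-hemorrhage components. Hemorrhage is not
#' in the palette because its red channel is assigned adaptively from HU
#' (see \code{\link{adaptive_red}}).
#'
#' @param skull RGB triple for skull/calcification pixels.
#' @param matter RGB triple for white and gray matter.
#' @param csf RGB triple for cerebrospinal fluid.
#' @param background RGB triple for everything else.
#' @param distinct_matter If \code{TRUE}, gray matter is drawn with
#'   \code{matter_gm} instead of sharing the matter green.
#' @param matter_gm RGB triple used for gray matter when
#'   \code{distinct_matter} is \code{TRUE}.
#' @return A named list of RGB triples, class \code{"hrt_palette"}.
#' @export
hrt_palette <- function(skull = c(155, 155, 155),
                        matter = c(0, 145, 0),
                        csf = c(25, 25, 145),
                        background = c(0, 0, 0),
                        distinct_matter = FALSE,
                        matter_gm = c(0, 190, 0)) {
  pal <- list(skull = skull, matter = matter, csf = csf,
              background = background,
              distinct_matter = isTRUE(distinct_matter),
              matter_gm = matter_gm)
  for (nm in c("skull", "matter", "csf", "background", "matter_gm")) {
    v <- pal[[nm]]
    if (!is.numeric(v) || length(v) != 3L || any(v < 0 | v > 255))
      stop("palette entry `", nm, "` must be 3 channel values in [0, 255]",
           call. = FALSE)
  }
  structure(pal, class = "hrt_palette")
}

#' Pipeline configuration
#'
#' Assembles the full set of tunable parameters for component extraction
#' and rendering. All defaults follow the method's published operating
#' point: a narrow sweep of brain windows (width 10 HU, levels 30--75 in
#' steps of 5) for hemorrhage, the standard brain window (80, 40) for
#' matter, (100, 135) for skull/calcium, binarization threshold 128, and
#' HU caps of 110 (hemorrhage), 15 (CSF) and a white-matter floor of 15.
#'
#' @param transfer List: \code{method} ("sigmoid"/"traditional"),
#'   \code{U}, \code{eps}.
#' @param sweep List: \code{ww} and ascending \code{wl_list} for the
#'   hemorrhage window sweep.
#' @param skull,matter Lists with \code{ww}, \code{wl} for the skull and
#'   matter masks.
#' @param caps List: \code{hemorrhage_hu}, \code{csf_hu}, \code{wm_min_hu}.
#' @param selection List: \code{mode} (only \code{"largest_drop"}),
#'   \code{tie_break} (only \code{"first"}).
#' @param fallback_b HU used as the upper matter bound \code{b} when no
#'   hemorrhage is found (default 40, the upper edge of normal parenchyma).
#' @param boundary List: \code{method} ("isocontour" or "morph_acwe"),
#'   \code{acwe_iterations}, \code{threshold} (binarization cut, 128).
#' @param strict_containment Use \code{H_l AND NOT K} instead of the
#'   literal \code{|K - H_l|} when building the hemorrhage suspect region.
#' @param thresholds_enabled If \code{FALSE}, drop the HU caps in all four
#'   region equations (the ablation toggle).
#' @param palette A \code{\link{hrt_palette}}.
#' @return A validated list of class \code{"hrt_config"}.
#' @export
hrt_config <- function(transfer = list(method = "sigmoid", U = 255, eps = 1.0),
                       sweep = list(ww = 10, wl_list = seq(30, 75, by = 5)),
                       skull = list(ww = 100, wl = 135),
                       matter = list(ww = 80, wl = 40),
                       caps = list(hemorrhage_hu = 110, csf_hu = 15,
                                   wm_min_hu = 15),
                       selection = list(mode = "largest_drop",
                                        tie_break = "first"),
                       fallback_b = 40,
                       boundary = list(method = "isocontour",
                                       acwe_iterations = 5,
                                       threshold = 128),
                       strict_containment = FALSE,
                       thresholds_enabled = TRUE,
                       palette = hrt_palette()) {
  cfg <- list(transfer = transfer, sweep = sweep, skull = skull,
              matter = matter, caps = caps, selection = selection,
              fallback_b = fallback_b, boundary = boundary,
              strict_containment = isTRUE(strict_containment),
              thresholds_enabled = isTRUE(thresholds_enabled),
              palette = palette)
  validate_hrt_config(cfg)
}

validate_hrt_config <- function(cfg) {
  stopifnot(cfg$transfer$method %in% c("sigmoid", "traditional"))
  # constructors run the per-field checks
  transfer_params(cfg$transfer$U, cfg$transfer$eps)
  window_setting(cfg$skull$ww, cfg$skull$wl)
  window_setting(cfg$matter$ww, cfg$matter$wl)
  wl <- cfg$sweep$wl_list
  if (length(wl) < 2L) stop("sweep needs at least 2 window levels",
                            call. = FALSE)
  if (is.unsorted(wl, strictly = TRUE))
    stop("sweep levels must be strictly ascending", call. = FALSE)
  if (cfg$sweep$ww <= 0) stop("sweep ww must be > 0", call. = FALSE)
  stopifnot(cfg$caps$hemorrhage_hu > 0,
            cfg$caps$csf_hu > 0,
            cfg$caps$wm_min_hu >= 0,
            cfg$fallback_b > cfg$caps$wm_min_hu)
  if (!cfg$selection$mode %in% "largest_drop")
    stop("unknown selection mode: ", cfg$selection$mode, call. = FALSE)
  if (!cfg$selection$tie_break %in% "first")
    stop("unknown tie_break: ", cfg$selection$tie_break, call. = FALSE)
  if (!cfg$boundary$method %in% c("isocontour", "morph_acwe"))
    stop("unknown boundary method: ", cfg$boundary$method, call. = FALSE)
  if (!inherits(cfg$palette, "hrt_palette"))
    cfg$palette <- do.call(hrt_palette, as.list(cfg$palette))
  structure(cfg, class = "hrt_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the corresponding defaults of
#' \code{\link{hrt_config}}; everything else keeps its default. Nested
#' keys merge (e.g. a file setting only \code{caps: {csf_hu: 20}} keeps
#' the default hemorrhage cap).
#'
#' @param path Path to a YAML file.
#' @return An \code{"hrt_config"} object.
#' @export
read_hrt_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  base <- unclass(hrt_config())
  merged <- modify_list_deep(base, user)
  if (!inherits(merged$palette, "hrt_palette"))
    merged$palette <- do.call(hrt_palette, merged$palette[
      intersect(names(merged$palette),
                names(formals(hrt_palette)))])
  validate_hrt_config(merged)
}

modify_list_deep <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
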