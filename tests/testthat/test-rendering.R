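# RGB composition: adaptive red and the three views.

test_that("adaptive red hits its endpoints and range", {
  P <- matrix(c(110, 10, 60), 1)
  Hp <- matrix(1L, 1, 3)
  r <- adaptive_red(P, Hp, min_hu = 10)
  expect_identical(r[1, 1], 55L)   # densest admissible blood -> dark red
  expect_identical(r[1, 2], 255L)  # region minimum -> full red
  expect_true(all(r >= 55L & r <= 255L))
  # off-mask pixels are zero
  r0 <- adaptive_red(P, matrix(0L, 1, 3), min_hu = 10)
  expect_true(all(r0 == 0L))
  # degenerate scale rejected
  expect_error(adaptive_red(P, Hp, min_hu = 110), "degenerate")
  expect_error(adaptive_red(P, Hp, min_hu = 200), "degenerate")
  # in-mask HU outside [min_hu, cap] is a contract violation
  expect_error(adaptive_red(matrix(120, 1, 1), matrix(1L, 1, 1),
                            min_hu = 10), "in-mask")
})

test_that("adaptive red is non-increasing in HU over the admissible range", {
  hu <- seq(10, 110, by = 0.5)
  r <- adaptive_red(matrix(hu, 1), matrix(1L, 1, length(hu)), min_hu = 10)
  expect_true(all(diff(as.integer(r)) <= 0L))
})

phantom_components <- function(spec = phantom_spec(), config = hrt_config()) {
  ph <- generate_phantom(spec)
  list(ph = ph, comp = extract_components(ph$hu, config))
}

test_that("full view paints palette colours with hemorrhage on top", {
  x <- phantom_components()
  img <- compose_full_view(x$comp)
  expect_identical(dim(img), c(128L, 128L, 3L))
  expect_true(all(img >= 0L & img <= 255L))
  # skull pixels gray
  sk <- x$comp$K == 1L & x$comp$Hp == 0L
  expect_true(all(img[, , 1][sk] == 155L))
  expect_true(all(img[, , 2][sk] == 155L))
  expect_true(all(img[, , 3][sk] == 155L))
  # hemorrhage pixels pure red in [55, 255]
  hp <- x$comp$Hp == 1L
  expect_true(any(hp))
  expect_true(all(img[, , 1][hp] >= 55L))
  expect_true(all(img[, , 2][hp] == 0L))
  expect_true(all(img[, , 3][hp] == 0L))
  # background black
  bg <- x$ph$truth$skull + x$ph$truth$bleed + x$ph$truth$wm +
    x$ph$truth$gm + x$ph$truth$csf + x$ph$truth$calcification
  out <- bg == 0L & x$comp$Hp == 0L
  expect_true(all(img[, , 1][out] == 0L))
  # purity: identical rerun
  expect_identical(img, compose_full_view(x$comp))
})

test_that("hemorrhage wins over skull when masks overlap", {
  # force an overlap by construction
  P <- matrix(60, 8, 8)
  comp <- structure(list(
    P = P, K = matrix(1L, 8, 8), M = matrix(0L, 8, 8),
    sweep = NULL, Hp = matrix(1L, 8, 8), Hhat = P,
    Chat = P * 0, Mhat = P * 0, Ghat = P * 0,
    min_hu = 60, b = 60, config = hrt_config()),
    class = "hrt_components")
  img <- compose_full_view(comp)
  expect_true(all(img[, , 1] == 255L))  # P == min_hu everywhere
  expect_true(all(img[, , 2] == 0L))
  expect_true(all(img[, , 3] == 0L))
})

test_that("fixed palette colours land on the right components", {
  # hand-built components exercising the CSF and matter colours, which a
  # default phantom cannot reach (see the vignette's limitations)
  P <- matrix(c(10, 20, 30, -1000), 2, 2)
  z <- matrix(0L, 2, 2)
  csf <- matrix(c(10, 0, 0, 0), 2, 2)
  wm <- matrix(c(0, 20, 0, 0), 2, 2)
  gm <- matrix(c(0, 0, 30, 0), 2, 2)
  comp <- structure(list(P = P, K = z, M = z, sweep = NULL, Hp = z,
                         Hhat = P * 0, Chat = csf, Mhat = wm, Ghat = gm,
                         min_hu = NA_real_, b = 40, config = hrt_config()),
                    class = "hrt_components")
  img <- compose_full_view(comp)
  expect_identical(img[1, 1, ], c(25L, 25L, 145L))   # CSF
  expect_identical(img[2, 1, ], c(0L, 145L, 0L))     # white matter
  expect_identical(img[1, 2, ], c(0L, 145L, 0L))     # gray matter, shared green
  expect_identical(img[2, 2, ], c(0L, 0L, 0L))       # background
  # distinct-green option separates gray matter
  img2 <- compose_full_view(comp, hrt_palette(distinct_matter = TRUE))
  expect_identical(img2[1, 2, ], c(0L, 190L, 0L))
})

test_that("classifier view shows only skull and hemorrhage", {
  x <- phantom_components()
  img <- compose_dnn_view(x$comp)
  shown <- x$comp$K == 1L | x$comp$Hp == 1L
  expect_true(all(img[, , 1][!shown] == 0L))
  expect_true(all(img[, , 2][!shown] == 0L))
  expect_true(all(img[, , 3][!shown] == 0L))
  hp <- x$comp$Hp == 1L
  expect_true(all(img[, , 1][hp] >= 55L))
  # red blob overlaps the true bleed
  expect_gte(dice((img[, , 1] >= 55 & img[, , 2] == 0) * (x$comp$K == 0),
                  x$ph$truth$bleed), 0.8)
  # all-air slice renders all black
  airc <- extract_components(matrix(-1000, 16, 16))
  expect_true(all(compose_dnn_view(airc) == 0L))
})

test_that("overlay view equals the brain-window base off-mask", {
  x <- phantom_components()
  img <- compose_overlay_view(x$comp)
  base <- transform_image(x$ph$hu, window_setting(80, 40), "sigmoid")
  off <- x$comp$Hp == 0L
  for (ch in 1:3)
    expect_identical(img[, , ch][off], as.integer(base)[off])
  hp <- x$comp$Hp == 1L
  expect_true(all(img[, , 2][hp] == 0L))
  expect_true(all(img[, , 3][hp] == 0L))
  # no hemorrhage: overlay is exactly the replicated grayscale
  airc <- extract_components(matrix(-1000, 16, 16))
  airbase <- transform_image(matrix(-1000, 16, 16), window_setting(80, 40),
                             "sigmoid")
  airimg <- compose_overlay_view(airc)
  for (ch in 1:3)
    expect_identical(unname(airimg[, , ch]), unname(airbase + 0L))
})
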