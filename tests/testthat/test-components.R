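# Component extraction: masks, suspect regions, boundary tracking and
# window selection.

test_that("binarize is strictly greater-than and idempotent", {
  g <- matrix(c(0L, 127L, 128L, 129L, 130L, 255L), 2, 3)
  m <- binarize(g)
  expect_identical(as.integer(m), c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_true(all(binarize(matrix(0L, 4, 4)) == 0L))
  # masks are already {0,1}; re-binarizing at any positive cut below 1 fixes them
  expect_identical(binarize(m * 255L), m)
})

test_that("initial hemorrhage masks shrink as the level rises", {
  # constant slice at 60 HU: all-ones up to level 55, all-zero from 60
  P <- matrix(60, 5, 5)
  mk <- initial_hemorrhage_masks(P)
  allon <- vapply(mk, function(x) all(x == 1L), logical(1))
  expect_identical(unname(allon),
                   c(rep(TRUE, 6), rep(FALSE, 4)))
  # all-air slice: every mask empty
  air <- matrix(-1000, 5, 5)
  expect_true(all(vapply(initial_hemorrhage_masks(air),
                         function(x) all(x == 0L), logical(1))))
  # pointwise non-increasing with level on a random slice
  set.seed(3)
  Q <- random_hu_grid(16, 16)
  mq <- initial_hemorrhage_masks(Q)
  for (i in seq_len(length(mq) - 1L))
    expect_true(all(mq[[i + 1L]] <= mq[[i]]))
  expect_error(initial_hemorrhage_masks(P, sweep_wl = 30), "at least 2")
})

test_that("skull and matter masks respond to the expected HU", {
  P <- matrix(c(1000, 30, 60, 0), 2, 2)
  K <- skull_mask(P)
  M <- matter_mask(P)
  expect_identical(as.integer(K), c(1L, 0L, 0L, 0L))
  expect_identical(as.integer(M), c(1L, 0L, 1L, 0L))
  air <- matrix(-1000, 3, 3)
  expect_true(all(skull_mask(air) == 0L))
  expect_true(all(matter_mask(air) == 0L))
})

test_that("hemorrhage suspect region follows the exclusion equation", {
  one <- matrix(1L, 1, 1); zero <- matrix(0L, 1, 1)
  p70 <- matrix(70, 1, 1); p120 <- matrix(120, 1, 1)
  expect_equal(as.numeric(suspect_hemorrhage(p70, one, one)), 0)
  expect_equal(as.numeric(suspect_hemorrhage(p70, one, zero)), 70)
  expect_equal(as.numeric(suspect_hemorrhage(p120, one, zero)), 0)
  # ablation drops the cap
  expect_equal(as.numeric(
    suspect_hemorrhage(p120, one, zero, thresholds_enabled = FALSE)), 120)
  # strict containment removes skull-only pixels instead of XOR-ing them
  expect_equal(as.numeric(
    suspect_hemorrhage(p70, zero, one, strict_containment = TRUE)), 0)
  expect_error(suspect_hemorrhage(matrix(70, 2, 2), one, one), "shape")
})

test_that("CSF / WM / GM regions follow their HU ranges", {
  one <- matrix(1L, 1, 1); zero <- matrix(0L, 1, 1)
  p <- function(v) matrix(v, 1, 1)
  expect_equal(as.numeric(csf_region(p(10), one, one)), 0)
  expect_equal(as.numeric(csf_region(p(10), one, zero)), 10)
  expect_equal(as.numeric(csf_region(p(20), one, zero)), 0)
  # white matter in [a, b/2], gray matter in (b/2, b], b = 40
  expect_equal(as.numeric(white_matter_region(p(20), one, zero, b = 40)), 20)
  expect_equal(as.numeric(white_matter_region(p(25), one, zero, b = 40)), 0)
  expect_equal(as.numeric(white_matter_region(p(10), one, zero, b = 40)), 0)
  expect_equal(as.numeric(gray_matter_region(p(25), one, zero, b = 40)), 25)
  expect_equal(as.numeric(gray_matter_region(p(20), one, zero, b = 40)), 0)
  expect_equal(as.numeric(gray_matter_region(p(45), one, zero, b = 40)), 0)
  # degenerate anchor: b <= a gives an empty white-matter region
  expect_true(all(white_matter_region(p(20), one, zero, a = 15, b = 10) == 0))
})

test_that("region equations match a naive per-pixel loop on random grids", {
  set.seed(123)
  for (k in 1:20) {
    P <- random_hu_grid(16, 16)
    A <- random_mask(16, 16); B <- random_mask(16, 16)
    b <- runif(1, 20, 100)
    expect_identical(suspect_hemorrhage(P, A, B),
                     loop_suspect_hemorrhage(P, A, B))
    expect_identical(csf_region(P, A, B), loop_csf(P, A, B))
    expect_identical(white_matter_region(P, A, B, b = b),
                     loop_wm(P, A, B, b = b))
    expect_identical(gray_matter_region(P, A, B, b = b),
                     loop_gm(P, A, B, b = b))
  }
})

test_that("suspect regions vanish where the two masks agree", {
  set.seed(5)
  P <- random_hu_grid(24, 24)
  A <- random_mask(24, 24); B <- random_mask(24, 24)
  H <- suspect_hemorrhage(P, A, B)
  expect_true(all(H[A == B] == 0))
  C <- csf_region(P, A, B)
  expect_true(all(C[A == B] == 0))
  # HU caps on the nonzero support
  expect_true(all(H[H != 0] <= 110))
  expect_true(all(C[C != 0] <= 15))
  # WM and GM supports are disjoint (their HU ranges are)
  W <- white_matter_region(P, A, B, b = 60)
  G <- gray_matter_region(P, A, B, b = 60)
  expect_identical(sum(W != 0 & G != 0), 0L)
})

test_that("boundary-point count traces the largest component only", {
  expect_identical(boundary_point_count(matrix(0, 8, 8)), 0L)
  # 10x10 filled square: 10 level-crossings per side plus the closing
  # vertex = 41 marching-squares vertices (hand-traced)
  sq <- matrix(0, 20, 20); sq[6:15, 6:15] <- 50
  expect_identical(boundary_point_count(sq), 41L)
  # adding a smaller second component must not change the count
  two <- sq; two[1:3, 1:3] <- 30
  expect_identical(boundary_point_count(two), 41L)
  # the smaller component alone traces fewer points
  small <- matrix(0, 20, 20); small[1:3, 1:3] <- 30
  expect_lt(boundary_point_count(small), 41L)
  # diagonal pixels are one component under 8-connectivity
  diagm <- matrix(0, 6, 6); diagm[cbind(1:4, 1:4)] <- 1
  labs <- boundary_point_count(diagm)
  expect_gt(labs, 0L)
  # active-contour mode agrees on a clean convex region
  expect_identical(boundary_point_count(sq, method = "morph_acwe"), 41L)
})

test_that("window selection picks the region after the largest drop", {
  shape <- c(4, 4)
  mk_regions <- function(n) replicate(n, matrix(50, shape[1], shape[2]),
                                      simplify = FALSE)
  mk_settings <- function(n) lapply(seq_len(n) * 5 + 25,
                                    function(l) window_setting(10, l))
  sw <- hemorrhage_sweep(mk_settings(5), mk_regions(5),
                         c(400, 390, 380, 120, 110))
  sel <- select_hemorrhage_window(sw)
  expect_identical(sel$selected_index, 4L)  # region after the 380 -> 120 drop
  expect_identical(sel$min_hu, 50)
  expect_true(all(sel$Hp == 1L))

  # all-equal counts: no positive decrease, no hemorrhage
  flat <- select_hemorrhage_window(
    hemorrhage_sweep(mk_settings(4), mk_regions(4), c(50, 50, 50, 50)))
  expect_true(is.na(flat$selected_index))
  expect_true(all(flat$Hp == 0L))
  expect_true(is.na(flat$min_hu))

  # ties break toward the earliest pair
  tie <- select_hemorrhage_window(
    hemorrhage_sweep(mk_settings(4), mk_regions(4), c(50, 10, 50, 45)))
  expect_identical(tie$selected_index, 2L)  # first drop of 40 wins

  expect_error(hemorrhage_sweep(mk_settings(1), mk_regions(1), 3), "length")
  expect_error(hemorrhage_sweep(mk_settings(3), mk_regions(3), c(1, -2, 3)),
               "non-negative")
})

test_that("end-to-end extraction is deterministic and empty on air", {
  air <- matrix(-1000, 32, 32)
  comp <- extract_components(air)
  expect_true(all(comp$K == 0L))
  expect_true(all(comp$Hp == 0L))
  expect_true(all(comp$Chat == 0))
  expect_true(all(comp$Mhat == 0))
  expect_true(all(comp$Ghat == 0))
  expect_identical(comp$b, 40)   # fallback anchor when no hemorrhage

  ph <- generate_phantom(phantom_spec())
  c1 <- extract_components(ph$hu)
  c2 <- extract_components(ph$hu)
  expect_identical(c1$Hp, c2$Hp)
  expect_identical(c1$sweep$boundary_counts, c2$sweep$boundary_counts)
  expect_identical(c1$min_hu, c2$min_hu)
})

test_that("phantom hemorrhage is recovered by the selected window", {
  ph <- generate_phantom(phantom_spec())
  comp <- extract_components(ph$hu)
  expect_gte(dice(comp$Hp, ph$truth$bleed), 0.8)
  # the selected level sits in the configured sweep
  lv <- vapply(comp$sweep$settings, function(s) s$wl, numeric(1))
  expect_true(lv[comp$sweep$selected_index] %in% seq(30, 75, 5))
  expect_identical(comp$min_hu, 60)   # the bleed's uniform HU, noise-free
})
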