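test_that("tile_pair partitions the image exactly and scores match a
           direct recomputation", {
  st <- phantom_pair(201, rho = 0.5)
  a <- st[[1]]; b <- st[[2]]
  g <- tile_pair(a, b, selection_config(tile_size = 64))
  expect_equal(nrow(g$tiles), 16L)
  # disjoint cover: every pixel in exactly one tile
  cover <- matrix(0L, 256, 256)
  for (k in seq_len(nrow(g$tiles))) {
    t <- g$tiles[k, ]
    cover[t$y0:t$y1, t$x0:t$x1] <- cover[t$y0:t$y1, t$x0:t$x1] + 1L
  }
  expect_true(all(cover == 1L))
  # per-tile score equals an independent recomputation at the pair range
  dr <- max(a, b) - min(a, b)
  for (k in c(1, 6, 16)) {
    t <- g$tiles[k, ]
    expect_equal(g$tiles$score[k],
                 ssim_score(a[t$y0:t$y1, t$x0:t$x1],
                            b[t$y0:t$y1, t$x0:t$x1], data_range = dr))
  }
  # identical channels score 1 everywhere
  gi <- tile_pair(a, a, selection_config(tile_size = 64))
  expect_true(all(abs(gi$tiles$score - 1) < 1e-12))
})

test_that("zone tiles score systematically lower than colocalized tiles", {
  st <- phantom_pair(202, rho = 0.5)
  g <- tile_pair(st[[1]], st[[2]], selection_config(tile_size = 64))
  sc <- matrix(g$tiles$score, 4, 4, byrow = TRUE)
  # exclusive blobs sit in the bottom band of the phantom
  expect_lt(mean(sc[4, ]), mean(sc[1:2, ]))
})

test_that("edge slivers merge into their neighbours", {
  set.seed(203)
  a <- matrix(runif(200 * 200), 200, 200)
  g <- suppressWarnings(tile_pair(a, a, selection_config(tile_size = 64)))
  # 200 = 64*3 + 8; the 8 px sliver (< 32) merges: 3 breaks per axis
  expect_equal(nrow(g$tiles), 9L)
  expect_equal(max(g$tiles$y1), 200L)
  widths <- g$tiles$x1 - g$tiles$x0 + 1L
  expect_setequal(unique(widths), c(64L, 72L))
  # image smaller than a tile: single-tile grid with a warning
  expect_warning(g1 <- tile_pair(a[1:40, 1:40], a[1:40, 1:40],
                                 selection_config(tile_size = 64)),
                 "single-tile")
  expect_equal(nrow(g1$tiles), 1L)
})

test_that("selection arithmetic is exact, floors at one tile, includes ties", {
  fake_grid <- function(scores) {
    structure(list(
      tiles = tibble::tibble(tile = seq_along(scores),
                             row = 1L, col = seq_along(scores),
                             y0 = 1L, y1 = 2L, x0 = 1L, x1 = 2L,
                             score = scores),
      tile_size = 2L, metric = "ssim", image_dim = c(2L, 2L),
      selected = integer(0)), class = "mosaic_grid")
  }
  set.seed(204)
  sc200 <- sample(seq(0, 1, length.out = 200))
  g <- select_low_similarity(fake_grid(sc200),
                             selection_config(percentile = 0.01))
  expect_length(g$selected, 2L)
  expect_setequal(g$selected, order(sc200)[1:2])
  expect_warning(
    g10 <- select_low_similarity(fake_grid(runif(10)),
                                 selection_config(percentile = 0.01)),
    "percentile")
  expect_length(g10$selected, 1L)
  # boundary ties are all included
  tied <- c(0.1, 0.1, 0.1, runif(97, 0.5, 1))
  gt <- suppressWarnings(
    select_low_similarity(fake_grid(tied),
                          selection_config(percentile = 0.01)))
  expect_length(gt$selected, 3L)
  # monotonicity: a larger percentile never drops a selected tile
  g5 <- suppressWarnings(
    select_low_similarity(fake_grid(sc200),
                          selection_config(percentile = 0.05)))
  expect_true(all(g$selected %in% g5$selected))
})

test_that("combining tiles preserves the pixel multiset and joint histogram", {
  st <- phantom_pair(205, rho = 0.5)
  a <- st[[1]]; b <- st[[2]]
  cfg <- selection_config(tile_size = 64, percentile = 1)
  g <- suppressWarnings(select_low_similarity(tile_pair(a, b, cfg), cfg))
  expect_length(g$selected, 16L)
  comp <- combine_selected(a, b, g)
  expect_setequal(as.vector(comp$a), as.vector(a))
  expect_equal(normalized_mi(comp$a, comp$b), normalized_mi(a, b))
  # single tile: composite is that crop
  g1 <- g; g1$selected <- 7L
  t <- g$tiles[7, ]
  c1 <- combine_selected(a, b, g1)
  expect_equal(c1$a, a[t$y0:t$y1, t$x0:t$x1])
  # two tiles: joint histogram equals the sum of per-tile joint histograms
  g2 <- g; g2$selected <- c(3L, 9L)
  c2 <- combine_selected(a, b, g2)
  jh <- function(x, y) {
    bx <- oracle_bin(as.vector(x), min(x), max(x), 32)
    by <- oracle_bin(as.vector(y), min(y), max(y), 32)
    table(factor(bx, 1:32), factor(by, 1:32))
  }
  crops <- lapply(c(3L, 9L), function(k) {
    t <- g$tiles[k, ]
    list(a = a[t$y0:t$y1, t$x0:t$x1], b = b[t$y0:t$y1, t$x0:t$x1])
  })
  # identical pixel multisets => same per-image ranges => identical joint
  # histograms up to tile order
  pooled_a <- c(sapply(crops, function(cr) as.vector(cr$a)))
  pooled_b <- c(sapply(crops, function(cr) as.vector(cr$b)))
  expect_equal(unname(jh(c2$a, c2$b)), unname(jh(pooled_a, pooled_b)))
})

test_that("mosaic estimation rescues colocalized pairs and matches
           whole-image estimation on disjoint ones", {
  # colocalized, unmixed: whole-image overcorrects, mosaic does not
  co <- phantom_pair(206, rho = 0.8)
  whole <- estimate_alpha(co[[1]], co[[2]])$argmin_alpha
  mos <- suppressWarnings(mosaic_alpha(co[[1]], co[[2]]))
  expect_gt(whole, 0.3)
  expect_lte(mos$forward$argmin_alpha, 0.05)
  expect_lte(mos$reverse$argmin_alpha, 0.05)
  # disjoint, mixed: mosaic agrees with whole-image within grid resolution
  dm <- phantom_pair(207, a12 = 0.2, a21 = 0.6)
  md <- suppressWarnings(mosaic_alpha(dm[[1]], dm[[2]]))
  expect_equal(md$forward$argmin_alpha,
               estimate_alpha(dm[[1]], dm[[2]])$argmin_alpha,
               tolerance = 0.02)
  expect_equal(md$reverse$argmin_alpha,
               estimate_alpha(dm[[2]], dm[[1]])$argmin_alpha,
               tolerance = 0.02)
  # heterogeneous colocalization with no mixing: mosaic stays near zero
  het <- phantom_pair(208, rho = 0.5)
  mh <- suppressWarnings(mosaic_alpha(het[[1]], het[[2]]))
  expect_lte(mh$forward$argmin_alpha, 0.05)
  expect_lte(mh$reverse$argmin_alpha, 0.05)
})

test_that("mosaic estimate does not exceed whole-image estimate on
           colocalized phantoms", {
  worse <- 0L
  for (s in 221:240) {
    st <- phantom_pair(s, rho = 0.8)
    w <- estimate_alpha(st[[1]], st[[2]])$argmin_alpha
    m <- suppressWarnings(mosaic_alpha(st[[1]], st[[2]]))
    if (m$forward$argmin_alpha >= w) worse <- worse + 1L
  }
  expect_lte(worse, 1L)  # >= 95% of 20 runs
})

test_that("heterogeneity report exposes the per-tile QC surface", {
  # disjoint phantom: per-tile ratios concentrate near zero
  dj <- phantom_pair(209)
  hr <- heterogeneity_report(dj[[1]], dj[[2]])
  expect_equal(nrow(hr), 16L)
  expect_lte(stats::median(hr$alpha_ab, na.rm = TRUE), 0.05)
  expect_lte(stats::IQR(hr$alpha_ab, na.rm = TRUE), 0.1)
  # mixed-colocalization phantom: high-similarity tiles inflate, the
  # low-similarity tiles sit near the true ratio of zero
  mx <- phantom_pair(210, rho = 0.5)
  hm <- heterogeneity_report(mx[[1]], mx[[2]])
  lo <- hm$ssim <= stats::median(hm$ssim)
  expect_gt(mean(hm$alpha_ab[!lo], na.rm = TRUE),
            mean(hm$alpha_ab[lo], na.rm = TRUE))
  # a constant tile yields a null (NA) ratio, not a dropped row
  a <- mx[[1]]; b <- mx[[2]]
  a[1:64, 1:64] <- 0; b[1:64, 1:64] <- 0
  hc <- heterogeneity_report(a, b)
  expect_equal(nrow(hc), 16L)
  expect_true(is.na(hc$alpha_ab[hc$row == 1 & hc$col == 1]))
  expect_warning(heterogeneity_report(mx[[1]], mx[[2]],
                                      selection_config(tile_size = 16)),
                 "unstable")
})
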