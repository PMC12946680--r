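make_pixels <- function(...) {
  do.call(rbind, lapply(list(...), function(e)
    matrix(rep(e$rgb, e$n), ncol = 3, byrow = TRUE,
           dimnames = list(NULL, c("r", "g", "b")))))
}

test_that("value filtering excludes V < v_min strictly", {
  px <- rbind(c(0, 0, 0), c(255, 255, 255), c(128, 0, 0), c(127, 0, 0))
  kept <- filter_value(px, 0.5)
  expect_equal(nrow(kept), 2)
  expect_true(any(kept[, 1] == 255))
  expect_true(any(kept[, 1] == 128))   # V = 128/255 = 0.502 kept
  expect_false(any(kept[, 1] == 127))  # V = 127/255 = 0.498 excluded

  # raising v_min never increases the number of passing pixels
  set.seed(31)
  rand <- matrix(sample(0:255, 300, TRUE), ncol = 3)
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(v) nrow(filter_value(rand, v)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("top-k counting is exact with deterministic tie-breaking", {
  px <- make_pixels(list(rgb = c(200, 10, 10), n = 60),
                    list(rgb = c(10, 200, 10), n = 30),
                    list(rgb = c(10, 10, 200), n = 10))
  top <- top_k_colors(px, 2)
  expect_equal(top$count, c(60, 30))
  expect_equal(top$r[1], 200)

  # count tie broken by ascending (R, G, B)
  tie <- make_pixels(list(rgb = c(50, 0, 0), n = 5),
                     list(rgb = c(10, 0, 0), n = 5))
  expect_equal(top_k_colors(tie, 1)$r, 10)

  expect_warning(small <- top_k_colors(px, 20), "distinct")
  expect_equal(nrow(small), 3)
  expect_error(top_k_colors(px[0, , drop = FALSE], 5, roi_index = 7), "ROI 7")
})

test_that("top-k matches a brute-force histogram sort on random multisets", {
  set.seed(32)
  for (rep in 1:10) {
    px <- matrix(sample(0:4, 3 * 500, TRUE) * 50, ncol = 3)
    for (k in c(1, 5, 20)) {
      ours <- suppressWarnings(top_k_colors(px, k))
      oracle <- oracle_top_k(px, k)
      expect_equal(ours$count, oracle$count)
      expect_equal(ours[c("r", "g", "b")], oracle[c("r", "g", "b")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("histogram counts conserve the number of V-passing pixels", {
  set.seed(33)
  px <- matrix(sample(0:255, 3 * 400, TRUE), ncol = 3)
  passing <- filter_value(px, 0.5)
  full <- suppressWarnings(top_k_colors(passing, nrow(passing) + 1))
  expect_equal(sum(full$count), nrow(passing))
})

test_that("palette compilation concatenates without deduplication", {
  a <- data.frame(r = 1, g = 2, b = 3, count = 10)
  b <- data.frame(r = c(1, 9), g = c(2, 9), b = c(3, 9), count = c(4, 2))
  pal <- compile_palette(list(a, b))
  expect_equal(nrow(pal), 3)
  expect_equal(pal$roi, c(1, 2, 2))
  # duplicated color across ROIs appears twice
  expect_equal(sum(pal$r == 1 & pal$g == 2 & pal$b == 3), 2)

  twenty <- lapply(1:20, function(i)
    data.frame(r = 0:19, g = i, b = 0, count = 20:1))
  expect_equal(nrow(compile_palette(twenty)), 400)

  expect_error(compile_palette(list(a[0, ], b[0, ])), "empty")
})

test_that("hue sorting is ascending with documented tie rules", {
  pal <- compile_palette(list(data.frame(
    r = c(0, 255, 0, 128), g = c(0, 0, 255, 128), b = c(255, 0, 0, 128),
    count = 1)))
  sorted <- hue_sort(pal)
  # grey (H=0, S=0) before red (H=0, S=1), then green (1/3), blue (2/3)
  expect_equal(sorted$r, c(128, 255, 0, 0))
  expect_equal(sorted$hue, c(0, 0, 1 / 3, 2 / 3))

  # random palette equals a brute-force comparison sort on the same key
  set.seed(34)
  rand <- compile_palette(list(data.frame(
    r = sample(0:255, 400, TRUE), g = sample(0:255, 400, TRUE),
    b = sample(0:255, 400, TRUE), count = sample(1:50, 400, TRUE))))
  sorted <- hue_sort(rand)
  hsv <- t(grDevices::rgb2hsv(t(as.matrix(rand[, c("r", "g", "b")])),
                              maxColorValue = 255))
  key <- paste(sprintf("%.10f", hsv[, 1]), sprintf("%.10f", hsv[, 2]),
               sprintf("%.10f", hsv[, 3]), sprintf("%03d", rand$r),
               sprintf("%03d", rand$g), sprintf("%03d", rand$b))
  oracle_order <- order(key)
  expect_equal(sorted$r, rand$r[oracle_order])
  expect_equal(sorted$count, rand$count[oracle_order])
})

test_that("color bars partition the width equally in palette order", {
  pal <- compile_palette(list(data.frame(
    r = c(10, 20, 30, 40), g = 0, b = 0, count = 1)))
  bar <- render_bar(pal, 400, 10)
  expect_equal(dim(bar), c(10, 400, 3))
  expect_equal(as.integer(bar[1, c(1, 100), 1]), c(10, 10))
  expect_equal(as.integer(bar[1, c(101, 200), 1]), c(20, 20))
  expect_equal(as.integer(bar[1, 400, 1]), 40)

  single <- render_bar(pal[1, ], 50, 5)
  expect_true(all(single[, , 1] == 10))

  expect_error(render_bar(pal, 3, 10), "narrower")

  # 400 1-px stripes, leftmost has the lowest hue
  set.seed(35)
  rand <- hue_sort(compile_palette(list(data.frame(
    r = sample(128:255, 400, TRUE), g = sample(0:255, 400, TRUE),
    b = sample(0:255, 400, TRUE), count = 1))))
  bar1 <- render_bar(rand, 400, 2)
  expect_equal(as.integer(bar1[1, 1, ]), c(rand$r[1], rand$g[1], rand$b[1]))
  expect_equal(as.integer(bar1[1, 400, ]),
               c(rand$r[400], rand$g[400], rand$b[400]))
})

test_that("palette content is independent of pixel iteration order", {
  set.seed(36)
  px <- matrix(sample(0:3, 3 * 200, TRUE) * 70, ncol = 3)
  a <- suppressWarnings(top_k_colors(px, 10))
  b <- suppressWarnings(top_k_colors(px[sample(nrow(px)), ], 10))
  expect_identical(a, b)
})
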