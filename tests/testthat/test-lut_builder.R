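test_that("builtin LUTs reproduce the published anchor sequences", {
  lut12 <- builtin_lut("12mpg")
  expect_equal(lut12$points$label, LUT_LABELS)
  expect_equal(lut12$points$fa,
               c(0, 0.0385, 0.077, 0.218, 0.323, 0.464, 0.627, 0.792,
                 0.858, 1))
  lut30 <- builtin_lut("30mpg")
  expect_equal(lut30$points$fa,
               c(0, 0.0365, 0.073, 0.173, 0.328, 0.481, 0.608, 0.797,
                 0.855, 1))
  expect_true(all(diff(lut12$points$fa) > 0))
  expect_true(all(diff(lut30$points$fa) > 0))
  # acquisition scheme moves only the basal-ganglia mean anchor appreciably
  d <- abs(lut12$points$fa - lut30$points$fa)
  expect_equal(lut12$points$label[d > 0.02], "BG_MEAN")
})

test_that("anchor ordering violations are reported with the offending pair", {
  tab <- generate_measurements(normative_group_specs(12, n_subjects = 30),
                               seed = 2)
  fits <- fit_all_groups(tab, 12)
  # artificially push the GM upper bound past the CC freehand lower bound
  fits$GM$pi_high <- fits$CC_FREEHAND$pi_low + 0.05
  expect_error(build_inflection_points(fits), "GM_PIUP.*CCF_PILOW")
  expect_error(build_inflection_points(fits[c("BG", "GM")]),
               "CC_FREEHAND.*CC_CROI")
})

test_that("interpolation is exact at anchors and linear between them", {
  lut <- builtin_lut("12mpg")
  pal <- default_palette()
  for (i in seq_along(LUT_LABELS)) {
    expect_equal(as.vector(interpolate_color(lut, lut$points$fa[i])),
                 as.vector(pal[[LUT_LABELS[i]]]),
                 label = LUT_LABELS[i])
  }
  # midpoint between black and white anchors is half-up gray
  mono <- build_inflection_points(
    lapply(fit_all_groups(generate_measurements(
      normative_group_specs(12, n_subjects = 20), seed = 3), 12), identity),
    palette = gray_palette())
  p <- mono$points
  mid <- (p$fa[1] + p$fa[2]) / 2
  expect_equal(as.vector(interpolate_color(mono, mid)),
               rep(as.integer(floor((p$r[1] + p$r[2]) / 2 + 0.5)), 3))
  # out-of-range FA clamps to the endpoint colors
  expect_equal(as.vector(interpolate_color(lut, -0.5)), c(0L, 0L, 0L))
  expect_equal(as.vector(interpolate_color(lut, 1.5)), c(255L, 255L, 255L))
  expect_error(interpolate_color(lut, NaN), "finite")
})

test_that("interpolation matches an independent brute-force oracle", {
  lut <- builtin_lut("12mpg")
  fa <- seq(0, 1, length.out = 1000)
  mine <- interpolate_color(lut, fa)
  oracle <- t(vapply(fa, function(v) brute_force_color(lut, v), integer(3)))
  expect_equal(unname(mine), unname(oracle))
})

test_that("interpolated ramps are continuous at the rounding scale", {
  lut <- builtin_lut("12mpg")
  fa <- seq(1e-6, 1 - 1e-6, length.out = 500)
  jump <- abs(interpolate_color(lut, fa + 1e-6) - interpolate_color(lut, fa))
  expect_lte(max(jump), 1)
})

test_that("the default palette yields distinct colors on the 256 grid", {
  s <- sample_lut(builtin_lut("12mpg"), 256)
  expect_equal(anyDuplicated(s[, c("r", "g", "b")]), 0L)
})

test_that("sample_lut discretizes on the closed uniform grid", {
  lut <- builtin_lut("12mpg")
  expect_error(sample_lut(lut, 1), "n_entries")
  two <- sample_lut(lut, 2)
  expect_equal(unlist(two[1, c("r", "g", "b")], use.names = FALSE), c(0L, 0L, 0L))
  expect_equal(unlist(two[2, c("r", "g", "b")], use.names = FALSE),
               c(255L, 255L, 255L))
  s <- sample_lut(lut, 256)
  expect_equal(s$fa, (0:255) / 255)
  # a monotone gray palette samples to nondecreasing gray levels
  mono <- builtin_lut("12mpg", palette = gray_palette())
  g <- sample_lut(mono, 256)
  expect_true(all(diff(g$r) >= 0))
  expect_equal(g$r, g$g)
  expect_equal(g$g, g$b)
  # coarse and fine grids agree at shared FA values (256 = 4*85 + ...);
  # grid 1024 shares fa with grid 256 only at multiples: use 256 vs 1021? No:
  # k/255 grid is shared with (4k)/1020 grid of size 1021
  fine <- sample_lut(lut, 1021)
  expect_equal(unname(as.matrix(fine[1 + 4 * (0:255), c("r", "g", "b")])),
               unname(as.matrix(s[, c("r", "g", "b")])))
})

test_that("ImageJ export writes exactly 768 bytes and round-trips", {
  lut <- builtin_lut("12mpg")
  path <- withr::local_tempfile(fileext = ".lut")
  export_imagej_lut(lut, path)
  expect_equal(file.size(path), 768)
  back <- import_imagej_lut(path)
  s <- sample_lut(lut, 256)
  expect_equal(back$r, s$r)
  expect_equal(back$g, s$g)
  expect_equal(back$b, s$b)
  # deterministic: identical inputs give bit-identical exports
  path2 <- withr::local_tempfile(fileext = ".lut")
  export_imagej_lut(builtin_lut("12mpg"), path2)
  expect_identical(readBin(path, "raw", 768), readBin(path2, "raw", 768))
  # all-black palette -> 768 zero bytes
  black <- setNames(lapply(LUT_LABELS, function(x) c(0L, 0L, 0L)), LUT_LABELS)
  export_imagej_lut(builtin_lut("12mpg", palette = black), path)
  expect_equal(readBin(path, "raw", 768), as.raw(rep(0, 768)))
  expect_error(import_imagej_lut(withr::local_tempfile(fileext = ".lut")),
               "no such file")
})

test_that("CSV colormap export round-trips on the sampled grid", {
  lut <- builtin_lut("30mpg")
  path <- withr::local_tempfile(fileext = ".csv")
  export_csv_colormap(lut, path, n_entries = 256)
  expect_length(readLines(path), 257L)
  back <- import_csv_colormap(path)
  s <- sample_lut(lut, 256)
  expect_equal(back$index, s$index)
  expect_equal(back$fa, s$fa)
  expect_equal(back[, c("r", "g", "b")], s[, c("r", "g", "b")])
  writeLines(c("index,fa,r,g,b", "0,0.0,0,0,0", "1,oops,1,2,3"), path)
  expect_error(import_csv_colormap(path), "line.*3")
  writeLines(c("index,fa,r,g", "0,0.0,0,0"), path)
  expect_error(import_csv_colormap(path), "missing column")
})

test_that("palettes round-trip through YAML and are validated", {
  pal <- default_palette()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_palette(pal, path)
  expect_equal(read_palette(path), lapply(pal, as.integer))
  bad <- pal
  bad$BG_MEAN <- c(300L, 0L, 0L)
  expect_error(write_palette(bad, path), "BG_MEAN")
  bad$BG_MEAN <- NULL
  expect_error(write_palette(bad, path), "missing label")
})

test_that("the shipped palette config matches the built-in default", {
  path <- system.file("extdata", "palette_default.yaml", package = "falut")
  expect_true(nzchar(path))
  expect_equal(read_palette(path), default_palette())
})

test_that("fitted LUT anchors equal the fit statistics that define them", {
  tab <- generate_measurements(normative_group_specs(12), seed = 21)
  fits <- fit_all_groups(tab, 12)
  lut <- build_inflection_points(fits)
  p <- lut$points
  expect_equal(p$fa[p$label == "BG_HALF_PILOW"], fits$BG$pi_low / 2)
  expect_equal(p$fa[p$label == "BG_MEAN"], fits$BG$mu_hat)
  expect_equal(p$fa[p$label == "GM_PIUP"], fits$GM$pi_high)
  expect_equal(p$fa[p$label == "CCF_PILOW"], fits$CC_FREEHAND$pi_low)
  expect_equal(p$fa[p$label == "CCROI_MEAN"], fits$CC_CROI$mu_hat)
  expect_equal(p$fa[c(1, 10)], c(0, 1))
})
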