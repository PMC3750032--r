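# Inflection-point placement, continuous per-channel color ramps, and LUT
# export in ImageJ raw and CSV formats.

#' LUT anchor labels, in FA order
#'
#' Eight normative anchors plus the two domain endpoints. The normative
#' anchors are: half the basal-ganglia prediction-interval lower bound
#' (`BG_HALF_PILOW`), the BG lower bound and mean, the gray-matter mean and
#' upper bound, the freehand corpus-callosum lower and upper bounds, and the
#' circular corpus-callosum mean.
#' @export
LUT_LABELS <- c("DOMAIN_MIN", "BG_HALF_PILOW", "BG_PILOW", "BG_MEAN",
                "GM_MEAN", "GM_PIUP", "CCF_PILOW", "CCF_PIUP",
                "CCROI_MEAN", "DOMAIN_MAX")

#' Anchor color palettes
#'
#' A palette maps every label in [LUT_LABELS] to an RGB triple of integers
#' in \[0, 255\]. The published anchor colors are not recoverable in RGB, so
#' the default palette is a stand-in designed to the same reading
#' conventions: low-FA basal ganglia in dark blue/purple, gray matter in
#' green, and dense white matter running red to yellow with rising FA, so
#' healthy peduncles and callosum render red/yellow. It is editable via a
#' YAML config ([write_palette()] / [read_palette()]).
#'
#' @return named list of length-3 integer vectors.
#' @export
default_palette <- function() {
  list(
    DOMAIN_MIN    = c(0L,   0L,   0L),
    BG_HALF_PILOW = c(32L,  0L,   64L),
    BG_PILOW      = c(64L,  0L,   128L),
    BG_MEAN       = c(0L,   64L,  255L),
    GM_MEAN       = c(0L,   160L, 96L),
    GM_PIUP       = c(96L,  192L, 0L),
    CCF_PILOW     = c(255L, 0L,   0L),
    CCF_PIUP      = c(255L, 128L, 0L),
    CCROI_MEAN    = c(255L, 255L, 0L),
    DOMAIN_MAX    = c(255L, 255L, 255L)
  )
}

validate_palette <- function(palette) {
  missing <- setdiff(LUT_LABELS, names(palette))
  if (length(missing))
    stop("palette is missing label(s): ", paste(missing, collapse = ", "))
  for (lab in LUT_LABELS) {
    rgb <- palette[[lab]]
    if (length(rgb) != 3L || any(!is.finite(rgb)) ||
        any(rgb < 0) || any(rgb > 255) || any(rgb != round(rgb)))
      stop("palette[", lab, "] must be 3 integers in [0, 255]")
  }
  invisible(palette)
}

#' @rdname default_palette
#' @param path YAML file mapping labels to `[r, g, b]`.
#' @export
read_palette <- function(path) {
  pal <- yaml::read_yaml(path)
  pal <- lapply(pal, function(x) as.integer(unlist(x)))
  validate_palette(pal)
  pal
}

#' @rdname default_palette
#' @param palette named list of RGB triples.
#' @export
write_palette <- function(palette, path) {
  validate_palette(palette)
  yaml::write_yaml(lapply(palette, as.integer), path)
  invisible(path)
}

#' Build LUT inflection points from group fits
#'
#' Places the color anchors at, in order: `BG.pi_low / 2`, `BG.pi_low`,
#' `BG.mu_hat`, `GM.mu_hat`, `GM.pi_high`, `CCF.pi_low`, `CCF.pi_high`,
#' `CCROI.mu_hat`, bracketed by domain endpoints at FA 0 and 1. The halved
#' lower BG bound gives very low FA values a ramp of their own instead of
#' collapsing them onto the endpoint color. Anchor FA values are clipped
#' into \[0, 1\] and must then be strictly increasing — a violation signals
#' a pathological normative cohort and is an error naming the offending
#' pair.
#'
#' @param fits named list of `ri_fit` containing `BG`, `GM`, `CC_FREEHAND`,
#'   `CC_CROI` (see [fit_all_groups()]).
#' @param palette anchor colors, see [default_palette()].
#' @param name LUT name.
#' @param source provenance tag (`"fitted"`, `"builtin-12MPG"`, ...).
#' @return object of class `color_lut`: a `points` data.frame
#'   (`label`, `fa`, `r`, `g`, `b`) plus `name` and `source`.
#' @export
build_inflection_points <- function(fits, palette = default_palette(),
                                    name = "falut", source = "fitted") {
  validate_palette(palette)
  missing <- setdiff(LUT_GROUPS, names(fits))
  if (length(missing))
    stop("fits are missing group(s): ", paste(missing, collapse = ", "))
  bg <- fits$BG; gm <- fits$GM; ccf <- fits$CC_FREEHAND; ccr <- fits$CC_CROI
  fa <- c(0,
          bg$pi_low / 2, bg$pi_low, bg$mu_hat,
          gm$mu_hat, gm$pi_high,
          ccf$pi_low, ccf$pi_high,
          ccr$mu_hat,
          1)
  fa <- pmin(pmax(fa, 0), 1)
  points <- data.frame(label = LUT_LABELS, fa = fa,
                       t(vapply(LUT_LABELS, function(l) palette[[l]],
                                integer(3))),
                       stringsAsFactors = FALSE)
  names(points)[3:5] <- c("r", "g", "b")
  rownames(points) <- NULL
  bad <- which(diff(points$fa) <= 0)
  if (length(bad))
    stop("anchor FA values are not strictly increasing: ",
         paste(sprintf("%s (%.4f) >= %s (%.4f)",
                       points$label[bad], points$fa[bad],
                       points$label[bad + 1L], points$fa[bad + 1L]),
               collapse = "; "))
  structure(list(points = points, name = name, source = source),
            class = "color_lut")
}

#' @export
print.color_lut <- function(x, ...) {
  cat(sprintf("<color_lut '%s' (%s)> %d anchors:\n", x$name, x$source,
              nrow(x$points)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Built-in LUTs from the published normative table
#'
#' Constructs the LUT directly from the published normative means and
#' prediction intervals ([fa_normative_values()]) for the 12 or 30 MPG
#' acquisition, without refitting.
#'
#' @param scheme `"12mpg"` or `"30mpg"`.
#' @param palette anchor colors.
#' @return a `color_lut` with source `builtin-12MPG` / `builtin-30MPG`.
#' @export
builtin_lut <- function(scheme = c("12mpg", "30mpg"),
                        palette = default_palette()) {
  scheme <- match.arg(scheme)
  mpg <- if (scheme == "12mpg") 12L else 30L
  ref <- fa_normative_values(mpg)
  fits <- lapply(setNames(LUT_GROUPS, LUT_GROUPS), function(g) {
    row <- ref[ref$roi_group == g, ]
    f <- new_ri_fit(g, mpg, mu_hat = row$mean, tau2_hat = NA_real_,
                    sigma2_hat = NA_real_, mu_var = NA_real_,
                    n_subjects = NA_integer_, n_obs = NA_integer_,
                    method = "published")
    f$pi_low <- row$pi_low
    f$pi_high <- row$pi_high
    f
  })
  build_inflection_points(fits, palette,
                          name = paste0("falut-", scheme),
                          source = paste0("builtin-", toupper(scheme)))
}

#' Interpolate the LUT color at given FA values
#'
#' Each channel is linearly interpolated in continuous space between the two
#' bracketing anchors, then rounded half-up to integers in \[0, 255\]
#' (interpolate-then-round). FA exactly at an anchor returns that anchor's
#' color exactly; FA outside \[0, 1\] is clamped to the nearest endpoint.
#'
#' @param lut a `color_lut`.
#' @param fa numeric vector of finite FA values.
#' @return integer matrix with one row per FA value and columns `r`, `g`, `b`.
#' @export
interpolate_color <- function(lut, fa) {
  stopifnot(inherits(lut, "color_lut"))
  if (any(!is.finite(fa)))
    stop("interpolate_color: fa must be finite (volume-level NaN handling ",
         "is the colorizer's job)")
  fa <- pmin(pmax(fa, 0), 1)
  p <- lut$points
  out <- vapply(c("r", "g", "b"), function(ch)
    as.integer(round_half_up(approx(p$fa, p[[ch]], xout = fa,
                                    method = "linear", ties = "ordered")$y)),
    integer(length(fa)))
  out <- matrix(out, ncol = 3L, dimnames = list(NULL, c("r", "g", "b")))
  out
}

#' Discretize a LUT onto a uniform FA grid
#'
#' Entry `k` (0-based) holds the color at `fa = k / (n_entries - 1)`, so the
#' first and last entries are the domain endpoint colors.
#'
#' @param lut a `color_lut`.
#' @param n_entries number of rows, at least 2 (default 256, the ImageJ
#'   table size).
#' @return data.frame with columns `index`, `fa`, `r`, `g`, `b`.
#' @export
sample_lut <- function(lut, n_entries = 256L) {
  if (!is.numeric(n_entries) || n_entries < 2L)
    stop("n_entries must be >= 2")
  n_entries <- as.integer(n_entries)
  fa <- (seq_len(n_entries) - 1L) / (n_entries - 1L)
  rgb <- interpolate_color(lut, fa)
  data.frame(index = seq_len(n_entries) - 1L, fa = fa,
             r = rgb[, "r"], g = rgb[, "g"], b = rgb[, "b"])
}

#' ImageJ raw LUT export / import
#'
#' The raw ImageJ `.lut` layout is exactly 768 bytes: 256 red bytes, then
#' 256 green, then 256 blue, sampled on the uniform 256-entry FA grid.
#'
#' @param lut a `color_lut`.
#' @param path output `.lut` file.
#' @return `export_imagej_lut()` returns `path` invisibly;
#'   `import_imagej_lut()` returns the 256-entry `index`/`r`/`g`/`b` table.
#' @export
export_imagej_lut <- function(lut, path) {
  s <- sample_lut(lut, 256L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(s$r, s$g, s$b)), con)
  invisible(path)
}

#' @rdname export_imagej_lut
#' @export
import_imagej_lut <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) != 768)
    stop("not a raw ImageJ LUT (expected 768 bytes, got ",
         file.size(path), "): ", path)
  bytes <- as.integer(readBin(path, "raw", n = 768L))
  data.frame(index = 0:255, r = bytes[1:256], g = bytes[257:512],
             b = bytes[513:768])
}

#' CSV colormap export / import
#'
#' Plain-text colormap with header `index,fa,r,g,b`, one row per grid entry.
#'
#' @param lut a `color_lut`.
#' @param path CSV file path.
#' @param n_entries grid size, default 256.
#' @return `export_csv_colormap()` returns `path` invisibly;
#'   `import_csv_colormap()` returns the sampled table.
#' @export
export_csv_colormap <- function(lut, path, n_entries = 256L) {
  s <- sample_lut(lut, n_entries)
  s$fa <- sprintf("%.17g", s$fa)
  write.csv(s, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_csv_colormap
#' @export
import_csv_colormap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "fa", "r", "g", "b")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  for (col in need) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric '", col, "' at line(s) ",
           paste(utils::head(bad, 10L) + 1L, collapse = ", "))
    raw[[col]] <- v
  }
  raw$index <- as.integer(raw$index)
  raw$r <- as.integer(raw$r); raw$g <- as.integer(raw$g)
  raw$b <- as.integer(raw$b)
  raw
}
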