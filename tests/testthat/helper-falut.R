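# shared fixtures, built in code

# balanced toy table: 3 subjects x 2 ROIs with hand-computable ANOVA
toy_table <- function() {
  measurement_table(data.frame(
    subject_id = rep(c("A", "B", "C"), each = 2),
    roi_group = "BG",
    roi_label = rep(c("roi_1", "roi_2"), times = 3),
    roi_kind = "circular",
    mpg_scheme = 12L,
    fa = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  ))
}

# small random balanced table for one group
balanced_table <- function(seed, n_subjects = 12, k = 4, mean = 0.5,
                           tau = 0.05, sigma = 0.04, group = "GM") {
  set.seed(seed)
  b <- rnorm(n_subjects, 0, tau)
  fa <- pmin(pmax(mean + rep(b, times = k) + rnorm(n_subjects * k, 0, sigma),
                  0), 1)
  measurement_table(data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), times = k),
    roi_group = group,
    roi_label = rep(sprintf("roi_%d", seq_len(k)), each = n_subjects),
    roi_kind = "circular",
    mpg_scheme = 12L,
    fa = fa
  ))
}

# monotone grayscale palette (equal channels, nondecreasing in FA)
gray_palette <- function() {
  vals <- c(0, 20, 45, 80, 110, 140, 180, 210, 235, 255)
  setNames(lapply(vals, function(v) rep(as.integer(v), 3)), falut::LUT_LABELS)
}

# independent brute-force per-channel linear interpolation oracle:
# explicit segment search + arithmetic, no approx()
brute_force_color <- function(lut, fa) {
  p <- lut$points
  fa <- min(max(fa, 0), 1)
  if (fa <= p$fa[1]) return(as.integer(c(p$r[1], p$g[1], p$b[1])))
  n <- nrow(p)
  for (i in seq_len(n - 1)) {
    if (fa <= p$fa[i + 1]) {
      t <- (fa - p$fa[i]) / (p$fa[i + 1] - p$fa[i])
      ch <- sapply(c("r", "g", "b"), function(cn)
        p[[cn]][i] + t * (p[[cn]][i + 1] - p[[cn]][i]))
      return(as.integer(floor(ch + 0.5)))
    }
  }
  as.integer(c(p$r[n], p$g[n], p$b[n]))
}
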