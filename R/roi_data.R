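# Measurement-table data model, delimited-text I/O and the synthetic
# normative-cohort generator.

#' ROI groups with built-in normative values
#'
#' The four LUT groups are basal ganglia (`BG`), gray matter (`GM`,
#' precentral gyrus and thalamus), freehand corpus-callosum selections
#' (`CC_FREEHAND`) and pooled circular corpus-callosum selections
#' (`CC_CROI`). `PYRAMIDAL` and `MCP` (middle cerebellar peduncle) are
#' additional validation regions that do not enter the LUT. Other group
#' names are accepted as custom groups.
#' @export
LUT_GROUPS <- c("BG", "GM", "CC_FREEHAND", "CC_CROI")

#' @rdname LUT_GROUPS
#' @export
EXTRA_GROUPS <- c("PYRAMIDAL", "MCP")

MEASUREMENT_COLUMNS <- c("subject_id", "roi_group", "roi_label",
                         "roi_kind", "mpg_scheme", "fa")
ROI_KINDS <- c("freehand", "circular")
MPG_SCHEMES <- c(12L, 30L)

#' Normative FA reference values
#'
#' Published normative estimates (population mean and 95% prediction
#' interval) per ROI group and motion-probing-gradient (MPG) scheme, from a
#' cohort of 76 healthy adults (59 rescanned at 30 MPG). These are the
#' default parameters of [generate_measurements()] and the inputs of
#' [builtin_lut()]. Pyramidal-tract and middle-cerebellar-peduncle rows are
#' the pooled (circular + freehand) estimates from the 12 MPG validation
#' measurements.
#'
#' @param mpg_scheme optional filter, 12 or 30.
#' @return data.frame with columns `roi_group`, `mpg_scheme`, `mean`,
#'   `pi_low`, `pi_high`.
#' @export
fa_normative_values <- function(mpg_scheme = NULL) {
  ref <- data.frame(
    roi_group = c("BG", "GM", "CC_FREEHAND", "CC_CROI", "CC_GENU", "CC_SPLENIUM",
                  "BG", "GM", "CC_FREEHAND", "CC_CROI", "CC_GENU", "CC_SPLENIUM",
                  "PYRAMIDAL", "MCP"),
    mpg_scheme = c(rep(12L, 6L), rep(30L, 6L), 12L, 12L),
    mean    = c(0.218, 0.323, 0.709, 0.858, 0.817, 0.899,
                0.173, 0.328, 0.703, 0.855, 0.812, 0.897,
                0.75, 0.73),
    pi_low  = c(0.077, 0.181, 0.627, 0.731, 0.712, 0.805,
                0.073, 0.175, 0.608, 0.717, 0.685, 0.806,
                0.67, 0.54),
    pi_high = c(0.359, 0.464, 0.792, 0.986, 0.923, 0.994,
                0.273, 0.481, 0.797, 0.992, 0.939, 0.989,
                0.82, 0.93),
    stringsAsFactors = FALSE
  )
  if (!is.null(mpg_scheme)) ref <- ref[ref$mpg_scheme == as.integer(mpg_scheme), ]
  rownames(ref) <- NULL
  ref
}

#' Specify one ROI group for synthetic measurement generation
#'
#' A group spec carries the target population mean, the 95% prediction
#' interval to be recovered, the design (subjects and ROIs per subject) and
#' the split of total variance between subjects (`icc_fraction`, the
#' intraclass correlation) and within subjects.
#'
#' @param roi_group group name (see [LUT_GROUPS]).
#' @param mean population mean FA.
#' @param pi_low,pi_high bounds of the 95% prediction interval for a new
#'   observation; must bracket `mean`.
#' @param n_subjects number of subjects.
#' @param rois_per_subject repeated ROI measurements per subject.
#' @param icc_fraction proportion of total variance between subjects, in (0, 1).
#' @param mpg_scheme 12 or 30.
#' @param roi_labels optional character vector of length `rois_per_subject`.
#' @param roi_kind `"circular"` or `"freehand"`, recycled across labels.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(roi_group, mean, pi_low, pi_high,
                       n_subjects, rois_per_subject,
                       icc_fraction = 0.5, mpg_scheme = 12L,
                       roi_labels = NULL, roi_kind = "circular") {
  stopifnot(is.character(roi_group), length(roi_group) == 1L, nzchar(roi_group))
  if (!(pi_low < mean && mean < pi_high) && !(pi_low == mean && mean == pi_high))
    stop("group_spec: need pi_low < mean < pi_high (group ", roi_group, ")")
  if (!(icc_fraction > 0 && icc_fraction < 1))
    stop("group_spec: icc_fraction must be in (0, 1)")
  if (n_subjects < 1L || rois_per_subject < 1L)
    stop("group_spec: n_subjects and rois_per_subject must be positive")
  if (!as.integer(mpg_scheme) %in% MPG_SCHEMES)
    stop("group_spec: mpg_scheme must be 12 or 30")
  if (is.null(roi_labels))
    roi_labels <- sprintf("%s_%d", tolower(roi_group), seq_len(rois_per_subject))
  if (length(roi_labels) != rois_per_subject)
    stop("group_spec: roi_labels must have length rois_per_subject")
  roi_kind <- rep_len(roi_kind, rois_per_subject)
  if (!all(roi_kind %in% ROI_KINDS))
    stop("group_spec: roi_kind must be 'freehand' or 'circular'")
  structure(list(roi_group = roi_group, mean = mean,
                 pi_low = pi_low, pi_high = pi_high,
                 n_subjects = as.integer(n_subjects),
                 rois_per_subject = as.integer(rois_per_subject),
                 icc_fraction = icc_fraction,
                 mpg_scheme = as.integer(mpg_scheme),
                 roi_labels = roi_labels, roi_kind = roi_kind),
            class = "group_spec")
}

#' Default normative measurement scheme
#'
#' Group specs reproducing the published normative design: 76 subjects, 16
#' ROIs each, partitioned as 2 freehand corpus-callosum selections, 4
#' circular corpus-callosum selections (genu and splenium, pooled into one
#' `CC_CROI` group), 4 gray-matter circular ROIs (bilateral precentral gyrus
#' and thalamus) and 6 basal-ganglia circular ROIs (bilateral putamen,
#' pallidum, caudate). Bilaterality of the partition is a package convention
#' (only the totals, 16 ROIs of which 14 circular, are fixed) and can be
#' overridden by passing custom [group_spec()] objects to
#' [generate_measurements()]. Validation groups (`PYRAMIDAL`, `MCP`,
#' 2 ROIs each: one circular, one freehand) are available via `groups`.
#'
#' @param mpg_scheme 12 or 30.
#' @param n_subjects cohort size (default 76).
#' @param icc_fraction between-subject share of total variance, default 0.5.
#' @param groups which groups to include.
#' @return list of `group_spec` objects.
#' @export
normative_group_specs <- function(mpg_scheme = 12L, n_subjects = 76L,
                                  icc_fraction = 0.5, groups = LUT_GROUPS) {
  ref <- fa_normative_values(mpg_scheme)
  design <- list(
    BG = list(k = 6L, labels = c("putamen_L", "putamen_R", "pallidum_L",
                                 "pallidum_R", "caudate_L", "caudate_R"),
              kind = "circular"),
    GM = list(k = 4L, labels = c("precentral_L", "precentral_R",
                                 "thalamus_L", "thalamus_R"),
              kind = "circular"),
    CC_FREEHAND = list(k = 2L, labels = c("rostrum_genu", "splenium"),
                       kind = "freehand"),
    CC_CROI = list(k = 4L, labels = c("genu_1", "genu_2", "splenium_1",
                                      "splenium_2"),
                   kind = "circular"),
    PYRAMIDAL = list(k = 2L, labels = c("pyramidal_croi", "pyramidal_freehand"),
                     kind = c("circular", "freehand")),
    MCP = list(k = 2L, labels = c("mcp_croi", "mcp_freehand"),
               kind = c("circular", "freehand"))
  )
  unknown <- setdiff(groups, names(design))
  if (length(unknown))
    stop("no built-in design for group(s): ", paste(unknown, collapse = ", "))
  lapply(setNames(groups, groups), function(g) {
    row <- ref[ref$roi_group == g, ]
    if (nrow(row) != 1L)
      stop("no normative values for group ", g, " at ", mpg_scheme, " MPG")
    d <- design[[g]]
    group_spec(g, row$mean, row$pi_low, row$pi_high,
               n_subjects = n_subjects, rois_per_subject = d$k,
               icc_fraction = icc_fraction, mpg_scheme = mpg_scheme,
               roi_labels = d$labels, roi_kind = d$kind)
  })
}

#' Construct / validate a measurement table
#'
#' A measurement table is a data.frame with one FA observation per row and
#' columns `subject_id`, `roi_group`, `roi_label`, `roi_kind`, `mpg_scheme`,
#' `fa`. FA values must be finite and in \[0, 1\];
#' `(subject_id, roi_group, roi_label, mpg_scheme)` must be unique.
#'
#' @param records data.frame with the six schema columns.
#' @param provenance free-text metadata (seed and generator parameters when
#'   synthetic), stored as an attribute.
#' @return the validated table, classed `fa_table`.
#' @export
measurement_table <- function(records, provenance = "") {
  validate_measurement_table(records)
  records$subject_id <- as.character(records$subject_id)
  records$roi_group  <- as.character(records$roi_group)
  records$roi_label  <- as.character(records$roi_label)
  records$roi_kind   <- as.character(records$roi_kind)
  records$mpg_scheme <- as.integer(records$mpg_scheme)
  records$fa         <- as.numeric(records$fa)
  records <- records[, MEASUREMENT_COLUMNS]
  rownames(records) <- NULL
  structure(records, provenance = provenance,
            class = c("fa_table", "data.frame"))
}

#' @rdname measurement_table
#' @export
validate_measurement_table <- function(records) {
  if (!is.data.frame(records)) stop("measurement table must be a data.frame")
  missing <- setdiff(MEASUREMENT_COLUMNS, names(records))
  if (length(missing))
    stop("measurement table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(records) == 0L) return(invisible(records))
  fa <- suppressWarnings(as.numeric(records$fa))
  bad <- which(!is.finite(fa) | fa < 0 | fa > 1)
  if (length(bad))
    stop("fa must be numeric and in [0, 1]; violated at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  mpg <- suppressWarnings(as.integer(records$mpg_scheme))
  bad <- which(!mpg %in% MPG_SCHEMES)
  if (length(bad))
    stop("mpg_scheme must be 12 or 30; violated at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which(!records$roi_kind %in% ROI_KINDS)
  if (length(bad))
    stop("roi_kind must be 'freehand' or 'circular'; violated at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  key <- paste(records$subject_id, records$roi_group,
               records$roi_label, mpg, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject_id, roi_group, roi_label, mpg_scheme) at row(s): ",
         paste(utils::head(which(duplicated(key)), 10L), collapse = ", "))
  invisible(records)
}

#' Read / write measurement tables as CSV
#'
#' Comma-separated UTF-8 text with a mandatory header naming all six schema
#' columns and `.` as decimal mark. `write_measurement_table()` serializes
#' FA at full double precision so that write-then-read is an exact identity.
#'
#' @param path file path.
#' @param sep field delimiter (default comma).
#' @return `read_measurement_table()` returns an `fa_table`;
#'   `write_measurement_table()` returns `path` invisibly.
#' @export
read_measurement_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character")
  missing <- setdiff(MEASUREMENT_COLUMNS, names(raw))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  fa <- suppressWarnings(as.numeric(raw$fa))
  bad <- which(!is.finite(fa) | fa < 0 | fa > 1)
  if (length(bad))
    stop("validation error in ", path, ": fa not numeric in [0, 1] at line(s) ",
         paste(utils::head(bad, 10L) + 1L, collapse = ", "))
  raw$fa <- fa
  measurement_table(raw, provenance = paste0("read from ", path))
}

#' @rdname read_measurement_table
#' @param table an `fa_table` (or conforming data.frame).
#' @export
write_measurement_table <- function(table, path, sep = ",") {
  table <- measurement_table(table, provenance = attr(table, "provenance") %||% "")
  out <- as.data.frame(table)
  out$fa <- sprintf("%.17g", out$fa)  # exact double round trip
  tryCatch(
    write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot write measurement table to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic normative measurement table
#'
#' Draws FA observations from the random-intercept model
#' `y_ij = mean + b_i + e_ij`, `b_i ~ N(0, tau2)`, `e_ij ~ N(0, sigma2)`,
#' per group spec. The total variance is recovered from the prediction
#' interval half-width, `tau2 + sigma2 = ((pi_high - pi_low) / (2 z))^2`
#' with `z = qnorm(0.975)`, and split by `icc_fraction`
#' (`tau2 = icc_fraction * total`). Values are clipped to \[0, 1\] after
#' noise; clipping never drops records, so the table has exactly
#' `sum(n_subjects * rois_per_subject)` rows. Subject identifiers are shared
#' across specs, emulating one cohort measured in every region.
#'
#' @param specs a `group_spec` or list of them (see [normative_group_specs()]).
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @return an `fa_table` with generator provenance.
#' @examples
#' tab <- generate_measurements(normative_group_specs(12), seed = 1)
#' nrow(tab)  # 76 subjects x 16 ROIs = 1216
#' @export
generate_measurements <- function(specs, seed) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L, all(vapply(specs, inherits, TRUE, "group_spec")))
  set.seed(as.integer(seed))
  z <- qnorm(0.975)
  pieces <- lapply(specs, function(sp) {
    total_var <- ((sp$pi_high - sp$pi_low) / (2 * z))^2
    tau <- sqrt(sp$icc_fraction * total_var)
    sig <- sqrt((1 - sp$icc_fraction) * total_var)
    n <- sp$n_subjects; k <- sp$rois_per_subject
    b <- rnorm(n, 0, tau)
    eps <- matrix(rnorm(n * k, 0, sig), nrow = n)
    y <- pmin(pmax(sp$mean + b + eps, 0), 1)  # recycle b down columns
    data.frame(
      subject_id = rep(sprintf("S%03d", seq_len(n)), times = k),
      roi_group  = sp$roi_group,
      roi_label  = rep(sp$roi_labels, each = n),
      roi_kind   = rep(sp$roi_kind, each = n),
      mpg_scheme = sp$mpg_scheme,
      fa = as.vector(y),
      stringsAsFactors = FALSE
    )
  })
  prov <- sprintf("synthetic: seed=%d; groups=%s", as.integer(seed),
                  paste(vapply(specs, `[[`, "", "roi_group"), collapse = "+"))
  measurement_table(do.call(rbind, pieces), provenance = prov)
}
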