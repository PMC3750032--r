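# Geometric FA phantoms and NIfTI scalar-volume I/O.

#' FA volume container
#'
#' A 3D scalar grid of FA values with voxel size in mm. Finite voxels are
#' expected in \[0, 1\]; `NaN` marks background (non-brain).
#'
#' @param data 3D numeric array.
#' @param pixdim voxel size in mm, length-3 (default 2.2 mm isotropic,
#'   matching typical diffusion acquisitions).
#' @return object of class `fa_volume`.
#' @export
fa_volume <- function(data, pixdim = c(2.2, 2.2, 2.2)) {
  if (length(dim(data)) != 3L) stop("fa_volume: data must be a 3D array")
  stopifnot(length(pixdim) == 3L, all(pixdim > 0))
  structure(list(data = data, pixdim = as.numeric(pixdim)),
            class = "fa_volume")
}

#' @export
print.fa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fa_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$pixdim[1], x$pixdim[2], x$pixdim[3]))
  fin <- x$data[is.finite(x$data)]
  if (length(fin))
    cat(sprintf("  finite FA range [%.3f, %.3f], %d NaN voxels\n",
                min(fin), max(fin), sum(!is.finite(x$data))))
  invisible(x)
}

#' Generate a geometric FA phantom
#'
#' Builds a simple head-like phantom: a zero background, an ellipsoidal
#' "gray-matter shell", a central "deep white-matter core" box and a pair of
#' spherical "peduncle" blobs (stand-ins for the middle cerebellar
#' peduncles). Each labeled region receives its configured FA value plus
#' Gaussian noise, clipped to \[0, 1\]; `msa_delta` is subtracted from the
#' peduncle regions before noise, emulating the FA depression seen in
#' multiple system atrophy. The background stays exactly 0.
#'
#' @param shape grid dimensions, length-3 integer.
#' @param region_fa named FA values for `gm_shell`, `wm_core`, `peduncle`.
#'   Defaults: shell 0.25, core 0.70, peduncle 0.82 (the circular-ROI
#'   normative peduncle value).
#' @param noise_sd within-region noise SD in FA units.
#' @param msa_delta FA decrement applied to the peduncle regions.
#' @param seed RNG seed; identical seed and parameters give identical output.
#' @param pixdim voxel size in mm.
#' @return list with `fa` (an [fa_volume()]) and `labels` (integer array,
#'   0 background, 1 shell, 2 core, 3/4 left/right peduncle).
#' @export
generate_phantom <- function(shape = c(48L, 48L, 24L),
                             region_fa = c(gm_shell = 0.25, wm_core = 0.70,
                                           peduncle = 0.82),
                             noise_sd = 0.02, msa_delta = 0, seed = 1L,
                             pixdim = c(2.2, 2.2, 2.2)) {
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  need <- c("gm_shell", "wm_core", "peduncle")
  if (!all(need %in% names(region_fa)))
    stop("region_fa must name: ", paste(need, collapse = ", "))
  if (any(region_fa < 0 | region_fa > 1))
    stop("region FA values must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ped_fa <- region_fa[["peduncle"]] - msa_delta
  if (ped_fa < 0)
    stop("msa_delta = ", msa_delta, " drives peduncle FA below 0")

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  # fractional coordinates in [0, 1]
  fx <- (seq_len(nx) - 0.5) / nx
  fy <- (seq_len(ny) - 0.5) / ny
  fz <- (seq_len(nz) - 0.5) / nz
  X <- array(rep(fx, times = ny * nz), dim = shape)
  Y <- array(rep(rep(fy, each = nx), times = nz), dim = shape)
  Z <- array(rep(fz, each = nx * ny), dim = shape)

  labels <- array(0L, dim = shape)
  shell <- ((X - 0.5) / 0.45)^2 + ((Y - 0.5) / 0.45)^2 + ((Z - 0.5) / 0.45)^2 <= 1
  labels[shell] <- 1L
  core <- abs(X - 0.5) <= 0.15 & abs(Y - 0.5) <= 0.15 & abs(Z - 0.5) <= 0.15
  labels[core] <- 2L
  ped_r2 <- 0.10^2
  pedL <- (X - 0.35)^2 + (Y - 0.5)^2 + (Z - 0.3)^2 <= ped_r2
  pedR <- (X - 0.65)^2 + (Y - 0.5)^2 + (Z - 0.3)^2 <= ped_r2
  labels[pedL] <- 3L
  labels[pedR] <- 4L

  value <- c(region_fa[["gm_shell"]], region_fa[["wm_core"]], ped_fa, ped_fa)
  fa <- array(0, dim = shape)
  set.seed(as.integer(seed))
  for (lab in 1:4) {
    idx <- labels == lab
    n <- sum(idx)
    if (n == 0L) next
    fa[idx] <- pmin(pmax(value[lab] + rnorm(n, 0, noise_sd), 0), 1)
  }
  list(fa = fa_volume(fa, pixdim), labels = labels)
}

#' Write / load FA volumes as NIfTI-1
#'
#' `write_fa()` stores the volume with an identity-orientation affine and
#' the voxel size recorded in the header. `load_fa()` reads a 3D NIfTI
#' file, sets values below 0 to 0 and above 1 to 1 (FA is mathematically
#' bounded; excursions are numerical noise), maps non-finite voxels to
#' `NaN`, and records the number of clamped voxels in the `clamped`
#' attribute (also reported via `message()`).
#'
#' @param volume an [fa_volume()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `load_fa()` returns an `fa_volume`; `write_fa()` returns `path`
#'   invisibly.
#' @export
write_fa <- function(volume, path) {
  stopifnot(inherits(volume, "fa_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_fa
#' @export
load_fa <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("format error: expected a 3D FA volume, got ",
         length(d), "D data in ", path)
  x <- as.array(img)
  x[!is.finite(x)] <- NaN
  clamped <- sum(x < 0 | x > 1, na.rm = TRUE)
  x[which(x < 0)] <- 0
  x[which(x > 1)] <- 1
  if (clamped > 0)
    message("load_fa: clamped ", clamped, " voxel(s) into [0, 1]")
  vol <- fa_volume(x, pixdim = RNifti::pixdim(img)[seq_len(3)])
  attr(vol, "clamped") <- clamped
  vol
}
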