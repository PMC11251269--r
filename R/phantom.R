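#' Miniature PET phantom
#'
#' A small SUV-valued 3D volume with spherical "tumour" blobs on a
#' noisy background, plus the blob mask, used to smoke-test the
#' discretisation-sensitivity pipeline end-to-end without real
#' imaging data. Positions and sizes are in mm; voxel centres sit at
#' `(i - 0.5) * voxel_size`.
#'
#' @param shape integer triple, voxel counts per axis.
#' @param voxel_size numeric triple, mm.
#' @param blobs list of `list(centre = c(x, y, z) mm, radius = mm,
#'   intensity = SUV)`.
#' @param background_mean,background_sd background SUV level and noise.
#' @param seed integer RNG seed.
#' @return A `radr_phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(24L, 24L, 16L), voxel_size = c(2, 2, 2),
                         blobs = list(list(centre = c(24, 24, 16),
                                           radius = 10, intensity = 8)),
                         background_mean = 0.5, background_sd = 0.1,
                         seed = 1L) {
  if (!length(blobs)) abort("at least one blob is required")
  extent <- shape * voxel_size
  for (b in blobs) {
    if (any(b$centre - b$radius < 0) || any(b$centre + b$radius > extent)) {
      abort("blob extends outside the volume")
    }
  }
  structure(list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
                 blobs = blobs, background_mean = background_mean,
                 background_sd = background_sd, seed = as.integer(seed)),
            class = "radr_phantom_spec")
}

#' Generate a phantom volume and tumour mask
#'
#' Deterministic given the seed. Background voxels are
#' `N(background_mean, background_sd)`; voxels whose centre lies
#' within a blob's radius take the blob intensity (later blobs win on
#' overlap). Intensities are clipped at 0 SUV.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (3D numeric array, SUV), `mask`
#'   (logical array over the blobs) and `voxel_size`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "radr_phantom_spec"))
  set.seed(spec$seed)
  dims <- spec$shape
  vol <- array(rnorm(prod(dims), spec$background_mean, spec$background_sd),
               dim = dims)
  cx <- (seq_len(dims[1]) - 0.5) * spec$voxel_size[1]
  cy <- (seq_len(dims[2]) - 0.5) * spec$voxel_size[2]
  cz <- (seq_len(dims[3]) - 0.5) * spec$voxel_size[3]
  mask <- array(FALSE, dim = dims)
  for (b in spec$blobs) {
    d2 <- outer(outer((cx - b$centre[1])^2, (cy - b$centre[2])^2, `+`),
                (cz - b$centre[3])^2, `+`)
    inside <- d2 <= b$radius^2
    vol[inside] <- b$intensity
    mask <- mask | inside
  }
  if (!any(mask)) abort("phantom mask is empty; enlarge a blob")
  vol[vol < 0] <- 0
  list(volume = vol, mask = mask, voxel_size = spec$voxel_size)
}

#' Write a phantom as NIfTI
#'
#' Interoperability hook for external feature extractors; requires the
#' RNifti package.
#'
#' @param phantom result of [generate_phantom()].
#' @param volume_path,mask_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_phantom_nifti <- function(phantom, volume_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("writing NIfTI requires the RNifti package")
  }
  img <- RNifti::asNifti(phantom$volume, pixdim = phantom$voxel_size)
  RNifti::writeNifti(img, volume_path)
  msk <- RNifti::asNifti(array(as.integer(phantom$mask),
                               dim = dim(phantom$mask)),
                         pixdim = phantom$voxel_size)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(volume_path, mask_path))
}

#' IBSI-style intensity discretisation
#'
#' `fbw_discretise()` implements the fixed-bin-size rule anchored at
#' the mask minimum: `index = floor((v - min(v)) / w) + 1`.
#' `fbn_discretise()` implements the fixed-bin-number rule
#' `index = min(n, floor(n * (v - min) / (max - min)) + 1)`; constant
#' input maps to bin 1.
#'
#' @param values numeric vector of masked voxel intensities (SUV).
#' @param bin_width bin width in SUV (> 0).
#' @param n_bins number of bins (>= 1).
#' @return Integer bin indices, same length as `values`.
#' @export
fbw_discretise <- function(values, bin_width) {
  if (!length(values)) abort("empty mask: no values to discretise")
  if (bin_width <= 0) abort("bin_width must be > 0")
  as.integer(floor((values - min(values)) / bin_width) + 1)
}

#' @rdname fbw_discretise
#' @export
fbn_discretise <- function(values, n_bins) {
  if (!length(values)) abort("empty mask: no values to discretise")
  if (n_bins < 1) abort("n_bins must be >= 1")
  rng <- max(values) - min(values)
  if (rng == 0) return(rep(1L, length(values)))
  pmin(as.integer(n_bins),
       as.integer(floor(n_bins * (values - min(values)) / rng) + 1))
}

#' First-order histogram features
#'
#' Entropy (bits) and uniformity of the discretised intensity
#' histogram, computed over occupied-bin probabilities: the two
#' first-order features most sensitive to the discretisation setting.
#'
#' @param indices integer bin indices from a discretiser.
#' @return Entropy in bits / uniformity (unitless).
#' @export
first_order_entropy <- function(indices) {
  p <- tabulate(indices)
  p <- p[p > 0] / length(indices)
  -sum(p * log2(p))
}

#' @rdname first_order_entropy
#' @export
first_order_uniformity <- function(indices) {
  p <- tabulate(indices)
  p <- p[p > 0] / length(indices)
  sum(p^2)
}

#' Resample a volume to an isotropic grid
#'
#' Centre-aligned resampling: the output grid has
#' `round(extent / target)` voxels per axis (at least 1) and shares
#' the physical centre of the input. `nearest_neighbour` picks the
#' closest input voxel (so output intensities are a subset of the
#' input's); `linear` is trilinear with edge clamping.
#'
#' @param volume 3D numeric array.
#' @param voxel_size input spacing, mm triple.
#' @param target target isotropic spacing, mm (> 0).
#' @param method `"nearest_neighbour"` or `"linear"`.
#' @return A list with `volume` and `voxel_size = rep(target, 3)`.
#' @export
resample_volume <- function(volume, voxel_size, target,
                            method = c("nearest_neighbour", "linear")) {
  method <- match.arg(method)
  if (target <= 0) abort("target voxel size must be > 0")
  dims <- dim(volume)
  extent <- dims * voxel_size
  n_out <- pmax(1L, as.integer(round(extent / target)))
  # continuous input index of each output voxel centre, per axis
  axis_idx <- lapply(1:3, function(d) {
    centres <- (seq_len(n_out[d]) - 0.5) * target + (extent[d] - n_out[d] * target) / 2
    centres / voxel_size[d] + 0.5
  })
  if (method == "nearest_neighbour") {
    nn <- lapply(1:3, function(d)
      pmin(dims[d], pmax(1L, as.integer(round(axis_idx[[d]])))))
    out <- volume[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(d)
      pmin(dims[d], pmax(1L, as.integer(floor(axis_idx[[d]])))))
    hi <- lapply(1:3, function(d) pmin(dims[d], lo[[d]] + 1L))
    fr <- lapply(1:3, function(d)
      pmin(1, pmax(0, axis_idx[[d]] - lo[[d]])))
    out <- array(0, dim = n_out)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ix <- if (dx) hi[[1]] else lo[[1]]
      iy <- if (dy) hi[[2]] else lo[[2]]
      iz <- if (dz) hi[[3]] else lo[[3]]
      wx <- if (dx) fr[[1]] else 1 - fr[[1]]
      wy <- if (dy) fr[[2]] else 1 - fr[[2]]
      wz <- if (dz) fr[[3]] else 1 - fr[[3]]
      w <- outer(outer(wx, wy), wz)
      out <- out + w * volume[ix, iy, iz, drop = FALSE]
    }
  }
  dimnames(out) <- NULL
  list(volume = out, voxel_size = rep(target, 3))
}
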