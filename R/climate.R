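#' Construct a climate stack
#'
#' A climate stack holds named environmental covariate layers on a common
#' planar grid, tagged with the scenario it represents (time slice,
#' circulation model, emission pathway). Synthetic grids use planar km
#' coordinates; cell centres are at `((col - 0.5), (row - 0.5)) * cell_size_km`.
#'
#' @param layers named list of numeric matrices, all with identical dimensions
#'   and no non-finite values.
#' @param cell_size_km positive cell edge length in km.
#' @param slice one of `"baseline"`, `"2050"`, `"2070"`.
#' @param gcm_id,rcp_id scenario member identifiers; must be `NA` for the
#'   baseline slice.
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(layers, cell_size_km = 10,
                          slice = "baseline", gcm_id = NA_character_,
                          rcp_id = NA_character_) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- lapply(layers, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1L)
    stop("all layers must share the same grid shape")
  if (!all(vapply(layers, function(m) all(is.finite(m)), TRUE)))
    stop("layers must not contain non-finite values")
  if (!is.numeric(cell_size_km) || cell_size_km <= 0)
    stop("cell_size_km must be positive")
  slice <- match.arg(slice, c("baseline", "2050", "2070"))
  if (slice == "baseline" && (!is.na(gcm_id) || !is.na(rcp_id)))
    stop("baseline stacks must have gcm_id = rcp_id = NA")
  structure(list(
    layers = lapply(layers, as.matrix),
    grid_shape = dim(layers[[1]]),
    cell_size_km = cell_size_km,
    scenario = list(slice = slice, gcm_id = gcm_id, rcp_id = rcp_id)
  ), class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("climate_stack: %d x %d grid (%g km cells), %d layer(s): %s\n",
              x$grid_shape[1], x$grid_shape[2], x$cell_size_km,
              length(x$layers), paste(names(x$layers), collapse = ", ")))
  cat(sprintf("scenario: slice=%s gcm=%s rcp=%s\n", sc$slice, sc$gcm_id, sc$rcp_id))
  invisible(x)
}

# row-normalised Gaussian band matrix; edge rows renormalise over the
# truncated kernel so smoothing never leaks mass off the grid
gauss_band <- function(n, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    w <- stats::dnorm(j - i, sd = sigma)
    B[i, j] <- w / sum(w)
  }
  B
}

smooth_field <- function(m, sigma_cells) {
  if (sigma_cells < 1e-8) return(m)
  Br <- gauss_band(nrow(m), sigma_cells)
  Bc <- gauss_band(ncol(m), sigma_cells)
  Br %*% m %*% t(Bc)
}

standardize_field <- function(m) (m - mean(m)) / stats::sd(m)

#' Generate a synthetic baseline climate stack
#'
#' Each layer is a spatially autocorrelated Gaussian random field: iid
#' Gaussian noise smoothed with a separable Gaussian kernel whose standard
#' deviation is `autocorr_length_km` (in km), then standardized to mean 0 and
#' unit variance over the grid. With `autocorr_length_km` shrinking to zero
#' the layers degenerate to iid noise. Deterministic given `seed`.
#'
#' @param grid_shape integer vector `(rows, cols)`; every dimension must be
#'   at least 2.
#' @param variable_names character vector of layer names.
#' @param autocorr_length_km positive autocorrelation length in km.
#' @param cell_size_km cell edge in km (default 10, the modelling resolution).
#' @param seed integer RNG seed.
#' @return a baseline [climate_stack()].
#' @export
generate_climate <- function(grid_shape, variable_names,
                             autocorr_length_km = 50, cell_size_km = 10,
                             seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2, length(variable_names) >= 1)
  if (any(grid_shape < 2)) stop("degenerate grid: every dimension must be >= 2")
  if (autocorr_length_km <= 0) stop("autocorr_length_km must be positive")
  set.seed(seed)
  sigma <- autocorr_length_km / cell_size_km
  layers <- lapply(variable_names, function(v) {
    z <- matrix(stats::rnorm(prod(grid_shape)), grid_shape[1], grid_shape[2])
    standardize_field(smooth_field(z, sigma))
  })
  names(layers) <- variable_names
  climate_stack(layers, cell_size_km = cell_size_km, slice = "baseline")
}

#' Project a baseline stack to a future scenario
#'
#' Adds a pathway-scaled deterministic trend and a smooth perturbation field
#' specific to the circulation model: `future = base + rcp_scale * trend +
#' GCM field`, where the GCM field is a standardized smooth random field
#' scaled to standard deviation `gcm_noise_sd`. The perturbation depends on
#' `gcm_id` (and the layer) but not on `rcp_id`, so the same circulation
#' model perturbs both pathways identically.
#'
#' @param base baseline [climate_stack()].
#' @param trend numeric vector, one entry per layer, in layer (sd) units.
#' @param gcm_noise_sd non-negative sd of the circulation-model perturbation.
#' @param rcp_scale non-negative multiplier applied to `trend` for this
#'   pathway/slice combination.
#' @param slice `"2050"` or `"2070"` (the baseline slice is rejected).
#' @param gcm_id,rcp_id scenario member identifiers.
#' @param autocorr_length_km autocorrelation length of the perturbation field.
#' @param seed integer seed; perturbations for different `gcm_id` differ.
#' @return a future [climate_stack()].
#' @export
shift_climate <- function(base, trend, gcm_noise_sd = 0, rcp_scale = 1,
                          slice, gcm_id = "gcm1", rcp_id = "rcp1",
                          autocorr_length_km = 100, seed = 1L) {
  stopifnot(inherits(base, "climate_stack"))
  if (identical(slice, "baseline")) stop("slice must be a future slice, not baseline")
  slice <- match.arg(slice, c("2050", "2070"))
  nl <- length(base$layers)
  if (length(trend) != nl) stop("trend needs one entry per layer")
  sigma <- autocorr_length_km / base$cell_size_km
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    f <- base$layers[[l]] + rcp_scale * trend[l]
    if (gcm_noise_sd > 0) {
      set.seed(derive_seed(seed, gcm_id, names(base$layers)[l]))
      z <- matrix(stats::rnorm(prod(base$grid_shape)),
                  base$grid_shape[1], base$grid_shape[2])
      f <- f + gcm_noise_sd * standardize_field(smooth_field(z, sigma))
    }
    layers[[l]] <- f
  }
  names(layers) <- names(base$layers)
  climate_stack(layers, cell_size_km = base$cell_size_km,
                slice = slice, gcm_id = gcm_id, rcp_id = rcp_id)
}

#' Derive a child seed from a master seed and string tags
#'
#' Deterministic fan-out of one master seed into per-species, per-algorithm,
#' per-permutation seeds, so execution order cannot change results. Mixes the
#' tags into a 31-bit integer with a multiply-and-add hash.
#'
#' @param master integer master seed.
#' @param ... character or numeric tags.
#' @return integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, ...) {
  tags <- paste(vapply(list(...), paste, "", collapse = "_"), collapse = "|")
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(tags)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Write a climate stack as plain-text layer grids
#'
#' Each layer is written as a headerless CSV matrix next to a JSON sidecar
#' recording grid shape, cell size and scenario tag.
#'
#' @param stack a [climate_stack()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return invisibly, the written file paths.
#' @export
write_climate_stack <- function(stack, dir, prefix = "climate") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in names(stack$layers)) {
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, v))
    utils::write.table(stack$layers[[v]], p, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, sprintf("%s_meta.json", prefix))
  jsonlite::write_json(list(grid_shape = stack$grid_shape,
                            cell_size_km = stack$cell_size_km,
                            scenario = stack$scenario,
                            layers = names(stack$layers)),
                       meta, auto_unbox = TRUE, null = "null")
  invisible(c(paths, meta))
}
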