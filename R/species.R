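#' Define a virtual species by a Gaussian-product niche
#'
#' The species responds to each environmental layer with an independent
#' Gaussian curve; suitability at a cell is the product over layers of
#' `exp(-(v - optimum)^2 / (2 * breadth^2))`. Its true range is the set of
#' cells whose suitability reaches `occupancy_threshold`.
#'
#' @param species_id character identifier.
#' @param optimum named numeric vector of niche optima (names are layer names).
#' @param breadth named numeric vector of strictly positive niche breadths,
#'   same names as `optimum`.
#' @param occupancy_threshold suitability cutoff in (0, 1) defining the true
#'   range.
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(species_id, optimum, breadth,
                            occupancy_threshold = 0.3) {
  stopifnot(length(optimum) == length(breadth),
            identical(names(optimum), names(breadth)))
  if (any(breadth <= 0)) stop("niche breadth must be strictly positive")
  if (occupancy_threshold <= 0 || occupancy_threshold >= 1)
    stop("occupancy_threshold must lie in (0, 1)")
  structure(list(species_id = species_id, optimum = optimum, breadth = breadth,
                 occupancy_threshold = occupancy_threshold),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' @param sp a [virtual_species()].
#' @param clim a [climate_stack()] containing every layer the species
#'   responds to.
#' @return numeric matrix in `[0, 1]` with the grid's shape.
#' @export
true_suitability <- function(sp, clim) {
  stopifnot(inherits(sp, "virtual_species"), inherits(clim, "climate_stack"))
  missing <- setdiff(names(sp$optimum), names(clim$layers))
  if (length(missing))
    stop("climate stack lacks layer(s): ", paste(missing, collapse = ", "))
  s <- matrix(1, clim$grid_shape[1], clim$grid_shape[2])
  for (v in names(sp$optimum)) {
    d <- clim$layers[[v]] - sp$optimum[[v]]
    s <- s * exp(-d^2 / (2 * sp$breadth[[v]]^2))
  }
  s
}

#' True (binary) range of a virtual species
#'
#' @inheritParams true_suitability
#' @return logical matrix: cells with suitability at or above the species'
#'   occupancy threshold.
#' @export
true_range <- function(sp, clim) {
  true_suitability(sp, clim) >= sp$occupancy_threshold
}

cell_centers <- function(rows, cols, cell_size_km) {
  data.frame(x_km = (cols - 0.5) * cell_size_km,
             y_km = (rows - 0.5) * cell_size_km)
}

#' Sample presence records for a virtual species
#'
#' Presence cells are drawn without replacement with probability proportional
#' to true suitability (optionally multiplied by a sampling-bias field), so
#' duplicate coordinates cannot arise. By default the draw is restricted to
#' the occupied (true) range — cells at or above the occupancy threshold —
#' since records of a real species come from where it occurs, not from every
#' cell with nonzero climatic suitability; set `within_range = FALSE` to
#' sample from the full suitability surface. Coordinates are cell centres in
#' km.
#'
#' @param sp a [virtual_species()].
#' @param clim a [climate_stack()].
#' @param n_presence number of presence cells to draw (at least 1).
#' @param bias_field optional non-negative matrix with the grid's shape.
#' @param within_range restrict sampling to the occupied range (default TRUE).
#' @param seed integer seed; the draw is a pure function of it.
#' @return an object of class `occurrence_set` with a `presences` data frame
#'   (`x_km`, `y_km`, `row`, `col`).
#' @export
sample_occurrences <- function(sp, clim, n_presence, bias_field = NULL,
                               within_range = TRUE, seed = 1L) {
  if (n_presence < 1) stop("n_presence must be at least 1")
  w <- true_suitability(sp, clim)
  if (within_range) w <- w * (w >= sp$occupancy_threshold)
  if (!is.null(bias_field)) {
    stopifnot(all(dim(bias_field) == clim$grid_shape), all(bias_field >= 0))
    w <- w * bias_field
  }
  admissible <- which(w > 0)
  if (length(admissible) < n_presence)
    stop(sprintf("only %d admissible cells (positive sampling weight) but %d presences requested",
                 length(admissible), n_presence))
  set.seed(seed)
  idx <- if (length(admissible) == 1L) admissible else
    sample(admissible, n_presence, prob = w[admissible])
  rc <- arrayInd(idx, clim$grid_shape)
  pres <- cbind(cell_centers(rc[, 1], rc[, 2], clim$cell_size_km),
                row = rc[, 1], col = rc[, 2])
  structure(list(species_id = sp$species_id, presences = pres, seed = seed),
            class = "occurrence_set")
}

#' Simulate a virtual community
#'
#' Draws `n_species` virtual species whose optima are the climate values of
#' randomly chosen grid cells (so each species has near-perfect suitability
#' somewhere in the baseline region) and whose per-layer breadths are uniform
#' on `breadth_range` (in layer sd units). Candidate species whose true
#' range covers fewer than `min_range_cells` cells are redrawn (seeded
#' rejection), so every simulated species can supply the occurrence sample
#' the modelling stage asks for; species with vanishing ranges could never
#' have been recorded at the required intensity in the first place.
#'
#' @param n_species number of species.
#' @param clim baseline [climate_stack()].
#' @param breadth_range length-2 numeric range for niche breadths.
#' @param occupancy_threshold shared occupancy threshold.
#' @param min_range_cells minimum true-range size in cells (default 250).
#' @param seed integer seed.
#' @return list of [virtual_species()], named by species id.
#' @export
simulate_virtual_community <- function(n_species, clim,
                                       breadth_range = c(0.5, 1.5),
                                       occupancy_threshold = 0.3,
                                       min_range_cells = 250, seed = 1L) {
  stopifnot(n_species >= 1, inherits(clim, "climate_stack"))
  set.seed(seed)
  vars <- names(clim$layers)
  out <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    for (try in seq_len(1000)) {
      cell <- sample(prod(clim$grid_shape), 1)
      opt <- vapply(clim$layers, function(m) m[cell], 0)
      br <- stats::runif(length(vars), breadth_range[1], breadth_range[2])
      names(br) <- vars
      sp <- virtual_species(sprintf("sp%03d", i), opt, br, occupancy_threshold)
      if (sum(true_range(sp, clim)) >= min_range_cells) break
      sp <- NULL
    }
    if (is.null(sp))
      stop("could not draw a species with a large enough range; widen breadth_range or lower min_range_cells")
    out[[i]] <- sp
  }
  names(out) <- vapply(out, `[[`, "", "species_id")
  out
}

#' Construct a climatic edge specialist
#'
#' A virtual species tied to the lower tail of a single layer: its optimum
#' sits just above the layer's observed minimum, so a sustained positive
#' trend on that layer pushes the whole climate out of its niche and its
#' future range collapses to nothing. The breadth is the smallest value (on
#' a fixed ladder) whose true range reaches `min_cells`, so the species can
#' still supply occurrence samples at the study's intensity.
#'
#' @param clim baseline [climate_stack()].
#' @param layer layer name the species responds to.
#' @param species_id identifier.
#' @param min_cells minimum true-range size in cells.
#' @param occupancy_threshold occupancy cutoff.
#' @return a [virtual_species()].
#' @export
edge_specialist <- function(clim, layer = names(clim$layers)[1],
                            species_id = "edge_specialist", min_cells = 250,
                            occupancy_threshold = 0.3) {
  stopifnot(layer %in% names(clim$layers))
  opt <- stats::setNames(min(clim$layers[[layer]]) + 0.2, layer)
  for (b in seq(0.6, 2.0, by = 0.1)) {
    sp <- virtual_species(species_id, opt, stats::setNames(b, layer),
                          occupancy_threshold)
    if (sum(true_range(sp, clim)) >= min_cells) return(sp)
  }
  stop("no breadth on the ladder reaches the requested range size")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %s, %d presences (seed %d)\n",
              x$species_id, nrow(x$presences), x$seed))
  invisible(x)
}

#' Write occurrence sets as CSV
#'
#' @param occs list of `occurrence_set` objects.
#' @param path output CSV (`species_id, x_km, y_km`).
#' @export
write_occurrences <- function(occs, path) {
  rows <- do.call(rbind, lapply(occs, function(o)
    data.frame(species_id = o$species_id,
               x_km = o$presences$x_km, y_km = o$presences$y_km)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
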