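#' Suitability map container
#'
#' @param species_id species identifier.
#' @param values numeric matrix in `[0, 1]`.
#' @param scenario list with `slice`, `gcm_id`, `rcp_id` (as in a
#'   [climate_stack()]).
#' @param members data frame recording the contributing ensemble members
#'   (`algorithm`, `gcm_id`, `rcp_id`).
#' @param cell_size_km cell edge in km.
#' @return object of class `suitability_map`.
#' @export
suitability_map <- function(species_id, values, scenario, members,
                            cell_size_km = 10) {
  values <- as.matrix(values)
  if (any(values < -1e-9 | values > 1 + 1e-9)) stop("values must lie in [0, 1]")
  structure(list(species_id = species_id, values = pmin(pmax(values, 0), 1),
                 scenario = scenario, members = members,
                 cell_size_km = cell_size_km),
            class = "suitability_map")
}

#' Unweighted ensemble mean of member suitability maps
#'
#' The consensus forecast is the per-cell arithmetic mean over all passing
#' members (algorithms for the baseline; algorithms x circulation models x
#' pathways for future slices); it is invariant to member order.
#'
#' @param member_maps non-empty list of `suitability_map` objects on one grid.
#' @return a `suitability_map` whose `members` stacks all member records.
#' @export
ensemble_mean <- function(member_maps) {
  if (length(member_maps) == 0)
    stop("no passing members: species is unmodelable")
  dims <- vapply(member_maps, function(m) paste(dim(m$values), collapse = "x"), "")
  if (length(unique(dims)) != 1) stop("members must share one grid")
  vals <- Reduce(`+`, lapply(member_maps, `[[`, "values")) / length(member_maps)
  suitability_map(member_maps[[1]]$species_id, vals,
                  member_maps[[1]]$scenario,
                  do.call(rbind, lapply(member_maps, `[[`, "members")),
                  member_maps[[1]]$cell_size_km)
}

#' Consensus binarisation threshold
#'
#' Arithmetic mean of the per-algorithm sensitivity-specificity equality
#' thresholds of the passing members.
#'
#' @param thresholds non-empty numeric vector.
#' @return the mean threshold.
#' @export
consensus_threshold <- function(thresholds) {
  if (length(thresholds) == 0) stop("need at least one threshold")
  mean(thresholds)
}

#' Binarise a suitability map
#'
#' Cells at or above the threshold become presences; connected patches
#' (8-neighbour connectivity, so diagonally touching cells form one
#' continuous area) are labelled and measured.
#'
#' @param map a [suitability_map()] or plain numeric matrix.
#' @param threshold cutoff in `[0, 1]`.
#' @param species_id,scenario,cell_size_km used when `map` is a bare matrix.
#' @return object of class `binary_range`: `mask` (logical matrix),
#'   `threshold_used`, `labels` (integer patch labels, 0 = background),
#'   `patch_areas` (cells per patch), `cell_size_km`, `species_id`,
#'   `scenario`.
#' @export
binarize <- function(map, threshold, species_id = NULL, scenario = NULL,
                     cell_size_km = 10) {
  if (inherits(map, "suitability_map")) {
    values <- map$values
    species_id <- map$species_id
    scenario <- map$scenario
    cell_size_km <- map$cell_size_km
  } else values <- as.matrix(map)
  if (threshold < 0) stop("threshold must be non-negative")
  mask <- values >= threshold
  lab <- label_patches(mask)
  structure(list(species_id = species_id, scenario = scenario, mask = mask,
                 threshold_used = threshold, labels = lab,
                 patch_areas = patch_areas(lab),
                 cell_size_km = cell_size_km),
            class = "binary_range")
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("binary_range%s: %d presence cells in %d patch(es), threshold %.3f\n",
              if (is.null(x$species_id)) "" else paste0(" [", x$species_id, "]"),
              sum(x$mask), length(x$patch_areas), x$threshold_used))
  invisible(x)
}

#' Label connected patches of a binary mask
#'
#' 8-connectivity labelling by iterative minimum-label propagation; labels
#' are renumbered 1..k in order of first (column-major) appearance.
#'
#' @param mask logical matrix.
#' @return integer matrix of patch labels, 0 for background.
#' @export
label_patches <- function(mask) {
  mask <- as.matrix(mask)
  r <- nrow(mask); c <- ncol(mask)
  lab <- matrix(0L, r, c)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  big <- sum(mask) + 1L
  work <- matrix(big, r + 2L, c + 2L)
  repeat {
    work[2:(r + 1), 2:(c + 1)] <- ifelse(mask, lab, big)
    m <- work[2:(r + 1), 2:(c + 1)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      m <- pmin(m, work[(2 + dr):(r + 1 + dr), (2 + dc):(c + 1 + dc)])
    }
    newlab <- ifelse(mask, pmin(lab, m), 0L)
    if (all(newlab == lab)) break
    lab <- newlab
  }
  ids <- unique(lab[lab > 0])
  lab[] <- match(lab, ids, nomatch = 0L)
  matrix(as.integer(lab), r, c)
}

patch_areas <- function(labels) {
  if (!any(labels > 0)) return(integer(0))
  tab <- table(labels[labels > 0])
  stats::setNames(as.integer(tab), names(tab))
}

# minimum cell-centre distance (km) from each cell set to a point set
min_dist_km <- function(cells_rc, points_xy, cell_size_km) {
  if (nrow(cells_rc) == 0 || nrow(points_xy) == 0) return(Inf)
  cx <- (cells_rc[, 2] - 0.5) * cell_size_km
  cy <- (cells_rc[, 1] - 0.5) * cell_size_km
  d2 <- outer(cx, points_xy$x_km, "-")^2 + outer(cy, points_xy$y_km, "-")^2
  sqrt(min(d2))
}

#' Dispersal filter for projected ranges
#'
#' Removes unrealistic isolated patches from a projected (future) binary
#' range. A patch is retained iff it (a) overlaps at least one cell of the
#' species' baseline range, or (b) lies within `max_km` of the main predicted
#' area (the largest patch of the future range, ties broken by label order),
#' or (c) lies within `max_km` of any known occurrence record. Distances are
#' minimum cell-centre to cell-centre (edge-to-edge at cell resolution), in
#' km on the planar grid; patches farther than `max_km` on every criterion
#' are deleted, a patch at exactly `max_km` is kept. Baseline ranges are
#' never filtered; an empty future mask is returned unchanged. The filter is
#' idempotent.
#'
#' @param future `binary_range` of a future slice.
#' @param baseline `binary_range` of the species' baseline prediction, same
#'   grid.
#' @param occurrences optional data frame of occurrence records with
#'   `x_km`/`y_km` columns.
#' @param max_km distance cutoff (default 400).
#' @return the filtered `binary_range`, with a `removal_log` data frame
#'   (`patch`, `area_cells`, `reason`) attached.
#' @export
dispersal_filter <- function(future, baseline, occurrences = NULL,
                             max_km = 400) {
  stopifnot(inherits(future, "binary_range"), inherits(baseline, "binary_range"))
  if (!all(dim(future$mask) == dim(baseline$mask)))
    stop("future and baseline ranges must share one grid")
  if (!any(future$mask)) {
    future$removal_log <- empty_removal_log()
    return(future)
  }
  lab <- future$labels
  areas <- future$patch_areas
  main_id <- as.integer(names(areas)[which.max(areas)])
  main_rc <- which(lab == main_id, arr.ind = TRUE)
  main_xy <- data.frame(x_km = (main_rc[, 2] - 0.5) * future$cell_size_km,
                        y_km = (main_rc[, 1] - 0.5) * future$cell_size_km)
  log <- empty_removal_log()
  keep_mask <- future$mask
  for (id in as.integer(names(areas))) {
    rc <- which(lab == id, arr.ind = TRUE)
    if (any(baseline$mask[rc])) next                          # (a) overlap
    d_main <- if (id == main_id) 0 else
      min_dist_km(rc, main_xy, future$cell_size_km)
    if (d_main <= max_km) next                                # (b) near main
    d_occ <- if (is.null(occurrences) || nrow(occurrences) == 0) Inf else
      min_dist_km(rc, occurrences, future$cell_size_km)
    if (d_occ <= max_km) next                                 # (c) near record
    keep_mask[rc] <- FALSE
    log <- rbind(log, data.frame(
      patch = id, area_cells = unname(areas[as.character(id)]),
      reason = sprintf("no overlap; %.0f km from main area, %.0f km from records",
                       d_main, d_occ)))
  }
  out <- binarize(keep_mask * 1, 0.5, species_id = future$species_id,
                  scenario = future$scenario,
                  cell_size_km = future$cell_size_km)
  out$threshold_used <- future$threshold_used
  out$removal_log <- log
  out
}

empty_removal_log <- function() {
  data.frame(patch = integer(0), area_cells = integer(0),
             reason = character(0))
}

#' Species with no climatically suitable area in future slices
#'
#' @param ranges nested list: `ranges[[species]][[slice]]` giving the
#'   dispersal-filtered `binary_range` of each species for each future slice.
#' @return list with per-slice character vectors of species whose mask is
#'   empty, plus a `table` data frame classifying species as losing all area
#'   in both slices (`"2050/2070"`) or in one slice only.
#' @export
detect_total_loss <- function(ranges) {
  slices <- unique(unlist(lapply(ranges, names)))
  by_slice <- lapply(slices, function(sl) {
    names(ranges)[vapply(ranges, function(r)
      sl %in% names(r) && !any(r[[sl]]$mask), TRUE)]
  })
  names(by_slice) <- slices
  all_sp <- unique(unlist(by_slice))
  category <- vapply(all_sp, function(sp) {
    hit <- slices[vapply(slices, function(sl) sp %in% by_slice[[sl]], TRUE)]
    paste(sort(hit), collapse = "/")
  }, "")
  list(by_slice = by_slice,
       table = data.frame(species = all_sp, lost_in = unname(category)))
}
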