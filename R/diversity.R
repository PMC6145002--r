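#' Coarse grid system over a fine raster
#'
#' Maps every fine raster cell to a coarse analysis cell (default 50 km on a
#' 10 km raster, i.e. 5x5 blocks), anchored at the grid origin. Only coarse
#' cells with at least one fine cell inside the region mask are retained;
#' partial edge cells are kept.
#'
#' @param grid_shape fine grid `(rows, cols)`.
#' @param cell_size_km fine cell edge (km).
#' @param coarse_km coarse cell edge (km), a positive multiple of the fine
#'   edge is recommended.
#' @param region_mask optional logical matrix (fine grid) delimiting the
#'   study region; default all cells.
#' @return object of class `grid_system`: `site_of` (integer matrix mapping
#'   fine cells to site ids, NA outside the region), `sites` (data frame
#'   `site_id, coarse_row, coarse_col, x_km, y_km, n_fine`).
#' @export
grid_system <- function(grid_shape, cell_size_km = 10, coarse_km = 50,
                        region_mask = NULL) {
  stopifnot(coarse_km > 0, cell_size_km > 0)
  f <- coarse_km / cell_size_km
  rows <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  cols <- matrix(rep(seq_len(grid_shape[2]), each = grid_shape[1]),
                 grid_shape[1], grid_shape[2])
  cr <- ceiling(rows / f); cc <- ceiling(cols / f)
  ncc <- max(cc)
  raw_id <- (cr - 1L) * ncc + cc
  if (is.null(region_mask)) region_mask <- matrix(TRUE, grid_shape[1], grid_shape[2])
  stopifnot(all(dim(region_mask) == grid_shape))
  raw_id[!region_mask] <- NA_integer_
  kept <- sort(unique(raw_id[!is.na(raw_id)]))
  site_of <- matrix(match(raw_id, kept), grid_shape[1], grid_shape[2])
  site_cr <- ((kept - 1L) %/% ncc) + 1L
  site_cc <- ((kept - 1L) %% ncc) + 1L
  sites <- data.frame(site_id = seq_along(kept),
                      coarse_row = site_cr, coarse_col = site_cc,
                      x_km = (site_cc - 0.5) * coarse_km,
                      y_km = (site_cr - 0.5) * coarse_km,
                      n_fine = as.integer(table(factor(site_of, levels = seq_along(kept)))))
  structure(list(site_of = site_of, sites = sites,
                 coarse_km = coarse_km, cell_size_km = cell_size_km,
                 grid_shape = grid_shape),
            class = "grid_system")
}

#' Aggregate a fine binary range to coarse sites
#'
#' A species is present in a coarse cell iff it is present in at least one
#' constituent fine cell (union rule).
#'
#' @param range a `binary_range` or logical matrix on the fine grid.
#' @param grid a [grid_system()].
#' @return logical vector over the grid's sites.
#' @export
aggregate_to_grid <- function(range, grid) {
  mask <- if (inherits(range, "binary_range")) range$mask else as.matrix(range)
  stopifnot(all(dim(mask) == grid$grid_shape))
  inside <- !is.na(grid$site_of)
  if (!any(inside)) {
    warning("range does not overlap the region mask")
    return(logical(nrow(grid$sites)))
  }
  hit <- tapply(mask[inside], grid$site_of[inside], any)
  out <- logical(nrow(grid$sites))
  out[as.integer(names(hit))] <- as.logical(hit)
  out
}

#' Presence-absence matrix from binary ranges
#'
#' @param ranges named list of `binary_range` objects (one per species) on a
#'   common fine grid.
#' @param grid a [grid_system()].
#' @return logical sites x species matrix with site ids as row names.
#' @export
build_pa_matrix <- function(ranges, grid) {
  pa <- vapply(ranges, aggregate_to_grid, logical(nrow(grid$sites)), grid = grid)
  rownames(pa) <- grid$sites$site_id
  pa
}

#' Per-site species richness
#'
#' @param pa logical/0-1 sites x species matrix.
#' @return integer vector of row sums.
#' @export
richness <- function(pa) {
  as.integer(rowSums(pa))
}

#' Per-site richness change and gain/loss classification
#'
#' @param current,future richness vectors on identical sites.
#' @return data frame `delta` (future - current) and `class` with levels
#'   loss/stable/gain.
#' @export
richness_change <- function(current, future) {
  if (length(current) != length(future))
    stop("current and future richness must cover the same sites")
  delta <- as.integer(future) - as.integer(current)
  cls <- cut(sign(delta), breaks = c(-1.5, -0.5, 0.5, 1.5),
             labels = c("loss", "stable", "gain"))
  data.frame(delta = delta, class = cls)
}

#' Paired t test of future vs current richness
#'
#' Classical paired t statistic on per-site differences (future - current),
#' two-sided.
#'
#' @param current,future per-site richness vectors, paired by site.
#' @return list `t`, `p`, `df`, `mean_diff`.
#' @export
paired_richness_test <- function(current, future) {
  if (length(current) != length(future) || length(current) < 2)
    stop("need >= 2 paired sites")
  d <- future - current
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t statistic undefined")
  ht <- stats::t.test(future, current, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}

#' Jaccard pair counts
#'
#' @param x1,x2 logical/0-1 species vectors of two sites.
#' @return list `a` (shared), `b` (only site 1), `c` (only site 2).
#' @export
pair_counts <- function(x1, x2) {
  x1 <- as.logical(x1); x2 <- as.logical(x2)
  list(a = sum(x1 & x2), b = sum(x1 & !x2), c = sum(!x1 & x2))
}

#' Jaccard dissimilarity from pair counts
#'
#' `D = (b + c) / (a + b + c)`; undefined (error) when both sites are empty.
#'
#' @param a,b,c non-negative pair counts.
#' @return dissimilarity in `[0, 1]`.
#' @export
jaccard_d <- function(a, b, c) {
  if (a + b + c <= 0) stop("Jaccard dissimilarity undefined for two empty sites")
  (b + c) / (a + b + c)
}

#' Baselga-family decomposition of Jaccard dissimilarity
#'
#' Splits `D = (b+c)/(a+b+c)` into a replacement (turnover) part
#' `Repl = 2 min(b,c) / (a + 2 min(b,c))` and a nestedness-resultant part
#' `Nes = D - Repl`, and reports the similarity `S = 1 - D`. Every triplet
#' `(S, Repl, Nes)` is non-negative and sums to 1.
#'
#' @inheritParams jaccard_d
#' @return list `S`, `Repl`, `Nes`, `D`.
#' @export
decompose_pair <- function(a, b, c) {
  d <- jaccard_d(a, b, c)
  m <- min(b, c)
  repl <- if (a + 2 * m == 0) 0 else 2 * m / (a + 2 * m)
  list(S = 1 - d, Repl = repl, Nes = d - repl, D = d)
}

# pairwise a/b/c over all site pairs, vectorised
pair_count_matrices <- function(pa) {
  pa <- matrix(as.numeric(pa), nrow(pa), ncol(pa))
  A <- tcrossprod(pa)
  ri <- rowSums(pa)
  B <- ri - A          # species only in site i (row)
  C <- t(B)            # species only in site j (col)
  list(a = A, b = B, c = C)
}

#' Jaccard dissimilarity matrix of a presence-absence matrix
#'
#' @param pa logical/0-1 sites x species matrix; no site may be empty.
#' @return symmetric dissimilarity matrix.
#' @export
jaccard_matrix <- function(pa) {
  if (any(rowSums(pa) == 0))
    stop("empty sites must be removed before computing Jaccard dissimilarities")
  pc <- pair_count_matrices(pa)
  D <- (pc$b + pc$c) / (pc$a + pc$b + pc$c)
  diag(D) <- 0
  dimnames(D) <- list(rownames(pa), rownames(pa))
  D
}

#' Decomposition triplets for all site pairs
#'
#' @param pa logical/0-1 sites x species matrix without empty sites.
#' @return data frame `site_i, site_j, S, Repl, Nes` over all unordered
#'   pairs.
#' @export
decompose_pairs <- function(pa) {
  if (any(rowSums(pa) == 0))
    stop("empty sites must be removed before decomposition")
  pc <- pair_count_matrices(pa)
  ut <- upper.tri(pc$a)
  a <- pc$a[ut]; b <- pc$b[ut]; c <- pc$c[ut]
  d <- (b + c) / (a + b + c)
  m <- pmin(b, c)
  repl <- ifelse(a + 2 * m == 0, 0, 2 * m / (a + 2 * m))
  ij <- which(ut, arr.ind = TRUE)
  ids <- if (is.null(rownames(pa))) as.character(seq_len(nrow(pa))) else rownames(pa)
  data.frame(site_i = ids[ij[, 1]], site_j = ids[ij[, 2]],
             S = 1 - d, Repl = repl, Nes = d - repl)
}

#' Local contributions to beta diversity
#'
#' Computes the total variance of community composition from the Jaccard
#' dissimilarity matrix and partitions it among sites: with `A = -D^2 / 2`
#' and `G` its double-centred form, `SStotal = trace(G)` (which equals the
#' pairwise form `sum(d_ij^2) / n`), `BDtotal = SStotal / (n - 1)`, and
#' `LCBD_i = G_ii / SStotal`, summing to 1 over sites. Large LCBD flags
#' sites of unusual composition. Empty sites (no predicted species) are
#' excluded before the computation and reported.
#'
#' @param pa logical/0-1 sites x species matrix.
#' @return object of class `lcbd_result`: `lcbd` (named by site), `sstotal`,
#'   `bdtotal`, `n_sites`, `excluded_sites`, `mean_pairwise_d`.
#' @export
lcbd <- function(pa) {
  pa <- as.matrix(pa) * 1
  if (is.null(rownames(pa))) rownames(pa) <- seq_len(nrow(pa))
  excluded <- rownames(pa)[rowSums(pa) == 0]
  pa <- pa[rowSums(pa) > 0, , drop = FALSE]
  n <- nrow(pa)
  if (n < 2) stop("need at least two non-empty sites")
  D <- jaccard_matrix(pa)
  comp <- lcbd_from_d(D)
  if (comp$sstotal <= 1e-12)
    stop("all sites identical: SStotal = 0, LCBD undefined")
  structure(list(lcbd = stats::setNames(comp$lcbd, rownames(pa)),
                 sstotal = comp$sstotal,
                 bdtotal = comp$sstotal / (n - 1),
                 n_sites = n, excluded_sites = excluded,
                 mean_pairwise_d = mean(D[upper.tri(D)])),
            class = "lcbd_result")
}

# Gower-centred partition of a squared dissimilarity matrix
lcbd_from_d <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  rm <- rowMeans(A); gm <- mean(A)
  g_diag <- diag(A) - 2 * rm + gm
  sstotal <- sum(g_diag)
  list(lcbd = if (sstotal > 0) g_diag / sstotal else rep(NA_real_, n),
       sstotal = sstotal)
}

#' @export
print.lcbd_result <- function(x, ...) {
  cat(sprintf("LCBD over %d sites (%d empty excluded): SStotal %.4f, BDtotal %.4f, mean pairwise D %.4f\n",
              x$n_sites, length(x$excluded_sites), x$sstotal, x$bdtotal,
              x$mean_pairwise_d))
  invisible(x)
}

#' Permutation test for LCBD
#'
#' Under the null, species are distributed independently of one another
#' across sites: each permutation shuffles every species column
#' independently. The p-value for site `i` uses the add-one estimator
#' `p_i = (1 + #\{LCBD*_i >= LCBD_i\}) / (1 + n_used)`. Permutations whose
#' matrix has an undefined Jaccard pair (two empty sites) or zero SStotal
#' are skipped and counted.
#'
#' @param pa logical/0-1 sites x species matrix.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param alpha significance level for the reported flag (default 0.05).
#' @return the [lcbd()] result with added `p_value` (per retained site),
#'   `significant` (`p_value < alpha`), `n_perm_used`, `n_perm_skipped`,
#'   `seed`.
#' @export
lcbd_permutation_test <- function(pa, n_perm = 999, seed = 1L, alpha = 0.05) {
  obs <- lcbd(pa)
  pa <- as.matrix(pa) * 1
  if (is.null(rownames(pa))) rownames(pa) <- seq_len(nrow(pa))
  pa <- pa[rowSums(pa) > 0, , drop = FALSE]
  n <- nrow(pa)
  set.seed(seed)
  exceed <- numeric(n)
  used <- skipped <- 0L
  for (b in seq_len(n_perm)) {
    perm <- apply(pa, 2, function(col) col[sample.int(n)])
    pc <- pair_count_matrices(perm)
    tot <- pc$a + pc$b + pc$c
    if (any(tot[upper.tri(tot)] == 0)) { skipped <- skipped + 1L; next }
    D <- (pc$b + pc$c) / tot
    diag(D) <- 0
    comp <- lcbd_from_d(D)
    if (comp$sstotal <= 1e-12) { skipped <- skipped + 1L; next }
    used <- used + 1L
    exceed <- exceed + (comp$lcbd >= obs$lcbd - 1e-12)
  }
  obs$p_value <- stats::setNames((1 + exceed) / (1 + used), names(obs$lcbd))
  obs$significant <- obs$p_value < alpha
  obs$n_perm_used <- used
  obs$n_perm_skipped <- skipped
  obs$seed <- seed
  obs
}

#' Graded range contraction scenario
#'
#' Builds a pure-contraction future (every species' future mask is a subset
#' of its current mask) by the mechanism climate change is expected to drive:
#' a spatial stress gradient extirpates species from cells, and tolerance to
#' stress scales with range size, so narrow-ranged specialists are lost
#' first while widespread species persist. Cells under high stress retain
#' nested subsets of the richer, low-stress cells' communities, which raises
#' the nestedness component of beta diversity. Uniform random thinning does
#' not have this property (it pushes pairs toward disjointness instead).
#'
#' @param masks named list of logical range masks on a common grid.
#' @param stress numeric matrix in `[0, 1]` on the same grid; defaults to a
#'   linear gradient along columns.
#' @param tolerance optional named vector in `[0, 1]` per species; defaults
#'   to `0.2 + 0.8 * rank(range size) / n`, so the most widespread species
#'   tolerates (almost) all stress.
#' @return named list of contracted masks, same order as `masks`.
#' @export
contract_ranges <- function(masks, stress = NULL, tolerance = NULL) {
  stopifnot(length(masks) >= 1)
  d <- dim(masks[[1]])
  if (is.null(stress))
    stress <- matrix(rep(seq(0, 1, length.out = d[2]), each = d[1]), d[1], d[2])
  stopifnot(all(dim(stress) == d), all(stress >= 0 & stress <= 1))
  if (is.null(tolerance)) {
    sizes <- vapply(masks, sum, 0)
    tolerance <- 0.2 + 0.8 * rank(sizes, ties.method = "first") / length(masks)
  }
  out <- lapply(seq_along(masks), function(i)
    masks[[i]] & (stress <= tolerance[[i]]))
  names(out) <- names(masks)
  out
}

#' Range expansion scenario
#'
#' Dilates every species' mask by `k` rings of 8-neighbour cells, a pure
#' expansion (every future mask is a superset of the current one) that
#' homogenises composition across sites and lowers total beta diversity.
#'
#' @param masks named list of logical range masks on a common grid.
#' @param k number of dilation rings (default 3).
#' @return named list of expanded masks.
#' @export
expand_ranges <- function(masks, k = 3) {
  dil <- function(m) {
    r <- nrow(m); c <- ncol(m)
    for (it in seq_len(k)) {
      w <- matrix(FALSE, r + 2L, c + 2L)
      w[2:(r + 1), 2:(c + 1)] <- m
      acc <- m
      for (dr in -1:1) for (dc in -1:1)
        acc <- acc | w[(2 + dr):(r + 1 + dr), (2 + dc):(c + 1 + dc)]
      m <- acc
    }
    m
  }
  lapply(masks, dil)
}

#' Mean decomposition triplet (ternary centroid)
#'
#' @param triplets data frame with `S`, `Repl`, `Nes` columns (one row per
#'   site pair).
#' @return list `S`, `Repl`, `Nes` (componentwise means, summing to 1).
#' @export
mean_triplet <- function(triplets) {
  if (nrow(triplets) == 0) stop("need at least one pair")
  as.list(colMeans(triplets[, c("S", "Repl", "Nes")]))
}

#' Cartesian coordinates of a triplet in the ternary plot
#'
#' Vertices: Repl at (0, 0), Nes at (1, 0), S at (1/2, sqrt(3)/2).
#'
#' @param S,Repl,Nes triplet components (vectors allowed), summing to 1.
#' @return data frame `x`, `y`.
#' @export
ternary_coords <- function(S, Repl, Nes) {
  data.frame(x = Nes + S / 2, y = S * sqrt(3) / 2)
}

#' Ternary plot of decomposition triplets
#'
#' Draws all site-pair triplets inside the similarity/replacement/nestedness
#' triangle and marks their centroid.
#'
#' @param triplets data frame with `S`, `Repl`, `Nes`.
#' @param main plot title.
#' @param ... passed to [graphics::points()] for the pair cloud.
#' @return invisibly, the centroid triplet.
#' @export
plot_ternary <- function(triplets, main = "Beta-diversity decomposition", ...) {
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.05, sqrt(3) / 2 + 0.1),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  graphics::text(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2) + c(-0.04, -0.04, 0.05),
                 c("Repl", "Nes", "S"))
  xy <- ternary_coords(triplets$S, triplets$Repl, triplets$Nes)
  graphics::points(xy$x, xy$y, pch = 16, cex = 0.4,
                   col = grDevices::grey(0.3, 0.5), ...)
  cen <- mean_triplet(triplets)
  cxy <- ternary_coords(cen$S, cen$Repl, cen$Nes)
  graphics::points(cxy$x, cxy$y, pch = 19, col = "blue", cex = 1.6)
  invisible(cen)
}
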