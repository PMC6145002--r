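#' Variance inflation factors
#'
#' For every variable `j`, `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the
#' coefficient of determination of an ordinary least-squares regression (with
#' intercept) of variable `j` on all the others. Perfectly collinear
#' variables get `VIF = Inf`; VIF is invariant to affine rescaling of the
#' columns.
#'
#' @param x numeric matrix or data frame, observations in rows, at least
#'   `ncol(x) + 2` rows, every column with nonzero variance.
#' @return named numeric vector of VIFs, each at least 1.
#' @export
compute_vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stop("need at least two variables")
  if (nrow(x) < p + 2) stop("need at least ncol(x) + 2 observations")
  if (any(apply(x, 2, stats::sd) == 0)) stop("every variable needs nonzero variance")
  vif <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  names(vif) <- colnames(x)
  vif
}

#' Iterative VIF-based variable selection
#'
#' Repeatedly removes the single variable with the largest VIF (ties broken
#' by input order) and recomputes, stopping once every remaining VIF is
#' strictly below `threshold`. A boundary VIF exactly equal to the threshold
#' still triggers removal. At least one variable is always retained, and each
#' iteration strictly reduces the variable count, so the loop runs at most
#' `ncol(x) - 1` times.
#'
#' When the input raster has many cells, VIF is conventionally computed on a
#' seeded subsample; [run_pipeline()] subsamples above 1e5 cells and records
#' it in the report.
#'
#' @param x numeric matrix or data frame (observations x variables) with
#'   column names.
#' @param threshold VIF cutoff (default 10).
#' @return an object of class `vif_report`: `retained` (names), `removed`
#'   (names in removal order), `iterations` (list of per-iteration VIF
#'   vectors), `threshold`, `n_obs`.
#' @export
select_variables <- function(x, threshold = 10) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  if (ncol(x) < 2) stop("need at least two variables")
  removed <- character(0)
  iterations <- list()
  repeat {
    if (ncol(x) == 1) break  # at least one variable always retained
    vif <- compute_vif(x)
    iterations[[length(iterations) + 1L]] <- vif
    if (all(vif < threshold)) break
    worst <- which.max(vif)  # ties: first in input order
    removed <- c(removed, colnames(x)[worst])
    x <- x[, -worst, drop = FALSE]
  }
  structure(list(retained = colnames(x), removed = removed,
                 iterations = iterations, threshold = threshold,
                 n_obs = nrow(x)),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("VIF selection (threshold %g, %d observations)\n",
              x$threshold, x$n_obs))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$removed))
    cat("removed (in order):", paste(x$removed, collapse = ", "), "\n")
  else cat("removed: none\n")
  invisible(x)
}

#' @export
#' @rdname select_variables
#' @param report a `vif_report`.
#' @param path output CSV path.
write_vif_report <- function(report, path) {
  rows <- do.call(rbind, lapply(seq_along(report$iterations), function(i) {
    v <- report$iterations[[i]]
    data.frame(iteration = i, variable = names(v), vif = unname(v))
  }))
  rows$retained <- rows$variable %in% report$retained
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
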