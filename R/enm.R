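#' Drop species with too few occurrence records
#'
#' Presences are collapsed to unique raster cells first, so the rule counts
#' informative cells, not raw records.
#'
#' @param occs named list of `occurrence_set` objects (or data frames with
#'   `row`/`col` columns).
#' @param min_records minimum number of unique presence cells (default 5).
#' @return named list with the retained occurrence sets; the counts of all
#'   input species are attached as attribute `counts`.
#' @export
filter_rare_species <- function(occs, min_records = 5) {
  if (length(occs) == 0) {
    warning("no species supplied")
    return(occs)
  }
  counts <- vapply(occs, function(o) {
    p <- if (inherits(o, "occurrence_set")) o$presences else o
    nrow(unique(p[, c("row", "col")]))
  }, 0L)
  keep <- counts >= min_records
  out <- occs[keep]
  attr(out, "counts") <- counts
  out
}

#' Sample background (pseudo-absence) cells
#'
#' Uniform draw, without replacement, over cells not occupied by a presence.
#'
#' @param clim a [climate_stack()] defining the grid.
#' @param presences data frame with `row`/`col` presence cells.
#' @param n_background number of background cells.
#' @param seed integer seed.
#' @return data frame `x_km, y_km, row, col`.
#' @export
make_background <- function(clim, presences, n_background, seed = 1L) {
  stopifnot(inherits(clim, "climate_stack"), n_background >= 0)
  if (n_background == 0)
    return(data.frame(x_km = numeric(0), y_km = numeric(0),
                      row = integer(0), col = integer(0)))
  pres_idx <- (presences$col - 1L) * clim$grid_shape[1] + presences$row
  pool <- setdiff(seq_len(prod(clim$grid_shape)), pres_idx)
  if (length(pool) < n_background)
    stop(sprintf("only %d non-presence cells but %d background requested",
                 length(pool), n_background))
  set.seed(seed)
  idx <- if (length(pool) == 1L) pool else sample(pool, n_background)
  rc <- arrayInd(idx, clim$grid_shape)
  cbind(cell_centers(rc[, 1], rc[, 2], clim$cell_size_km),
        row = rc[, 1], col = rc[, 2])
}

#' Stratified train/test split
#'
#' @param labels 0/1 vector.
#' @param test_frac held-out fraction (default 0.2).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`; stratified by label,
#'   disjoint and exhaustive.
#' @export
train_test_split <- function(labels, test_frac = 0.2, seed = 1L) {
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(test_frac * length(idx)))
    if (n_test >= length(idx)) n_test <- length(idx) - 1L
    take <- if (length(idx) == 1L) idx else sample(idx, n_test)
    test <- c(test, take)
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

# layer values at given cells, as a covariates data frame
extract_covariates <- function(clim, cells, variables = names(clim$layers)) {
  idx <- (cells$col - 1L) * clim$grid_shape[1] + cells$row
  out <- lapply(clim$layers[variables], function(m) m[idx])
  as.data.frame(out)
}

# all cells of the grid, in column-major cell order
grid_covariates <- function(clim, variables = names(clim$layers)) {
  as.data.frame(lapply(clim$layers[variables], as.vector))
}

#' Fit a niche model
#'
#' One interface over the four algorithm families used for
#' presence/background suitability modelling:
#' \describe{
#'   \item{glm}{binomial GLM with logit link, linear plus quadratic terms in
#'     each covariate (the standard parametric response shape for unimodal
#'     niches).}
#'   \item{brt}{boosted regression trees: stagewise gradient boosting of
#'     shallow trees (depth 3, learning rate 0.1, 100 rounds, logistic loss),
#'     via xgboost on a single thread.}
#'   \item{rf}{random forest of 500 probability trees (randomForest).}
#'   \item{svm}{radial-kernel support vector machine with Platt-scaled
#'     class probabilities (e1071).}
#' }
#' All fits are seeded and deterministic given the seed; predictions are
#' suitability scores in `[0, 1]`.
#'
#' @param x data frame of covariates at training points.
#' @param y 0/1 labels (1 = presence); both classes must be present.
#' @param algorithm one of `"glm"`, `"brt"`, `"rf"`, `"svm"`.
#' @param seed integer seed.
#' @return an object of class `enm_model` with a [predict.enm_model()] method.
#' @export
enm_fit <- function(x, y, algorithm = c("glm", "brt", "rf", "svm"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- as.data.frame(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("training labels contain a single class; cannot fit")
  set.seed(seed)
  fit <- switch(algorithm,
    glm = {
      # unimodal (or monotone) response in each covariate: quadratic terms
      # with positive coefficients make the logit convex and explode under
      # projection to novel climates, so they are dropped until the
      # remaining response surface is concave
      d <- cbind(aug_quadratic(x), .y = y)
      repeat {
        fit <- suppressWarnings(stats::glm(.y ~ ., data = d,
                                           family = stats::binomial()))
        co <- stats::coef(fit)
        sq <- grep("_sq$", names(co), value = TRUE)
        bad <- sq[!is.na(co[sq]) & co[sq] > 0]
        if (length(bad) == 0) break
        worst <- bad[which.max(co[bad])]
        d <- d[, setdiff(names(d), worst), drop = FALSE]
      }
      fit
    },
    brt = xgboost::xgboost(
      x = as.matrix(x), y = factor(y, levels = c(0, 1)),
      objective = "binary:logistic", nrounds = 100, max_depth = 3,
      learning_rate = 0.1, nthreads = 1, verbosity = 0),
    rf = randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                    ntree = 500),
    svm = e1071::svm(x = as.matrix(x), y = factor(y, levels = c(0, 1)),
                     kernel = "radial", probability = TRUE)
  )
  structure(list(algorithm = algorithm, fit = fit,
                 features = names(x), seed = seed),
            class = "enm_model")
}

aug_quadratic <- function(x) {
  sq <- as.data.frame(lapply(x, function(v) v^2))
  names(sq) <- paste0(names(x), "_sq")
  cbind(x, sq)
}

#' Predict suitability from a fitted niche model
#'
#' @param object an [enm_fit()] model.
#' @param newdata data frame of covariates.
#' @param ... unused.
#' @return numeric vector of suitability scores in `[0, 1]`.
#' @export
predict.enm_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$features, drop = FALSE]
  out <- switch(object$algorithm,
    glm = unname(stats::predict(object$fit, aug_quadratic(newdata),
                                type = "response")),
    brt = as.numeric(stats::predict(object$fit, as.matrix(newdata))),
    rf = unname(stats::predict(object$fit, newdata, type = "prob")[, "1"]),
    svm = {
      p <- stats::predict(object$fit, as.matrix(newdata), probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    }
  )
  pmin(1, pmax(0, as.numeric(out)))
}

#' @export
print.enm_model <- function(x, ...) {
  cat(sprintf("enm_model: %s on %d covariate(s) [%s], seed %d\n",
              x$algorithm, length(x$features),
              paste(x$features, collapse = ", "), x$seed))
  invisible(x)
}

#' Rank-based AUC
#'
#' The Mann-Whitney estimator: the probability that a presence outscores a
#' background point, ties counting one half.
#'
#' @param scores_presence,scores_background non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (np == 0 || nb == 0) stop("both score vectors must be non-empty")
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' True skill statistic from confusion counts
#'
#' @param tp,fn,tn,fp confusion-matrix counts; `tp + fn` and `tn + fp` must
#'   both be positive.
#' @return sensitivity + specificity - 1, in `[-1, 1]`.
#' @export
tss_score <- function(tp, fn, tn, fp) {
  if (tp + fn <= 0 || tn + fp <= 0) stop("both classes must be represented")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

sens_spec_at <- function(scores, labels, t) {
  c(sens = mean(scores[labels == 1] >= t),
    spec = mean(scores[labels == 0] < t))
}

#' Sensitivity-specificity equality threshold
#'
#' Scans candidate thresholds (the sorted unique scores plus midpoints
#' between consecutive unique scores) and returns the one minimising
#' `|sensitivity - specificity|`; ties are broken by larger TSS, then by the
#' smaller threshold. A cell is predicted present when its score is at or
#' above the threshold.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 labels, both classes present.
#' @return the selected threshold.
#' @export
equality_threshold <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warning("constant scores; returning the constant as threshold")
    return(u)
  }
  cand <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
  gap <- tss <- numeric(length(cand))
  for (i in seq_along(cand)) {
    ss <- sens_spec_at(scores, labels, cand[i])
    gap[i] <- abs(ss["sens"] - ss["spec"])
    tss[i] <- ss["sens"] + ss["spec"] - 1
  }
  ok <- which(gap == min(gap))
  ok <- ok[tss[ok] == max(tss[ok])]
  cand[min(ok)]
}

#' Evaluate a niche model on held-out data
#'
#' Computes the test AUC, the sensitivity-specificity equality threshold on
#' the test scores, the TSS at that threshold, and the pass flag used for
#' ensemble inclusion: a model passes iff `AUC >= auc_min` and
#' `TSS >= tss_min` (models below either cutoff are considered no better
#' than random and are excluded).
#'
#' @param model an [enm_fit()] model.
#' @param x_test covariates of the held-out points.
#' @param y_test 0/1 labels of the held-out points, both classes present.
#' @param auc_min,tss_min exclusion cutoffs (defaults 0.75 and 0.3).
#' @return object of class `enm_eval`: `auc`, `tss`, `threshold_eq`,
#'   `sensitivity`, `specificity`, `passed`.
#' @export
enm_evaluate <- function(model, x_test, y_test, auc_min = 0.75, tss_min = 0.3) {
  y_test <- as.integer(y_test)
  if (length(unique(y_test)) < 2) stop("both classes must be present in the test set")
  s <- predict(model, x_test)
  auc <- auc_score(s[y_test == 1], s[y_test == 0])
  thr <- equality_threshold(s, y_test)
  ss <- sens_spec_at(s, y_test, thr)
  tss <- unname(ss["sens"] + ss["spec"] - 1)
  structure(list(auc = auc, tss = tss, threshold_eq = thr,
                 sensitivity = unname(ss["sens"]),
                 specificity = unname(ss["spec"]),
                 passed = auc >= auc_min && tss >= tss_min),
            class = "enm_eval")
}

#' @export
print.enm_eval <- function(x, ...) {
  cat(sprintf("AUC %.3f, TSS %.3f (threshold %.3f); %s\n",
              x$auc, x$tss, x$threshold_eq,
              if (x$passed) "passed" else "excluded"))
  invisible(x)
}
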