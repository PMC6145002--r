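test_that("the five-record rule drops exactly the under-sampled species", {
  occs <- list(sp_a = occ_df(1:3, 1:3),          # 3 unique cells
               sp_b = occ_df(1:5, 1:5),          # 5 (boundary: kept)
               sp_c = occ_df(rep(1:4, 3), rep(1:3, each = 4)))  # 12
  kept <- filter_rare_species(occs, min_records = 5)
  expect_setequal(names(kept), c("sp_b", "sp_c"))
  # four unique cells among duplicated records: dropped
  dup <- list(sp_d = occ_df(c(1, 1, 2, 2, 3, 4), c(1, 1, 2, 2, 3, 4)))
  expect_length(filter_rare_species(dup, 5), 0)
  expect_warning(filter_rare_species(list()), "no species")
  all_ok <- filter_rare_species(occs, min_records = 3)
  expect_setequal(names(all_ok), names(occs))
})

test_that("background sampling avoids presences and is deterministic", {
  clim <- toy_climate(10, 10, seed = 1)
  pres <- occ_df(1:5, 1:5)
  bg <- make_background(clim, pres, 30, seed = 2)
  expect_equal(nrow(bg), 30)
  expect_equal(nrow(unique(bg[, c("row", "col")])), 30)
  overlap <- merge(bg[, c("row", "col")], pres[, c("row", "col")])
  expect_equal(nrow(overlap), 0)
  expect_identical(bg, make_background(clim, pres, 30, seed = 2))
  expect_equal(nrow(make_background(clim, pres, 0)), 0)
})

test_that("background is forced onto the only free cells and bounded by them", {
  clim <- toy_climate(4, 4, seed = 1)
  all_cells <- expand.grid(row = 1:4, col = 1:4)
  pres <- occ_df(all_cells$row[1:13], all_cells$col[1:13])
  bg <- make_background(clim, pres, 3, seed = 1)
  expect_setequal(paste(bg$row, bg$col),
                  paste(all_cells$row[14:16], all_cells$col[14:16]))
  expect_error(make_background(clim, pres, 4), "non-presence")
})

test_that("background cells are uniform over quadrants", {
  clim <- toy_climate(40, 40, seed = 1)
  none <- occ_df(integer(0), integer(0))
  bg <- make_background(clim, none, 800, seed = 3)
  quad <- table(bg$row > 20, bg$col > 20)
  expect_gt(chisq.test(quad)$p.value, 1e-3)
})

test_that("AUC matches its closed forms and the brute-force pair count", {
  expect_equal(auc_score(c(0.9, 0.8), c(0.2, 0.1)), 1.0)
  expect_equal(auc_score(rep(0.5, 4), rep(0.5, 6)), 0.5)
  expect_equal(auc_score(c(0.9, 0.4), c(0.6, 0.1)), 0.75)
  set.seed(10)
  for (i in 1:50) {
    pres <- round(runif(sample(2:30, 1)), 2)   # rounding forces ties
    bg <- round(runif(sample(2:30, 1)), 2)
    expect_equal(auc_score(pres, bg), auc_brute(pres, bg))
  }
  expect_error(auc_score(numeric(0), 1), "non-empty")
})

test_that("TSS is sensitivity + specificity - 1", {
  expect_equal(tss_score(90, 10, 80, 20), 0.7)
  expect_equal(tss_score(10, 0, 20, 0), 1)
  expect_equal(tss_score(5, 5, 5, 5), 0)       # sens = 1 - spec: no skill
  expect_error(tss_score(0, 0, 5, 5), "classes")
})

test_that("the equality threshold follows its tie-breaking conventions", {
  # perfect separation: smallest candidate with sens = spec = 1 is the
  # midpoint 0.5 between the classes
  expect_equal(equality_threshold(c(0.8, 0.7, 0.3, 0.2), c(1, 1, 0, 0)), 0.5)
  # single pair: any t in (0.4, 0.6] works; convention picks 0.5
  t1 <- equality_threshold(c(0.6, 0.4), c(1, 0))
  expect_gt(t1, 0.4); expect_lte(t1, 0.6)
  expect_equal(t1, 0.5)
  expect_warning(t0 <- equality_threshold(rep(0.3, 5), c(1, 1, 0, 0, 0)),
                 "constant")
  expect_equal(t0, 0.3)
})

test_that("the equality threshold minimises |sens - spec| over the candidate set", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    t <- equality_threshold(scores, labels)
    gap_at <- function(th) {
      sens <- mean(scores[labels == 1] >= th)
      spec <- mean(scores[labels == 0] < th)
      abs(sens - spec)
    }
    u <- sort(unique(scores))
    cand <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
    expect_equal(gap_at(t), min(vapply(cand, gap_at, 0)))
  }
})

test_that("all four algorithm families separate a separable cloud", {
  d <- separable_cloud(n = 60, gap = 4, seed = 2)
  for (alg in c("glm", "brt", "rf", "svm")) {
    fit <- enm_fit(d$x, d$y, alg, seed = 3)
    s <- predict(fit, d$x)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(auc_score(s[d$y == 1], s[d$y == 0]), 1,
                 tolerance = 1e-8, label = alg)
  }
})

test_that("fits are deterministic given the seed and reject single-class data", {
  d <- separable_cloud(n = 40, gap = 1, seed = 4)
  for (alg in c("glm", "brt", "rf", "svm")) {
    f1 <- enm_fit(d$x, d$y, alg, seed = 5)
    f2 <- enm_fit(d$x, d$y, alg, seed = 5)
    expect_identical(predict(f1, d$x), predict(f2, d$x), label = alg)
    expect_error(enm_fit(d$x, rep(1, nrow(d$x)), alg), "single class")
  }
})

test_that("shuffled labels give chance-level test AUC", {
  # datasets are generated up front: fitting reseeds the RNG internally
  set.seed(6)
  datasets <- replicate(20, list(
    x = data.frame(env1 = rnorm(150), env2 = rnorm(150)),
    y = rbinom(150, 1, 0.4)), simplify = FALSE)
  aucs <- vapply(datasets, function(d) {
    if (length(unique(d$y[1:100])) < 2 || length(unique(d$y[101:150])) < 2)
      return(NA_real_)
    fit <- enm_fit(d$x[1:100, ], d$y[1:100], "glm", seed = 1)
    s <- predict(fit, d$x[101:150, ])
    auc_score(s[d$y[101:150] == 1], s[d$y[101:150] == 0])
  }, 0)
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.08)
})

test_that("evaluation reports AUC, TSS at the equality threshold, and the pass rule", {
  d <- separable_cloud(n = 50, gap = 4, seed = 7)
  fit <- enm_fit(d$x, d$y, "glm", seed = 1)
  ev <- enm_evaluate(fit, d$x, d$y)
  expect_equal(ev$auc, 1, tolerance = 1e-8)
  expect_equal(ev$tss, 1, tolerance = 1e-8)
  expect_true(ev$passed)
  expect_equal(ev$tss, ev$sensitivity + ev$specificity - 1, tolerance = 1e-12)
  # either metric below its cutoff excludes the model
  ev2 <- enm_evaluate(fit, d$x, d$y, tss_min = 1.1)
  expect_false(ev2$passed)
  ev3 <- enm_evaluate(fit, d$x, d$y, auc_min = 1.1)
  expect_false(ev3$passed)
  expect_error(enm_evaluate(fit, d$x, rep(1, nrow(d$x))), "both classes")
})

test_that("stratified splitting is disjoint, exhaustive and keeps both classes", {
  y <- c(rep(1, 25), rep(0, 100))
  sp <- train_test_split(y, 0.2, seed = 8)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_setequal(unique(y[sp$test]), c(0, 1))
  expect_equal(sum(y[sp$test]), 5)  # 20% of each class
  expect_identical(sp, train_test_split(y, 0.2, seed = 8))
})
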