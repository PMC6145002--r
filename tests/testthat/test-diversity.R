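test_that("every fine cell maps to exactly one coarse site", {
  g <- grid_system(c(40, 40), cell_size_km = 10, coarse_km = 50)
  expect_equal(nrow(g$sites), 64)
  expect_false(any(is.na(g$site_of)))
  expect_equal(sum(g$sites$n_fine), 40 * 40)
  expect_equal(unique(as.vector(table(g$site_of))), 25)
})

test_that("partial edge cells and region masks are honoured", {
  g <- grid_system(c(12, 12), cell_size_km = 10, coarse_km = 50)
  expect_equal(nrow(g$sites), 9)          # 3x3 with partial edges kept
  mask <- matrix(FALSE, 12, 12); mask[1:5, 1:5] <- TRUE
  gm <- grid_system(c(12, 12), 10, 50, region_mask = mask)
  expect_equal(nrow(gm$sites), 1)
  expect_true(all(is.na(gm$site_of[6:12, ])))
})

test_that("aggregation follows the union rule", {
  g <- grid_system(c(20, 20), 10, 50)
  empty <- matrix(FALSE, 20, 20)
  expect_false(any(aggregate_to_grid(empty, g)))
  one <- empty; one[7, 13] <- TRUE        # coarse cell (2, 3)
  v <- aggregate_to_grid(one, g)
  expect_equal(sum(v), 1)
  hit <- g$sites[v, ]
  expect_equal(c(hit$coarse_row, hit$coarse_col), c(2, 3))
})

test_that("richness is a per-site species count", {
  expect_equal(richness(diag(5)), rep(1L, 5))
  expect_equal(richness(matrix(TRUE, 3, 5)), rep(5L, 3))
  pa <- random_pa(20, 30, seed = 4)
  expect_equal(richness(pa),
               as.integer(apply(pa, 1, function(r) sum(r == 1))))
})

test_that("richness change classifies gains, losses and stability", {
  cur <- c(3L, 5L, 2L)
  expect_true(all(richness_change(cur, cur)$class == "stable"))
  rc <- richness_change(c(3L, 5L, 2L), c(4L, 3L, 2L))
  expect_equal(rc$delta, c(1L, -2L, 0L))
  expect_equal(as.character(rc$class), c("gain", "loss", "stable"))
  expect_error(richness_change(1:3, 1:4), "same sites")
})

test_that("the paired t statistic matches hand arithmetic", {
  # differences (-1, 0, -2): mean -1, sd 1, t = -sqrt(3), df = 2
  res <- paired_richness_test(current = c(1, 2, 3), future = c(0, 2, 1))
  expect_equal(res$t, -sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-sqrt(3), df = 2), tolerance = 1e-12)
  expect_error(paired_richness_test(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
  # direction follows the mean shift
  set.seed(5)
  cur <- rpois(50, 10); fut <- cur + 2 + rpois(50, 1)
  expect_gt(paired_richness_test(cur, fut)$t, 0)
})

test_that("Jaccard dissimilarity matches its formula and vegan", {
  expect_equal(jaccard_d(3, 0, 0), 0)
  expect_equal(jaccard_d(0, 2, 3), 1)
  expect_equal(jaccard_d(1, 1, 1), 2 / 3)
  expect_error(jaccard_d(0, 0, 0), "empty")
  pa <- random_pa(12, 25, seed = 6)
  D <- jaccard_matrix(pa)
  expect_equal(as.vector(as.dist(D)),
               as.vector(vegan::vegdist(pa, method = "jaccard", binary = TRUE)),
               tolerance = 1e-12)
})

test_that("pair counts and the decomposition cover the canonical cases", {
  pc <- pair_counts(c(1, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(unlist(pc), c(a = 1, b = 2, c = 1))
  nested <- decompose_pair(1, 2, 0)
  expect_equal(nested$D, 2 / 3)
  expect_equal(nested$Repl, 0)
  expect_equal(nested$Nes, 2 / 3)
  turn <- decompose_pair(1, 1, 1)
  expect_equal(turn$Repl, 2 / 3)
  expect_equal(turn$Nes, 0)
  expect_equal(turn$S, 1 / 3)
  ident <- decompose_pair(4, 0, 0)
  expect_equal(c(ident$S, ident$Repl, ident$Nes), c(1, 0, 0))
})

test_that("triplets close to 1 with non-negative components on random counts", {
  set.seed(7)
  a <- sample(0:10, 2000, replace = TRUE)
  b <- sample(0:10, 2000, replace = TRUE)
  c <- sample(0:10, 2000, replace = TRUE)
  keep <- a + b + c > 0
  for (i in which(keep)[1:500]) {
    t <- decompose_pair(a[i], b[i], c[i])
    expect_equal(t$S + t$Repl + t$Nes, 1, tolerance = 1e-12)
    expect_true(all(c(t$S, t$Repl, t$Nes) >= -1e-12))
    if (min(b[i], c[i]) == 0) expect_equal(t$Repl, 0)
  }
})

test_that("matrix-wise decomposition agrees with the scalar one", {
  pa <- random_pa(10, 20, seed = 8)
  rownames(pa) <- paste0("site", 1:10)
  tr <- decompose_pairs(pa)
  expect_equal(nrow(tr), choose(10, 2))
  k <- 17
  i <- match(tr$site_i[k], rownames(pa)); j <- match(tr$site_j[k], rownames(pa))
  pc <- pair_counts(pa[i, ], pa[j, ])
  ref <- decompose_pair(pc$a, pc$b, pc$c)
  expect_equal(c(tr$S[k], tr$Repl[k], tr$Nes[k]),
               c(ref$S, ref$Repl, ref$Nes), tolerance = 1e-12)
})

test_that("LCBD reproduces the worked three-site example", {
  pa <- rbind(s1 = c(1, 0), s2 = c(1, 0), s3 = c(0, 1))
  colnames(pa) <- c("sp1", "sp2")
  res <- lcbd(pa)
  expect_equal(unname(res$lcbd), c(1 / 6, 1 / 6, 2 / 3), tolerance = 1e-12)
  expect_equal(res$sstotal, 2 / 3, tolerance = 1e-12)
  expect_equal(res$bdtotal, 1 / 3, tolerance = 1e-12)
})

test_that("two distinct sites share LCBD equally", {
  pa <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
  expect_equal(unname(lcbd(pa)$lcbd), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("LCBD identities hold on random matrices (Gower trace = pairwise form)", {
  for (s in 1:25) {
    pa <- random_pa(sample(5:30, 1), sample(8:40, 1),
                    prob = runif(1, 0.2, 0.7), seed = s)
    res <- lcbd(pa)
    expect_equal(sum(res$lcbd), 1, tolerance = 1e-12)
    # plain Jaccard dissimilarities are not Euclidean-embeddable, so the
    # centred diagonal can dip marginally below zero; the dips stay small
    expect_true(all(res$lcbd >= -0.01))
    D <- jaccard_matrix(pa)
    n <- nrow(pa)
    expect_equal(res$sstotal, sum(D[upper.tri(D)]^2) / n, tolerance = 1e-10)
    expect_equal(res$bdtotal, res$sstotal / (n - 1), tolerance = 1e-12)
  }
})

test_that("degenerate LCBD inputs are rejected and empty sites excluded", {
  ident <- rbind(a = c(1, 1), b = c(1, 1), c = c(1, 1))
  expect_error(lcbd(ident), "identical")
  pa <- rbind(a = c(1, 0), b = c(0, 0), c = c(0, 1), d = c(1, 1))
  res <- lcbd(pa)
  expect_identical(res$excluded_sites, "b")
  expect_equal(res$n_sites, 3)
  expect_error(lcbd(rbind(a = c(1, 0))), "two non-empty")
})

test_that("the permutation test is deterministic and flags a planted unique site", {
  set.seed(9)
  base <- matrix(rbinom(19 * 30, 1, 0.5), 19, 30)
  unique_site <- c(rep(0, 25), rep(1, 5))   # species nobody else has
  pa <- rbind(base, unique_site)
  pa[, 26:30][pa[, 26:30] == 1 & row(pa[, 26:30]) <= 19] <- 0
  rownames(pa) <- paste0("s", 1:20)
  r1 <- lcbd_permutation_test(pa, n_perm = 199, seed = 4)
  r2 <- lcbd_permutation_test(pa, n_perm = 199, seed = 4)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(names(which.max(r1$lcbd)), "s20")
  expect_equal(names(which.min(r1$p_value)), "s20")
  expect_lt(r1$p_value[["s20"]], 0.05)
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
})

test_that("duplicating a widespread species never increases BDtotal", {
  for (s in 1:20) {
    pa <- random_pa(sample(6:25, 1), sample(8:30, 1),
                    prob = runif(1, 0.25, 0.6), seed = 100 + s)
    before <- lcbd(pa)$bdtotal
    after <- lcbd(cbind(pa, everywhere = 1))$bdtotal
    expect_lte(after, before + 1e-12)
  }
})

test_that("graded range contraction yields subsets and raises the nestedness share", {
  for (s in 1:5) {
    clim <- generate_climate(c(40, 40), c("e1", "e2", "e3"), 50, 10, seed = s)
    com <- simulate_virtual_community(12, clim, c(0.5, 1.5), 0.3,
                                      min_range_cells = 100, seed = s + 50)
    masks <- lapply(com, true_range, clim = clim)
    fut <- contract_ranges(masks)
    expect_true(all(mapply(function(f, c) all(c[f]), fut, masks)))
    g <- grid_system(c(40, 40), 10, 50)
    pa_c <- sapply(masks, aggregate_to_grid, grid = g)
    pa_f <- sapply(fut, aggregate_to_grid, grid = g)
    nes_c <- mean_triplet(decompose_pairs(
      pa_c[rowSums(pa_c) > 0, , drop = FALSE]))$Nes
    nes_f <- mean_triplet(decompose_pairs(
      pa_f[rowSums(pa_f) > 0, , drop = FALSE]))$Nes
    expect_gte(nes_f, nes_c)
  }
})

test_that("range expansion yields supersets and lowers BDtotal", {
  for (s in 1:5) {
    clim <- generate_climate(c(40, 40), c("e1", "e2", "e3"), 50, 10, seed = s)
    com <- simulate_virtual_community(12, clim, c(0.5, 1.5), 0.3,
                                      min_range_cells = 100, seed = s + 50)
    masks <- lapply(com, true_range, clim = clim)
    fut <- expand_ranges(masks, k = 3)
    expect_true(all(mapply(function(f, c) all(f[c]), fut, masks)))
    g <- grid_system(c(40, 40), 10, 50)
    pa_c <- sapply(masks, aggregate_to_grid, grid = g)
    pa_f <- sapply(fut, aggregate_to_grid, grid = g)
    expect_lt(lcbd(pa_f)$bdtotal, lcbd(pa_c)$bdtotal)
  }
})

test_that("triplet means and ternary coordinates follow their geometry", {
  one <- data.frame(S = 0.2, Repl = 0.5, Nes = 0.3)
  expect_equal(unlist(mean_triplet(one)), c(S = 0.2, Repl = 0.5, Nes = 0.3))
  two <- data.frame(S = c(1, 0), Repl = c(0, 1), Nes = c(0, 0))
  expect_equal(unlist(mean_triplet(two)), c(S = 0.5, Repl = 0.5, Nes = 0))
  set.seed(10)
  raw <- matrix(rexp(300), 100, 3)
  tr <- as.data.frame(raw / rowSums(raw))
  names(tr) <- c("S", "Repl", "Nes")
  m <- mean_triplet(tr)
  expect_equal(unlist(m), colMeans(as.matrix(tr)), tolerance = 1e-12)
  expect_equal(m$S + m$Repl + m$Nes, 1, tolerance = 1e-12)

  expect_equal(unlist(ternary_coords(1, 0, 0)), c(x = 0.5, y = sqrt(3) / 2))
  expect_equal(unlist(ternary_coords(0, 1, 0)), c(x = 0, y = 0))
  expect_equal(unlist(ternary_coords(0, 0, 1)), c(x = 1, y = 0))
  expect_equal(unlist(ternary_coords(1 / 3, 1 / 3, 1 / 3)),
               c(x = 0.5, y = sqrt(3) / 6), tolerance = 1e-12)
})
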