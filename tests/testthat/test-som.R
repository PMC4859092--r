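# SOM fixtures: block-structured profiles with two well-separated clusters
two_cluster_data <- function(n_per = 15, n_samples = 12, sep = 10, sd = 0.2,
                             seed = 4) {
  set.seed(seed)
  proto1 <- c(rep(sep, n_samples / 2), rep(0, n_samples / 2))
  proto2 <- c(rep(0, n_samples / 2), rep(sep, n_samples / 2))
  x <- rbind(
    t(replicate(n_per, proto1 + rnorm(n_samples, 0, sd))),
    t(replicate(n_per, proto2 + rnorm(n_samples, 0, sd)))
  )
  rownames(x) <- c(paste0("a", seq_len(n_per)), paste0("b", seq_len(n_per)))
  x
}

test_that("identical profiles collapse onto a single unit", {
  prof <- c(1, -2, 3, 0.5)
  x <- matrix(rep(prof, each = 40), nrow = 40)
  rownames(x) <- paste0("s", 1:40)
  m <- train_som(x, grid_rows = 6, grid_cols = 6, epochs = 12, seed = 2)
  expect_equal(length(unique(m$assignment)), 1)
  bmu <- unique(m$assignment)
  expect_equal(unname(m$weights[bmu, ]), prof, tolerance = 0.05)
})

test_that("well-separated clusters land in separate grid regions", {
  x <- two_cluster_data()
  m <- train_som(x, grid_rows = 10, grid_cols = 10, epochs = 12, seed = 1)
  units_a <- m$assignment[startsWith(names(m$assignment), "a")]
  units_b <- m$assignment[startsWith(names(m$assignment), "b")]
  cen <- function(u) c(mean(m$grid$row[u]), mean(m$grid$col[u]))
  d <- sqrt(sum((cen(units_a) - cen(units_b))^2))
  expect_gt(d, m$config$radius)          # cluster centroids beyond the radius
  expect_length(intersect(units_a, units_b), 0)
})

test_that("training is deterministic given the seed", {
  x <- two_cluster_data(seed = 7)
  m1 <- train_som(x, grid_rows = 8, grid_cols = 8, seed = 123)
  m2 <- train_som(x, grid_rows = 8, grid_cols = 8, seed = 123)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$assignment, m2$assignment)
  m3 <- train_som(x, grid_rows = 8, grid_cols = 8, seed = 124)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("trained maps preserve topology (neighbors closer than random pairs)", {
  x <- two_cluster_data(n_per = 25, seed = 9)
  m <- train_som(x, grid_rows = 10, grid_cols = 10, epochs = 12, seed = 5)
  W <- m$weights
  g <- m$grid
  adj_d <- c()
  for (u in seq_len(nrow(g))) {
    right <- which(g$row == g$row[u] & g$col == g$col[u] + 1)
    down <- which(g$row == g$row[u] + 1 & g$col == g$col[u])
    for (v in c(right, down)) {
      adj_d <- c(adj_d, sqrt(sum((W[u, ] - W[v, ])^2)))
    }
  }
  set.seed(1)
  rand_pairs <- matrix(sample(nrow(W), 400, replace = TRUE), ncol = 2)
  rand_pairs <- rand_pairs[rand_pairs[, 1] != rand_pairs[, 2], ]
  rand_d <- sqrt(rowSums((W[rand_pairs[, 1], ] - W[rand_pairs[, 2], ])^2))
  expect_lt(mean(adj_d), mean(rand_d))
})

test_that("sinks of one planted block stay within grid radius of each other", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(100 + seed)
    protos <- list(c(rep(10, 3), rep(0, 9)), c(rep(0, 3), rep(10, 3), rep(0, 6)),
                   c(rep(0, 6), rep(10, 3), rep(0, 3)), c(rep(0, 9), rep(10, 3)))
    x <- do.call(rbind, lapply(1:4, function(k) {
      t(replicate(8, protos[[k]] + rnorm(12, 0, 0.1)))
    }))
    rownames(x) <- paste0(rep(letters[1:4], each = 8), 1:8)
    m <- train_som(x, grid_rows = 10, grid_cols = 10, epochs = 12, seed = seed)
    ok <- TRUE
    for (block in letters[1:4]) {
      u <- m$assignment[startsWith(names(m$assignment), block)]
      dmax <- max(dist(cbind(m$grid$row[u], m$grid$col[u])))
      if (dmax > m$config$radius) ok <- FALSE
    }
    hits <- hits + ok
  }
  expect_gte(hits / 10, 0.9)
})

test_that("portraits average the unit weights over class samples", {
  x <- two_cluster_data(n_samples = 6, seed = 3)
  colnames(x) <- paste0("smp", 1:6)
  m <- train_som(x, grid_rows = 6, grid_cols = 6, seed = 11)
  sheet <- data.frame(sample_id = colnames(x),
                      class_label = c("solo", "duo", "duo", "rest", "rest", "rest"),
                      dataset_id = "d", is_control = c(TRUE, rep(FALSE, 5)))
  p_solo <- class_portrait(m, sheet, "solo")
  expect_equal(as.vector(t(unclass(p_solo))), unname(m$weights[, 1]))
  p_duo <- class_portrait(m, sheet, "duo")
  expect_equal(as.vector(t(unclass(p_duo))),
               unname(rowMeans(m$weights[, 2:3])))
  expect_error(class_portrait(m, sheet, "nope"), "unknown or empty")
})

test_that("the all-sample portrait of centralized data is near zero", {
  d <- synthetic_design(n_pathways = 5, seed = 21)
  pwfull <- generate_pathways(d)
  sim <- simulate_expression(d, pwfull$graphs, pwfull$truth)
  fc <- compute_fold_change(sim$values, sim$sheet)$values
  psf <- compute_psf_matrix(pwfull$graphs, fc)
  cc <- centralize_psf(psf)
  m <- train_som(cc, grid_rows = 8, grid_cols = 8, seed = 1)
  sheet_all <- sim$sheet
  sheet_all$class_label <- "all"
  sheet_all$is_control[1] <- TRUE
  p <- class_portrait(m, sheet_all, "all")
  expect_lt(abs(mean(p)), 0.1)
})

test_that("spot detection finds bumps, dips and nothing on flat portraits", {
  mk_portrait <- function(vals) {
    structure(vals, class_label = "t", class = c("Portrait", "matrix", "array"))
  }
  gauss_bump <- function(r0, c0, sign = 1, n = 10) {
    outer(1:n, 1:n, function(r, c) sign * exp(-((r - r0)^2 + (c - c0)^2) / 4))
  }
  p1 <- mk_portrait(gauss_bump(3, 3))
  s1 <- detect_spots(p1)
  expect_length(s1, 1)
  expect_equal(s1[[1]]$polarity, "over")
  expect_true(any(s1[[1]]$cells[, 1] == 3 & s1[[1]]$cells[, 2] == 3))

  p2 <- mk_portrait(gauss_bump(3, 3) + gauss_bump(8, 8, sign = -1))
  s2 <- detect_spots(p2)
  expect_setequal(vapply(s2, `[[`, "", "polarity"), c("over", "under"))

  p3 <- mk_portrait(matrix(0, 10, 10))
  expect_warning(s3 <- detect_spots(p3), "constant")
  expect_length(s3, 0)

  # spot units are exactly those passing the threshold predicate
  s1b <- detect_spots(p1, threshold_fraction = 0.5)
  units <- sort(unlist(lapply(s1b, `[[`, "units")))
  mask <- which(t(unclass(p1) >= 0.5 * max(p1)))
  expect_equal(units, sort(mask))
})

test_that("summary map merges overlapping class spots and letters by peak", {
  mk <- function(cells, peak, sinks = character(0)) {
    structure(list(list(polarity = "over", cells = cells,
                        units = (cells[, 1] - 1) * 6 + cells[, 2],
                        peak = peak, sinks = sinks)),
              class = "SpotSet")
  }
  sA <- mk(rbind(c(1, 1), c(1, 2)), peak = 2, sinks = "p1:s1")
  sB <- mk(rbind(c(5, 5)), peak = 5, sinks = "p2:s2")
  sm <- summary_spot_map(list(c1 = sA, c2 = sB), 6, 6)
  expect_length(sm$spots, 2)
  expect_equal(sm$spots[[1]]$label, "A")
  expect_equal(sm$spots[[1]]$peak, 5)            # ordered by descending peak
  expect_equal(sm$spots[[1]]$classes, "c2")

  # overlapping spots merge and list both classes
  sC <- mk(rbind(c(1, 2), c(1, 3)), peak = 3, sinks = "p3:s3")
  sm2 <- summary_spot_map(list(c1 = sA, c3 = sC), 6, 6)
  expect_length(sm2$spots, 1)
  expect_setequal(sm2$spots[[1]]$classes, c("c1", "c3"))
  expect_setequal(sm2$spots[[1]]$sinks, c("p1:s1", "p3:s3"))
})

test_that("four planted class branches surface as four summary spots", {
  d <- synthetic_design(n_pathways = 4, noise_sd = 0.15, seed = 31,
                        inhibition_prob = 0,
                        classes = data.frame(
                          class_label = c("HC", paste0("D", 1:4)),
                          target_pathway = c(NA, 1:4), target_sink = 1,
                          direction = c(NA, rep("up", 4)),
                          effect_size = c(1, rep(2, 4)),
                          n_samples = 12, is_control = c(TRUE, rep(FALSE, 4)),
                          branch_mode = c(NA, rep("pathway", 4))))
  pw <- generate_pathways(d)
  sim <- simulate_expression(d, pw$graphs, pw$truth)
  fc <- compute_fold_change(sim$values, sim$sheet)$values
  psf <- compute_psf_matrix(pw$graphs, fc)
  cc <- centralize_psf(psf)
  m <- train_som(cc, grid_rows = 10, grid_cols = 10, seed = 1)
  spotsets <- lapply(setNames(paste0("D", 1:4), paste0("D", 1:4)), function(cl) {
    detect_spots(class_portrait(m, sim$sheet, cl), m)
  })
  sm <- summary_spot_map(spotsets, 10, 10)
  truth_sinks <- unique(unlist(lapply(pw$truth$classes,
                                      function(t) t$truth_sinks)))
  found <- unique(unlist(lapply(sm$spots, `[[`, "sinks")))
  expect_gte(length(intersect(found, truth_sinks)) / length(truth_sinks), 0.8)
  expect_gte(length(sm$spots), 4)
})

test_that("SOM models survive the text save/load round trip", {
  x <- two_cluster_data(n_per = 5, seed = 13)
  m <- train_som(x, grid_rows = 5, grid_cols = 5, seed = 6)
  dir <- tempfile()
  save_som_model(m, dir)
  m2 <- load_som_model(dir)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$assignment, m$assignment)
  expect_equal(m2$config$grid_rows, m$config$grid_rows)
})
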