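two_blobs <- function(seed, n = 60, sep = 10) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2) + sep, n, 2))
  rownames(m) <- paste0("c", seq_len(2 * n))
  m
}

test_that("embedding separates planted cell types and is deterministic", {
  cfg <- synthetic_config(
    80, 120,
    modules = list(list(size = 30), list(size = 30)),
    cell_types = list(
      list(name = "a", n_cells = 60, active_modules = 1L),
      list(name = "b", n_cells = 60, active_modules = 2L)),
    noise_sd = 0.2, activity_shift = 3, seed = 7)
  d <- generate_expression(cfg)
  lx <- log_transform(d$expr)
  co <- embed_cells(lx)
  expect_identical(co, embed_cells(lx))
  # mean silhouette of the true labels in the 2D embedding
  dd <- as.matrix(dist(co))
  truth <- d$truth$cell_type[rownames(co)]
  sil <- vapply(seq_len(nrow(co)), function(i) {
    own <- mean(dd[i, truth == truth[i] & seq_len(nrow(co)) != i])
    other <- mean(dd[i, truth != truth[i]])
    (other - own) / max(own, other)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  single <- matrix(1, 3, 1, dimnames = list(letters[1:3], "c1"))
  expect_error(embed_cells(sc_expr(single)), "single cell")
  expect_error(embed_cells(lx, n_neighbors = 1000), "n_neighbors")
})

test_that("SNN clustering resolves well-separated blobs and orders labels by size", {
  m <- two_blobs(1)
  truth <- rep(1:2, each = 60)

  # neighbourhoods sized to the blobs: exact recovery
  labels <- cluster_snn(m, k = 25)
  expect_equal(length(unique(labels)), 2)
  expect_equal(adjusted_rand(labels, truth), 1)

  # small neighbourhoods subdivide blobs but never mix them: every
  # cluster nests inside one blob
  l10 <- cluster_snn(m, k = 10)
  tab <- table(l10, truth)
  expect_true(all(rowSums(tab > 0) == 1))

  # identical points collapse to one cluster
  same <- matrix(1, 20, 2, dimnames = list(paste0("c", 1:20), NULL))
  expect_equal(unique(unname(cluster_snn(same, k = 5))), 1L)

  # planted clusters sized 60/30/10: integer labels decrease in size and
  # clusters stay pure
  set.seed(4)
  m3 <- rbind(cbind(rnorm(60), rnorm(60)),
              cbind(rnorm(30) + 12, rnorm(30)),
              cbind(rnorm(10), rnorm(10) + 12))
  rownames(m3) <- paste0("c", 1:100)
  truth3 <- rep(1:3, c(60, 30, 10))
  l3 <- cluster_snn(m3, k = 8)
  sizes <- table(l3)[as.character(sort(unique(l3)))]
  expect_true(all(diff(unname(sizes)) <= 0))
  expect_true(all(rowSums(table(l3, truth3) > 0) == 1))
  expect_error(cluster_snn(m3, k = 0), "k")
  expect_error(cluster_snn(m3, k = 100), "k")
})

test_that("lineages are root-to-leaf paths of the centroid MST", {
  # three collinear clusters
  co <- rbind(matrix(c(0, 0), 10, 2, byrow = TRUE),
              matrix(c(5, 0), 10, 2, byrow = TRUE),
              matrix(c(10, 0), 10, 2, byrow = TRUE)) +
    matrix(rnorm(60, 0, 0.1), 30, 2)
  rownames(co) <- paste0("c", 1:30)
  labels <- setNames(rep(c("C1", "C2", "C3"), each = 10), rownames(co))
  lin <- infer_lineages(co, labels, "C1")
  expect_equal(lin, list(c("C1", "C2", "C3")))

  # Y shape: C1 - C2, then C3 and C4 branch off C2
  co4 <- rbind(matrix(c(0, 0), 10, 2, byrow = TRUE),
               matrix(c(5, 0), 10, 2, byrow = TRUE),
               matrix(c(9, 3), 10, 2, byrow = TRUE),
               matrix(c(9, -3), 10, 2, byrow = TRUE)) +
    matrix(rnorm(80, 0, 0.1), 40, 2)
  rownames(co4) <- paste0("c", 1:40)
  labels4 <- setNames(rep(c("C1", "C2", "C3", "C4"), each = 10),
                      rownames(co4))
  lin4 <- infer_lineages(co4, labels4, "C1")
  expect_equal(length(lin4), 2)
  expect_true(all(vapply(lin4, function(l)
    identical(l[1:2], c("C1", "C2")), logical(1))))
  expect_error(infer_lineages(co4, labels4, "C9"), "root")
  # single cluster: one trivial lineage
  expect_equal(infer_lineages(co[1:10, ], labels[1:10], "C1"), list("C1"))
})

test_that("pseudotime is arc length along the centroid path", {
  # cells exactly on a line: pseudotime preserves the x ordering between
  # the end centroids and clamps beyond them
  co <- cbind(seq(0, 10, length.out = 30), rep(0, 30))
  rownames(co) <- paste0("c", 1:30)
  labels <- setNames(rep(c("C1", "C2", "C3"), each = 10), rownames(co))
  pt <- compute_pseudotime(co, c("C1", "C2", "C3"), labels)
  cents <- range(tapply(co[, 1], labels, mean))
  interior <- co[, 1] >= cents[1] & co[, 1] <= cents[2]
  expect_equal(cor(pt[interior], co[interior, 1], method = "spearman"), 1)
  expect_true(all(pt >= 0 & pt <= 1))
  expect_true(all(pt[co[, 1] < cents[1]] == 0))
  expect_true(all(pt[co[, 1] > cents[2]] == 1))

  # a cell exactly at the root centroid has pseudotime 0: placing the
  # probe cell at the mean of its 9 cluster-mates makes it the fixed
  # point of the centroid
  co2 <- co + matrix(rnorm(60, 0, 0.05), 30, 2)
  rownames(co2) <- rownames(co)
  co2["c1", ] <- colMeans(co2[labels == "C1" &
                              rownames(co2) != "c1", ])
  pt2 <- compute_pseudotime(co2, c("C1", "C2", "C3"), labels)
  expect_equal(unname(pt2["c1"]), 0, tolerance = 1e-10)

  # rigid rotation + translation leaves pseudotime unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  co3 <- co %*% rot + 5
  rownames(co3) <- rownames(co)
  pt3 <- compute_pseudotime(co3, c("C1", "C2", "C3"), labels)
  expect_equal(pt, pt3, tolerance = 1e-10)
  expect_error(compute_pseudotime(co, c("C1", "C9"), labels), "unknown")
})

test_that("planted pseudotime is recovered from expression", {
  d <- generate_trajectory_dataset(trajectory_config(2, 1, noise_sd = 0.3))
  tr <- run_trajectory(d)
  big <- which.max(vapply(tr$lineages, function(l)
    sum(as.character(tr$labels) %in% l), numeric(1)))
  pt <- compute_pseudotime(tr$coords, tr$lineages[[big]], tr$labels)
  ok <- !is.na(pt)
  rho <- cor(pt[ok], d$truth$pseudotime[names(pt)[ok]], method = "spearman")
  expect_gte(abs(rho), 0.9)
})

test_that("module dynamics classify monotone, null and planted programs", {
  set.seed(10)
  pt <- setNames(runif(200), paste0("c", 1:200))
  eig <- rbind(M1 = pt / sd(pt))
  colnames(eig) <- names(pt)
  dyn <- module_dynamics(eig, pt, "M1", n_perm = 300)
  expect_equal(dyn$direction, "increasing")
  expect_equal(dyn$trend, 1)

  # independent eigengene: the direction call keeps its nominal size
  calls <- vapply(1:60, function(seed) {
    set.seed(seed + 300)
    e <- rbind(M1 = rnorm(120))
    p <- setNames(runif(120), paste0("c", 1:120))
    colnames(e) <- names(p)
    module_dynamics(e, p, "M1", n_perm = 200, seed = seed)$direction
  }, character(1))
  expect_gte(mean(calls == "non-monotone"), 0.9)
  expect_error(module_dynamics(eig, pt, "M1", span = 0), "span")
  expect_error(module_dynamics(eig, pt, "M9"), "unknown module")
})

test_that("anti-correlated module pairs are flagged mutually exclusive", {
  e <- rbind(M1 = c(1, 2, 3), M17 = c(-1, -2, -3), M2 = c(1, 2, 3))
  colnames(e) <- paste0("c", 1:3)
  ex <- module_exclusivity(e, "M1", "M17")
  expect_equal(ex$correlation, -1)
  expect_true(ex$mutually_exclusive)
  ex2 <- module_exclusivity(e, "M1", "M2")
  expect_equal(ex2$correlation, 1)
  expect_false(ex2$mutually_exclusive)
  expect_error(module_exclusivity(e, "M1", "M99"), "unknown")
})
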