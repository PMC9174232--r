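test_that("signed adjacency follows the ((1+cor)/2)^beta convention", {
  cc <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(signed_adjacency(cc, 6)[1, 2], 0.5^6)
  expect_error(signed_adjacency(cc, 0), "beta")
  expect_error(signed_adjacency(matrix(c(1, 2, 2, 1), 2), 2), "\\[-1, 1\\]")
})

test_that("connectivity decreases and selection falls back with a warning", {
  set.seed(8)
  v <- matrix(rnorm(50 * 30), 50, 30,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:30)))
  v <- pmax(v + 3, 0)
  fit <- suppressWarnings(pick_soft_threshold(v, powers = 1:8))
  expect_true(all(diff(fit$fit$mean_k) < 0))
  # pure noise cannot look scale-free: falls back to the best power
  expect_warning(pick_soft_threshold(v, powers = 1:8), "best power")
  expect_false(fit$reached_target)
  expect_equal(fit$beta,
               fit$fit$power[which.max(fit$fit$r2_signed)])
})

test_that("soft threshold reaches the fit target on hub-structured data", {
  # genes couple to a shared factor with heavy-tailed weights, giving a
  # decreasing, approximately power-law connectivity distribution
  for (seed in 1:3) {
    set.seed(seed)
    ng <- 400
    nc <- 150
    w <- runif(ng)^3
    f <- rnorm(nc)
    v <- t(sapply(seq_len(ng), function(g)
      w[g] * f + sqrt(1 - w[g]^2) * rnorm(nc)))
    dimnames(v) <- list(paste0("g", 1:ng), paste0("c", 1:nc))
    fit <- pick_soft_threshold(pmax(v + 5, 0), powers = 1:14)
    expect_true(fit$reached_target)
    expect_gte(fit$fit$r2_signed[fit$fit$power == fit$beta], 0.85)
  }
})

test_that("topological overlap matches hand-computed small cases", {
  # two genes, a_12 = 1
  a2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(topological_overlap(a2)[1, 2], 1)
  # three genes, all off-diagonal 0.5: (0.25 + 0.5) / (1 + 1 - 0.5)
  a3 <- matrix(0.5, 3, 3)
  diag(a3) <- 1
  expect_equal(unique(topological_overlap(a3)[upper.tri(a3)]), 0.5)
  # empty network
  a0 <- diag(4)
  expect_true(all(topological_overlap(a0)[upper.tri(a0)] == 0))
  expect_error(topological_overlap(matrix(c(1, 0.2, 0.5, 1), 2)),
               "symmetric")
})

test_that("module detection recovers planted blocks and ignores noise", {
  # two clean 40-gene blocks in 30 background genes
  cfg <- planted_modules_config(6, n_genes = 110, n_cells = 100,
                                sizes = c(40, 40), noise_sd = 0)
  d <- generate_expression(cfg)
  ms <- detect_from_expr(d$expr)$modules
  expect_equal(length(ms$modules), 2)
  expect_equal(adjusted_rand(ms$assignment, d$truth$gene_module), 1)

  # pure-noise matrix: almost everything unassigned
  unassigned_frac <- vapply(1:10, function(seed) {
    set.seed(seed)
    v <- matrix(rlnorm(200 * 80), 200, 80,
                dimnames = list(paste0("g", 1:200), paste0("c", 1:80)))
    ms <- suppressWarnings(detect_from_expr(v)$modules)
    mean(ms$assignment == "unassigned")
  }, numeric(1))
  expect_true(all(unassigned_frac >= 0.9))
})

test_that("module detection is invariant to gene input order", {
  cfg <- planted_modules_config(13, n_genes = 150, n_cells = 100,
                                sizes = c(40, 40))
  d <- generate_expression(cfg)
  lx <- log_transform(d$expr)$values
  tom <- topological_overlap(signed_adjacency(gene_correlation(lx), 6))
  ms1 <- detect_modules(tom, min_size = 30, expr = lx)
  set.seed(99)
  perm <- sample(nrow(lx))
  ms2 <- detect_modules(tom[perm, perm], min_size = 30, expr = lx[perm, ])
  expect_equal(adjusted_rand(ms1$assignment,
                             ms2$assignment[names(ms1$assignment)]), 1)
})

test_that("eigengenes are unit-variance, oriented, and explain rank-1 modules", {
  # identical standardised genes: eigengene correlates 1 with each member
  set.seed(3)
  f <- rnorm(60)
  v <- rbind(g1 = 2 * f + 1, g2 = 5 * f - 2, g3 = f)
  colnames(v) <- paste0("c", 1:60)
  asg <- setNames(rep("M1", 3), rownames(v))
  eig <- module_eigengenes(v, asg)
  expect_equal(sd(eig["M1", ]), 1)
  expect_true(all(abs(cor(t(v), eig["M1", ]) - 1) < 1e-12))
  # orientation: positively correlated with the rising planted factor
  expect_gt(cor(eig["M1", ], f), 0.999)
  expect_gt(attr(eig, "var_explained")[["M1"]], 0.999)

  # anti-correlated 2-gene module: |cor| = 1 with both, opposite signs
  v2 <- rbind(up = f, down = -f)
  colnames(v2) <- paste0("c", 1:60)
  eig2 <- module_eigengenes(v2, setNames(rep("M1", 2), rownames(v2)))
  cors <- cor(t(v2), eig2["M1", ])
  expect_equal(abs(as.numeric(cors)), c(1, 1), tolerance = 1e-12)
  expect_equal(sum(sign(cors)), 0)

  # constant member gene is a hard error naming the module
  v3 <- rbind(a = f, b = rep(1, 60))
  colnames(v3) <- paste0("c", 1:60)
  expect_error(module_eigengenes(v3, setNames(rep("M1", 2), rownames(v3))),
               "M1")

  # eigengene variance explained approaches 1 as noise vanishes
  ve <- vapply(c(0.8, 0.3, 0.05), function(noise) {
    cfg <- planted_modules_config(21, n_genes = 60, n_cells = 80,
                                  sizes = 40, noise_sd = noise)
    d <- generate_expression(cfg)
    lx <- log_transform(d$expr)$values
    e <- module_eigengenes(lx, d$truth$gene_module)
    attr(e, "var_explained")[["M1"]]
  }, numeric(1))
  expect_true(all(diff(ve) > 0))
  expect_gt(ve[3], 0.95)
})

test_that("module membership ranks hub genes first and handles edge cases", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    f <- rnorm(100)
    v <- rbind(hub = f + 0.1 * rnorm(100),
               t(sapply(1:29, function(i) f + 0.8 * rnorm(100))))
    rownames(v) <- c("hub", sprintf("m%02d", 1:29))
    colnames(v) <- paste0("c", 1:100)
    asg <- setNames(rep("M1", 30), rownames(v))
    eig <- module_eigengenes(v, asg)
    mem <- module_membership(v, eig)
    top_module_genes(mem, "M1", 10)$gene[1] == "hub"
  }, logical(1))
  expect_gte(sum(hits), 18)

  # constant gene: correlation recorded as 0 with a flag, not NaN
  set.seed(2)
  f <- rnorm(50)
  v <- rbind(a = f, b = f + 0.1 * rnorm(50), flat = rep(3, 50))
  colnames(v) <- paste0("c", 1:50)
  eig <- module_eigengenes(v, setNames(c("M1", "M1", "unassigned"),
                                       rownames(v)))
  mem <- module_membership(v, eig)
  expect_equal(mem["flat", "M1"], 0)
  expect_equal(attr(mem, "constant"), "flat")

  # k beyond the gene count returns everything
  expect_equal(nrow(top_module_genes(mem, "M1", 100)), 3)
  expect_error(top_module_genes(mem, "M9"), "unknown module")
})
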