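test_that("generation is bit-identical under a fixed seed", {
  cfg <- planted_modules_config(11, n_genes = 120, n_cells = 60,
                                sizes = c(20, 20))
  d1 <- generate_expression(cfg)
  d2 <- generate_expression(cfg)
  expect_identical(d1$expr$values, d2$expr$values)
  expect_identical(d1$truth$gene_module, d2$truth$gene_module)
  # different seed changes the draw
  cfg2 <- planted_modules_config(12, n_genes = 120, n_cells = 60,
                                 sizes = c(20, 20))
  expect_false(identical(generate_expression(cfg2)$expr$values,
                         d1$expr$values))
})

test_that("a noiseless equal-loading module is an exact rank-1 block", {
  cfg <- synthetic_config(30, 50,
                          modules = list(list(size = 10, activity_sd = 0.5,
                                              loading_range = c(1, 1))),
                          noise_sd = 0, dropout_rate = 0, seed = 1)
  d <- generate_expression(cfg)
  lx <- log_transform(d$expr)$values
  mod_genes <- names(d$truth$gene_module)[d$truth$gene_module == "M1"]
  stopifnot(all(d$expr$values[mod_genes, ] > 0))  # no clipping in play
  cc <- cor(t(lx[mod_genes, ]))
  expect_true(all(abs(cc - 1) < 1e-12))
})

test_that("marker genes are expressed predominantly in their own cell type", {
  cfg <- synthetic_config(
    100, 200,
    cell_types = list(list(name = "alpha", n_cells = 100, marker_genes = 5),
                      list(name = "beta", n_cells = 100, marker_genes = 5)),
    noise_sd = 0.3, seed = 2)
  d <- generate_expression(cfg)
  v <- d$expr$values
  for (ct in c("alpha", "beta")) {
    own <- names(d$truth$cell_type)[d$truth$cell_type == ct]
    other <- setdiff(colnames(v), own)
    mk <- d$truth$markers[[ct]]
    expect_gt(mean(v[mk, own]), 2 * mean(v[mk, other]))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(10, 0), "zero cells")
  expect_error(synthetic_config(10, 5, noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(10, 5,
                                modules = list(list(size = 11))),
               "more than 'n_genes'")
  expect_error(synthetic_config(10, 5, dropout_rate = 1.2), "dropout_rate")
  expect_error(synthetic_config(
    10, 5, cell_types = list(list(name = "a", n_cells = 3))), "sum")
  expect_error(synthetic_config(
    20, 10, trajectory = list(n_lineages = 3)), "1 or 2")
})

test_that("dropout keeps values nonnegative and removes detections monotonically", {
  detected <- vapply(c(0, 0.2, 0.5, 0.8), function(rate) {
    cfg <- synthetic_config(200, 50,
                            modules = list(list(size = 40)),
                            noise_sd = 0.3, dropout_rate = rate, seed = 9)
    v <- generate_expression(cfg)$expr$values
    expect_true(all(v >= 0))
    mean(colSums(v > 0))
  }, numeric(1))
  expect_true(all(diff(detected) < 0))
})

test_that("the LR database is the planted pairs plus background decoys", {
  types <- c("fb", "cm")
  cfg <- synthetic_config(
    100, 60,
    modules = list(list(size = 20), list(size = 20)),
    cell_types = list(
      list(name = "fb", n_cells = 30, marker_genes = 3, active_modules = 1L),
      list(name = "cm", n_cells = 30, marker_genes = 3, active_modules = 2L)),
    lr_plan = data.frame(source = c("fb", "fb", "cm"),
                         target = c("cm", "fb", "fb")),
    noise_sd = 0.2, seed = 5)
  d <- generate_expression(cfg)

  db0 <- generate_lr_database(d$truth, n_decoys = 0)
  expect_identical(db0$ligand, d$truth$lr_pairs$ligand)
  expect_identical(db0$receptor, d$truth$lr_pairs$receptor)

  db <- generate_lr_database(d$truth, n_decoys = 5, seed = 3)
  expect_equal(nrow(db), 8)
  expect_equal(anyDuplicated(db), 0)
  decoys <- db[-(1:3), ]
  decoy_genes <- c(decoys$ligand, decoys$receptor)
  expect_true(all(d$truth$gene_module[decoy_genes] == "unassigned"))

  # ligand of every planted pair sits in a module active in its source type
  for (i in seq_len(nrow(d$truth$lr_pairs))) {
    lig_mod <- d$truth$gene_module[[d$truth$lr_pairs$ligand[i]]]
    src <- d$truth$lr_pairs$source[i]
    active <- paste0("M", cfg$cell_types[[match(src, types)]]$active_modules)
    expect_true(lig_mod %in% active)
  }

  expect_error(generate_lr_database(d$truth, n_decoys = 1e6), "decoys")
})

test_that("trajectory datasets modulate module activity along pseudotime", {
  # noiseless single lineage: the rising module's eigengene tracks
  # pseudotime perfectly
  d <- generate_trajectory_dataset(trajectory_config(3, 1, noise_sd = 0))
  eig <- module_eigengenes(log_transform(d$expr)$values,
                           d$truth$gene_module)
  expect_equal(cor(eig["M1", ], d$truth$pseudotime, method = "spearman"), 1)
  expect_equal(cor(eig["M3", ], d$truth$pseudotime, method = "spearman"), -1)

  # two lineages: branch programs agree before the branch point and
  # diverge after it
  d2 <- generate_trajectory_dataset(trajectory_config(5, 2, noise_sd = 0))
  tr <- d2$truth
  act <- tr$module_activity
  pre <- tr$pseudotime <= 0.5
  ramp <- 3 * tr$pseudotime  # trajectory scale used by trajectory_config()
  for (i in 1:2) {
    m <- paste0("M", i)
    own <- tr$lineage == i
    # before the branch point both branches follow the same shared ramp
    expect_equal(unname(act[m, pre]), unname(ramp[pre]), tolerance = 1e-12)
    # after it, only the module's own branch keeps ramping
    expect_equal(unname(act[m, !pre & own]), unname(ramp[!pre & own]),
                 tolerance = 1e-12)
    expect_gt(min(ramp[!pre & !own] - act[m, !pre & !own]), 0)
  }
  expect_error(generate_trajectory_dataset(
    planted_modules_config(1, 50, 20, sizes = 10)), "trajectory")
})

test_that("proteome generation plants exact group shifts", {
  pr <- generate_proteome(c(A = 5, B = 5),
                          effects = list(p1 = c(B = 2)),
                          noise_sd = 0, seed = 1)
  v <- pr$proteome$values
  grp <- pr$proteome$sample_group
  expect_true(all(v["p1", grp == "B"] - v["p1", grp == "A"][1] == 2))

  # four ordered severity groups: group means follow the configured shifts
  pr4 <- generate_proteome(
    c(control = 40, nonadvanced = 20, advanced_pre = 15, advanced_post = 15),
    effects = list(m = c(nonadvanced = 1, advanced_pre = 2,
                         advanced_post = 3)),
    noise_sd = 0.5, seed = 2)
  mns <- tapply(pr4$proteome$values["m", ],
                pr4$proteome$sample_group, mean)
  expect_true(all(diff(mns[c("control", "nonadvanced", "advanced_pre",
                             "advanced_post")]) > 0))
  expect_error(generate_proteome(c(A = 0, B = 5),
                                 effects = list(p = c())), "at least 1 sample")
  expect_error(generate_proteome(c(A = 5), effects = list(p = c())),
               "2 groups")
})

test_that("null proteome differences give uniform t-test p-values", {
  ps <- vapply(1:100, function(seed) {
    pr <- generate_proteome(c(A = 10, B = 10), effects = list(p = c()),
                            noise_sd = 1, seed = seed)
    grp <- pr$proteome$sample_group
    stats::t.test(pr$proteome$values["p", grp == "A"],
                  pr$proteome$values["p", grp == "B"])$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
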