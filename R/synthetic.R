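#' Configuration for the synthetic single-cell generator
#'
#' Describes a synthetic gene-by-cell dataset with planted structure: signed
#' co-expression modules driven by latent per-cell activities, cell types
#' that activate chosen modules, optional one- or two-branch pseudotime
#' trajectories that modulate module activities, planted ligand-receptor
#' pairs between cell types, and Bernoulli dropout. Expression follows a
#' log-normal latent-factor model,
#' `expr = max(exp(baseline + sum_m loading * activity + noise) - 1, 0)`,
#' which is continuous like FPKM/RPKM data and is sufficient for the
#' correlation-structure recovery all downstream stages rely on.
#'
#' @param n_genes,n_cells positive counts.
#' @param modules list of module descriptions, each a list with `size`
#'   (gene count), `activity_sd` (SD of the latent per-cell activity,
#'   default 1) and `loading_range` (interval for per-gene loadings,
#'   default `c(0.8, 1.2)`). Modules occupy the first genes in order;
#'   remaining genes are unassigned background.
#' @param cell_types list of cell-type descriptions, each a list with
#'   `name`, `n_cells`, `marker_genes` (count, default 0), `active_modules`
#'   (integer indices into `modules`, default none) and `condition`
#'   (metadata label, default "control"). Cell counts must sum to
#'   `n_cells`. When empty, all cells belong to one type "cell".
#' @param noise_sd SD of gene-level Gaussian noise in log space (>= 0).
#' @param dropout_rate probability in \[0, 1\] that any entry is zeroed
#'   (independent Bernoulli dropout).
#' @param trajectory optional list with `n_lineages` (1 or 2), `modules_up`,
#'   `modules_down` (module indices whose activity rises/falls with
#'   pseudotime), `branch_point` (shared pseudotime before divergence,
#'   default 0.5) and `scale` (activity amplitude, default 2).
#' @param lr_plan optional data.frame (or list of length-2 character
#'   vectors) with columns `source`, `target`: one planted ligand-receptor
#'   pair per row, ligand drawn from a module active in the source type,
#'   receptor from a module active in the target type.
#' @param activity_shift mean activity increase of a module in the cell
#'   types that activate it (log-space units, default 2).
#' @param marker_strength log-space expression boost of dedicated marker
#'   genes in their own cell type (used only for types with no active
#'   module; types with active modules take their markers from the first
#'   such module).
#' @param seed integer seed; identical configurations with identical seeds
#'   generate bit-identical data.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes, n_cells,
                             modules = list(),
                             cell_types = list(),
                             noise_sd = 0.3,
                             dropout_rate = 0,
                             trajectory = NULL,
                             lr_plan = NULL,
                             activity_shift = 2,
                             marker_strength = 2,
                             seed = 1) {
  if (n_genes < 1) stop("'n_genes' must be >= 1")
  if (n_cells < 1) stop("'n_cells' must be >= 1 (zero cells requested)")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("'dropout_rate' must be in [0, 1]")
  modules <- lapply(modules, function(m) {
    m <- utils::modifyList(list(activity_sd = 1, loading_range = c(0.8, 1.2)), m)
    if (is.null(m$size) || m$size < 1) stop("each module needs a size >= 1")
    if (m$activity_sd < 0) stop("module 'activity_sd' must be >= 0")
    if (length(m$loading_range) != 2 || diff(m$loading_range) < 0)
      stop("'loading_range' must be an interval c(lo, hi)")
    m
  })
  if (length(modules) && sum(vapply(modules, `[[`, 0, "size")) > n_genes)
    stop("module sizes sum to more than 'n_genes'")
  cell_types <- lapply(cell_types, function(ct) {
    ct <- utils::modifyList(list(marker_genes = 0L,
                                 active_modules = integer(0),
                                 condition = "control"), ct)
    if (is.null(ct$name) || !nzchar(ct$name)) stop("cell type needs a name")
    if (is.null(ct$n_cells) || ct$n_cells < 1)
      stop("cell type '", ct$name, "' needs n_cells >= 1")
    if (length(ct$active_modules) &&
        (max(ct$active_modules) > length(modules) || min(ct$active_modules) < 1))
      stop("cell type '", ct$name, "' references unknown modules")
    ct
  })
  if (length(cell_types)) {
    if (anyDuplicated(vapply(cell_types, `[[`, "", "name")))
      stop("duplicate cell type names")
    if (sum(vapply(cell_types, `[[`, 0, "n_cells")) != n_cells)
      stop("cell-type cell counts must sum to 'n_cells'")
  }
  if (!is.null(trajectory)) {
    trajectory <- utils::modifyList(
      list(n_lineages = 1L, modules_up = integer(0),
           modules_down = integer(0), branch_point = 0.5, scale = 2), trajectory)
    if (!trajectory$n_lineages %in% c(1L, 2L))
      stop("'n_lineages' must be 1 or 2")
    ids <- c(trajectory$modules_up, trajectory$modules_down)
    if (length(ids) && (max(ids) > length(modules) || min(ids) < 1))
      stop("trajectory references unknown modules")
    if (trajectory$branch_point <= 0 || trajectory$branch_point >= 1)
      stop("'branch_point' must be in (0, 1)")
  }
  if (!is.null(lr_plan)) {
    if (!is.data.frame(lr_plan))
      lr_plan <- do.call(rbind, lapply(lr_plan, function(p)
        data.frame(source = p[[1]], target = p[[2]])))
    type_names <- vapply(cell_types, `[[`, "", "name")
    bad <- setdiff(unique(c(lr_plan$source, lr_plan$target)), type_names)
    if (length(bad)) stop("lr_plan references unknown cell type(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 modules = modules, cell_types = cell_types,
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 trajectory = trajectory, lr_plan = lr_plan,
                 activity_shift = activity_shift,
                 marker_strength = marker_strength,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic expression matrix with recorded ground truth
#'
#' Draws one dataset from a [synthetic_config()]. Module activities are
#' Gaussian per cell (plus `activity_shift` in cell types that activate the
#' module); trajectory-driven modules instead follow a deterministic ramp in
#' pseudotime (rising for `modules_up`, falling for `modules_down`; in
#' two-branch trajectories each rising module is tied to one lineage and
#' plateaus on the other after the branch point). Marker genes for a cell
#' type are the leading genes of its first active module, or dedicated
#' boosted background genes if the type activates no module.
#'
#' @param config a [synthetic_config()].
#' @return list with `expr` (an [sc_expr()]; metadata columns `cell_type`,
#'   `condition`) and `truth`, a list recording `gene_module` (gene ->
#'   module id or "unassigned"), `cell_type`, `pseudotime` and `lineage`
#'   (when a trajectory is configured), `markers` (cell type -> gene set),
#'   `lr_pairs` (data.frame ligand/receptor/source/target, or NULL),
#'   `module_activity` (module x cell matrix) and `loadings`.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  nc <- config$n_cells
  genes <- sprintf("g%05d", seq_len(ng))
  cells <- sprintf("c%05d", seq_len(nc))
  n_mod <- length(config$modules)
  mod_ids <- if (n_mod) paste0("M", seq_len(n_mod)) else character(0)

  gene_module <- rep("unassigned", ng)
  mod_genes <- list()
  at <- 0L
  for (m in seq_len(n_mod)) {
    idx <- at + seq_len(config$modules[[m]]$size)
    gene_module[idx] <- mod_ids[m]
    mod_genes[[mod_ids[m]]] <- genes[idx]
    at <- at + config$modules[[m]]$size
  }
  names(gene_module) <- genes

  # cell types and metadata
  if (length(config$cell_types)) {
    type_of <- rep(vapply(config$cell_types, `[[`, "", "name"),
                   vapply(config$cell_types, `[[`, 0, "n_cells"))
    cond_of <- rep(vapply(config$cell_types, `[[`, "", "condition"),
                   vapply(config$cell_types, `[[`, 0, "n_cells"))
  } else {
    type_of <- rep("cell", nc)
    cond_of <- rep("control", nc)
  }
  names(type_of) <- cells

  baseline <- stats::runif(ng, 1, 2)

  # trajectory latent variables
  pseudotime <- NULL
  lineage <- NULL
  traj <- config$trajectory
  up_lineage <- integer(0)
  if (!is.null(traj)) {
    pseudotime <- stats::runif(nc)
    lineage <- if (traj$n_lineages == 2L)
      sample(c(1L, 2L), nc, replace = TRUE) else rep(1L, nc)
    names(pseudotime) <- names(lineage) <- cells
    if (length(traj$modules_up))
      up_lineage <- ((seq_along(traj$modules_up) - 1L) %% traj$n_lineages) + 1L
    cond_of <- ifelse(pseudotime < 0.25, "control", "case")
  }

  # module activities (module x cell)
  A <- matrix(0, nrow = n_mod, ncol = nc,
              dimnames = list(mod_ids, cells))
  active_in <- lapply(seq_len(n_mod), function(m)
    vapply(config$cell_types, function(ct) m %in% ct$active_modules, TRUE))
  for (m in seq_len(n_mod)) {
    sdm <- config$modules[[m]]$activity_sd
    A[m, ] <- stats::rnorm(nc, 0, sdm)
    if (length(config$cell_types)) {
      act_types <- vapply(config$cell_types, `[[`, "", "name")[active_in[[m]]]
      A[m, type_of %in% act_types] <-
        A[m, type_of %in% act_types] + config$activity_shift
    }
  }
  if (!is.null(traj)) {
    b <- traj$branch_point
    for (i in seq_along(traj$modules_up)) {
      m <- traj$modules_up[i]
      own <- lineage == up_lineage[i]
      # ramps along its own lineage; on the other branch the program is
      # suppressed back toward baseline after the branch point (branch
      # programs are mutually exclusive, as failing-heart module pairs are)
      A[m, ] <- traj$scale * ifelse(own | pseudotime <= b, pseudotime,
                                    pmax(b - (pseudotime - b), 0))
    }
    for (m in traj$modules_down)
      A[m, ] <- traj$scale * (1 - pseudotime)
  }

  loadings <- lapply(seq_len(n_mod), function(m)
    stats::runif(config$modules[[m]]$size,
                 config$modules[[m]]$loading_range[1],
                 config$modules[[m]]$loading_range[2]))

  Z <- matrix(baseline, nrow = ng, ncol = nc,
              dimnames = list(genes, cells))
  for (m in seq_len(n_mod)) {
    idx <- which(gene_module == mod_ids[m])
    Z[idx, ] <- Z[idx, ] + outer(loadings[[m]], A[m, ])
  }

  # markers: leading genes of the type's first active module, or dedicated
  # background genes boosted in the type's own cells
  markers <- list()
  free_bg <- genes[gene_module == "unassigned"]
  for (ct in config$cell_types) {
    if (ct$marker_genes < 1) next
    if (length(ct$active_modules)) {
      src <- mod_genes[[mod_ids[ct$active_modules[1]]]]
      if (length(src) < ct$marker_genes)
        stop("cell type '", ct$name, "' requests more markers than its module has")
      markers[[ct$name]] <- src[seq_len(ct$marker_genes)]
    } else {
      if (length(free_bg) < ct$marker_genes)
        stop("not enough unassigned genes for markers of '", ct$name, "'")
      mk <- free_bg[seq_len(ct$marker_genes)]
      free_bg <- setdiff(free_bg, mk)
      markers[[ct$name]] <- mk
      Z[mk, type_of == ct$name] <- Z[mk, type_of == ct$name] +
        config$marker_strength
    }
  }
  if (length(markers) > 1 && anyDuplicated(unlist(markers)))
    stop("marker sets overlap across cell types; give each type its own module")

  # planted LR pairs: ligand from a module active in the source type,
  # receptor from a module active in the target type
  lr_pairs <- NULL
  if (!is.null(config$lr_plan) && nrow(config$lr_plan)) {
    used <- unlist(markers, use.names = FALSE)
    pick_gene <- function(type_name) {
      ct <- config$cell_types[[match(type_name,
              vapply(config$cell_types, `[[`, "", "name"))]]
      if (!length(ct$active_modules))
        stop("lr_plan type '", type_name, "' activates no module")
      pool <- unlist(mod_genes[mod_ids[ct$active_modules]], use.names = FALSE)
      pool <- setdiff(pool, used)
      if (!length(pool))
        stop("no free module genes left for LR pair in type '", type_name, "'")
      g <- pool[1]
      used <<- c(used, g)
      g
    }
    lr_pairs <- do.call(rbind, lapply(seq_len(nrow(config$lr_plan)), function(i) {
      s <- config$lr_plan$source[i]
      t <- config$lr_plan$target[i]
      data.frame(ligand = pick_gene(s), receptor = pick_gene(t),
                 source = s, target = t, stringsAsFactors = FALSE)
    }))
  }

  if (config$noise_sd > 0)
    Z <- Z + matrix(stats::rnorm(ng * nc, 0, config$noise_sd), ng, nc)
  values <- pmax(exp(Z) - 1, 0)
  if (config$dropout_rate > 0)
    values <- values *
      (matrix(stats::runif(ng * nc), ng, nc) >= config$dropout_rate)
  dimnames(values) <- list(genes, cells)

  meta <- data.frame(cell_id = cells, cell_type = type_of,
                     condition = cond_of, stringsAsFactors = FALSE)
  truth <- list(gene_module = gene_module,
                cell_type = type_of,
                pseudotime = pseudotime,
                lineage = lineage,
                markers = markers,
                lr_pairs = lr_pairs,
                module_activity = A,
                loadings = loadings,
                config = config)
  list(expr = sc_expr(values, meta), truth = truth)
}

#' Generate a trajectory dataset
#'
#' Convenience wrapper around [generate_expression()] that requires a
#' configured trajectory (one or two lineages).
#'
#' @inheritParams generate_expression
#' @return as [generate_expression()]; `truth$pseudotime` and
#'   `truth$lineage` are always set.
#' @export
generate_trajectory_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$trajectory))
    stop("config has no trajectory; set 'trajectory' in synthetic_config()")
  generate_expression(config)
}

#' Generate a ligand-receptor database from planted truth
#'
#' Returns the planted ligand-receptor pairs of a synthetic dataset plus
#' `n_decoys` decoy pairs drawn uniformly among ordered pairs of distinct
#' unassigned genes (genes in no planted module), with no duplicate
#' (ligand, receptor) rows.
#'
#' @param truth the `truth` component of [generate_expression()].
#' @param n_decoys number of decoy pairs to add.
#' @param seed integer seed for decoy sampling.
#' @return data.frame of class `lr_database` with columns `ligand`,
#'   `receptor`.
#' @export
generate_lr_database <- function(truth, n_decoys = 0, seed = 1) {
  planted <- truth$lr_pairs
  if (is.null(planted))
    planted <- data.frame(ligand = character(0), receptor = character(0),
                          stringsAsFactors = FALSE)
  if (nrow(planted) == 0 && n_decoys == 0)
    stop("no planted LR pairs and no decoys requested")
  db <- planted[, c("ligand", "receptor"), drop = FALSE]
  if (n_decoys > 0) {
    bg <- names(truth$gene_module)[truth$gene_module == "unassigned"]
    n_avail <- length(bg) * (length(bg) - 1L)
    if (n_decoys > n_avail)
      stop("requested ", n_decoys, " decoys but only ", n_avail,
           " ordered pairs of unassigned genes exist")
    set.seed(seed)
    seen <- character(0)
    decoys <- vector("list", n_decoys)
    k <- 0L
    while (k < n_decoys) {
      pair <- sample(bg, 2L)
      key <- paste(pair, collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      k <- k + 1L
      decoys[[k]] <- pair
    }
    db <- rbind(db, data.frame(ligand = vapply(decoys, `[`, "", 1L),
                               receptor = vapply(decoys, `[`, "", 2L),
                               stringsAsFactors = FALSE))
  }
  db <- unique(db)
  rownames(db) <- NULL
  class(db) <- c("lr_database", "data.frame")
  db
}

#' Generate a multi-group proteome table with planted effects
#'
#' Simulates a protein-by-sample abundance table over labelled groups
#' (e.g. control / non-advanced / advanced heart failure before and after
#' transplantation): `value = baseline + group_shift + N(0, noise_sd)`.
#'
#' @param groups named integer vector (or data.frame with `name`,
#'   `n_samples`): samples per group; at least two groups, each >= 1 sample.
#' @param effects named list: protein -> named numeric vector of per-group
#'   mean shifts (groups not named get shift 0).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @param baseline common baseline abundance.
#' @return list with `proteome` (class `proteome_table`: list of `values`
#'   protein x sample matrix and `sample_group` factor) and `truth`
#'   (`biomarker_effects = effects`).
#' @export
generate_proteome <- function(groups, effects, noise_sd = 1, seed = 1,
                              baseline = 10) {
  if (is.data.frame(groups)) {
    g <- stats::setNames(as.integer(groups$n_samples), groups$name)
  } else g <- groups
  if (length(g) < 2) stop("need at least 2 groups")
  if (any(g < 1)) stop("every group needs at least 1 sample")
  if (!length(effects)) stop("need at least 1 protein")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  set.seed(seed)
  sample_group <- factor(rep(names(g), g), levels = names(g))
  n <- length(sample_group)
  samples <- sprintf("s%05d", seq_len(n))
  proteins <- names(effects)
  values <- matrix(baseline, nrow = length(proteins), ncol = n,
                   dimnames = list(proteins, samples))
  for (p in proteins) {
    sh <- effects[[p]]
    shift <- ifelse(as.character(sample_group) %in% names(sh),
                    unname(sh[as.character(sample_group)]), 0)
    shift[is.na(shift)] <- 0
    values[p, ] <- values[p, ] + shift
  }
  if (noise_sd > 0)
    values <- values + matrix(stats::rnorm(length(proteins) * n, 0, noise_sd),
                              nrow = length(proteins))
  proteome <- structure(list(values = values,
                             sample_group = stats::setNames(sample_group, samples)),
                        class = "proteome_table")
  list(proteome = proteome, truth = list(biomarker_effects = effects))
}

#' @export
print.proteome_table <- function(x, ...) {
  cat("proteome_table: ", nrow(x$values), " proteins x ", ncol(x$values),
      " samples (", paste(levels(x$sample_group), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}
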