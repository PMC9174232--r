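# Readers and writers for the on-disk formats (TSV and matrix-market
# expression, LR database TSV, truth JSON) and the end-to-end pipeline
# runner. All writers use fixed column order, tab separators and "\n" line
# endings so reruns are byte-identical.

#' Write an expression matrix
#'
#' `format = "tsv"`: one file, genes in rows, first column `gene`, one
#' column per cell. `format = "mtx"`: `path` is a directory receiving
#' `matrix.mtx` (sparse triplet), `genes.tsv` and `barcodes.tsv`. Cell
#' metadata, when present, goes to `<path>_meta.tsv` (tsv) or
#' `cell_meta.tsv` (mtx).
#'
#' @param x `sc_expr` or genes-by-cells matrix.
#' @param path output file (tsv) or directory (mtx).
#' @param format "tsv" or "mtx".
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  v <- expr_values(x)
  meta <- expr_meta(x)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    if (!is.null(meta))
      utils::write.table(meta, paste0(path, "_meta.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, eol = "\n")
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(v), file.path(path, "genes.tsv"))
    writeLines(colnames(v), file.path(path, "barcodes.tsv"))
    if (!is.null(meta))
      utils::write.table(meta, file.path(path, "cell_meta.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Read an expression matrix
#'
#' Inverse of [write_expression()]. Enforces the container invariants:
#' unique gene and cell ids, matching dimension/id files, and nonnegative
#' entries (a negative entry is reported with its gene and cell).
#'
#' @param path file (tsv) or directory (mtx).
#' @param format "auto" (directory means mtx), "tsv" or "mtx".
#' @return an [sc_expr()] (with metadata when a metadata file is found).
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "mtx" else "tsv"
  if (format == "tsv") {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    genes <- df[[1L]]
    v <- as.matrix(df[, -1L, drop = FALSE])
    rownames(v) <- genes
    meta_path <- paste0(path, "_meta.tsv")
  } else {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf))
      if (!file.exists(f)) stop("no such file: ", f)
    m <- Matrix::readMM(mtx)
    genes <- readLines(gf)
    cells <- readLines(bf)
    if (length(genes) != nrow(m))
      stop("genes.tsv has ", length(genes), " entries for ", nrow(m),
           " matrix rows (", gf, ")")
    if (length(cells) != ncol(m))
      stop("barcodes.tsv has ", length(cells), " entries for ", ncol(m),
           " matrix columns (", bf, ")")
    v <- as.matrix(m)
    dimnames(v) <- list(genes, cells)
    meta_path <- file.path(path, "cell_meta.tsv")
  }
  storage.mode(v) <- "double"
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop("negative entry at gene '", rownames(v)[bad[1L]], "', cell '",
         colnames(v)[bad[2L]], "'")
  }
  meta <- if (file.exists(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE) else NULL
  sc_expr(v, meta)
}

#' Write / read a ligand-receptor database as TSV
#'
#' Two tab-separated columns, `ligand` and `receptor`, one pair per row.
#'
#' @param lr_db data.frame with `ligand`, `receptor`.
#' @param path TSV file path.
#' @return `path` invisibly (write); `lr_database` data.frame (read).
#' @export
write_lr_database <- function(lr_db, path) {
  utils::write.table(lr_db[, c("ligand", "receptor")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_lr_database
#' @export
read_lr_database <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% colnames(df)))
    stop("LR database must have 'ligand' and 'receptor' columns")
  df <- unique(df[, c("ligand", "receptor")])
  rownames(df) <- NULL
  class(df) <- c("lr_database", "data.frame")
  df
}

#' Write synthetic ground truth as JSON
#'
#' Serialises the recoverable parts of a synthetic truth record (module
#' assignment, cell types, pseudotime, lineages, markers, LR pairs).
#'
#' @param truth the `truth` component of [generate_expression()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(gene_module = as.list(truth$gene_module),
              cell_type = as.list(truth$cell_type),
              pseudotime = if (!is.null(truth$pseudotime))
                as.list(truth$pseudotime),
              lineage = if (!is.null(truth$lineage))
                as.list(truth$lineage),
              markers = truth$markers,
              lr_pairs = truth$lr_pairs)
  jsonlite::write_json(out[!vapply(out, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_named_tsv <- function(x, path, key = "id", value = "value") {
  df <- data.frame(a = names(x), b = unname(x), stringsAsFactors = FALSE)
  colnames(df) <- c(key, value)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

write_matrix_tsv <- function(m, path, key = "id") {
  df <- data.frame(a = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- key
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Unknown
#' stage names or parameters are rejected. The resolved configuration is
#' written next to the outputs of every run.
#'
#' @param out_dir output directory.
#' @param seed master seed for the run.
#' @param sim a [synthetic_config()] generating the input dataset, or NULL
#'   when `input` is given.
#' @param input optional list(path=, format=) pointing at an expression
#'   matrix on disk.
#' @param qc list: `min_genes` (cells must detect more than this many
#'   genes; default 300), `min_value`, `min_cells` (gene filter, defaults
#'   10 and 1).
#' @param log_values logical: apply log2(x+1) before correlations
#'   (default TRUE).
#' @param network list: `power` ("auto" or an integer), `min_size`
#'   (default 30), `merge_cor` (default 0.75).
#' @param communication NULL to skip, else list: `n_decoys`,
#'   `edge_cor_min` (LR database decoys and map edge threshold; the LR
#'   database and marker sets come from the simulation truth).
#' @param trajectory NULL to skip, else list: `k` (SNN neighbours),
#'   `root` (cluster label, or NULL to pick the control-dominated
#'   cluster), `span` (dynamics smoothing).
#' @param classification NULL to skip, else list: `n_trees`, `label_col`
#'   (metadata column to classify; default "condition").
#' @param proteome NULL to skip, else list: `groups`, `effects`,
#'   `noise_sd`, `diagnosis_split`, `severity_split` (see
#'   [generate_proteome()] and [severity_vs_diagnosis_screen()]).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = NULL, input = NULL,
                            qc = list(), log_values = TRUE,
                            network = list(), communication = NULL,
                            trajectory = NULL, classification = NULL,
                            proteome = NULL) {
  if (is.null(sim) && is.null(input))
    stop("either 'sim' or 'input' is required")
  if (!is.null(sim) && !inherits(sim, "synthetic_config"))
    stop("'sim' must be a synthetic_config")
  qc <- merge_params(list(min_genes = 300, min_value = 10, min_cells = 1),
                     qc, "qc")
  network <- merge_params(list(power = "auto", min_size = 30,
                               merge_cor = 0.75), network, "network")
  if (!is.null(communication))
    communication <- merge_params(list(n_decoys = 0, edge_cor_min = 0.5),
                                  communication, "communication")
  if (!is.null(trajectory))
    trajectory <- merge_params(list(k = 10, root = NULL, span = 0.3),
                               trajectory, "trajectory")
  if (!is.null(classification))
    classification <- merge_params(list(n_trees = 200,
                                        label_col = "condition"),
                                   classification, "classification")
  if (!is.null(proteome))
    proteome <- merge_params(list(groups = NULL, effects = NULL,
                                  noise_sd = 1, diagnosis_split = NULL,
                                  severity_split = NULL),
                             proteome, "proteome")
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 input = input, qc = qc, log_values = log_values,
                 network = network, communication = communication,
                 trajectory = trajectory, classification = classification,
                 proteome = proteome),
            class = "pipeline_config")
}

merge_params <- function(defaults, given, stage) {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop("unknown ", stage, " parameter(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, given)
}

#' Run the full analysis pipeline
#'
#' Executes QC filtering, network construction and module detection, then
#' (as configured) LR communication mapping, trajectory analysis with
#' module dynamics, random-forest module importance, and the proteome
#' biomarker screen. Every stage writes its tables under `out_dir` and is
#' recorded in `manifest.json` together with the parameters it applied and
#' the md5 checksum of each output; rerunning the same configuration
#' reproduces byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(seed = config$seed, stages = list())
  record <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      parameters = params,
      outputs = lapply(stats::setNames(files, basename(files)), function(f)
        unname(tools::md5sum(f))))
  }
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  # --- input -----------------------------------------------------------
  truth <- NULL
  tryCatch({
    if (!is.null(config$sim)) {
      sim <- generate_expression(config$sim)
      x <- sim$expr
      truth <- sim$truth
      write_expression(x, out("expression.tsv"))
      write_truth_json(truth, out("truth.json"))
      record("input", list(source = "simulated", seed = config$sim$seed),
             c(out("expression.tsv"), out("truth.json")))
    } else {
      x <- read_expression(config$input$path)
      record("input", list(source = config$input$path), character(0))
    }
  }, error = function(e) fail("input", e))

  # --- qc --------------------------------------------------------------
  tryCatch({
    x <- filter_cells_by_detected_genes(x, config$qc$min_genes)
    x <- filter_genes_by_expression(x, config$qc$min_value,
                                    config$qc$min_cells)
    lx <- if (config$log_values) log_transform(x) else x
    write_expression(lx, out("expression_qc.tsv"))
    record("qc", config$qc[c("min_genes", "min_value", "min_cells")],
           out("expression_qc.tsv"))
  }, error = function(e) fail("qc", e))

  # --- network ---------------------------------------------------------
  modules <- NULL
  eig <- NULL
  tryCatch({
    lv <- expr_values(lx)
    beta <- config$network$power
    if (identical(beta, "auto"))
      beta <- suppressWarnings(pick_soft_threshold(lv)$beta)
    tom <- topological_overlap(signed_adjacency(gene_correlation(lv), beta))
    modules <- detect_modules(tom, min_size = config$network$min_size,
                              merge_cor = config$network$merge_cor,
                              expr = lv)
    eig <- module_eigengenes(lv, modules)
    mem <- module_membership(lv, eig)
    write_named_tsv(modules$assignment, out("module_assignment.tsv"),
                    "gene", "module")
    write_matrix_tsv(eig, out("module_eigengenes.tsv"), "module")
    write_matrix_tsv(round(mem, 10), out("module_membership.tsv"), "gene")
    record("network",
           list(power = beta, min_size = config$network$min_size,
                merge_cor = config$network$merge_cor),
           c(out("module_assignment.tsv"), out("module_eigengenes.tsv"),
             out("module_membership.tsv")))
  }, error = function(e) fail("network", e))

  # --- communication ---------------------------------------------------
  if (!is.null(config$communication)) tryCatch({
    if (is.null(truth))
      stop("LR communication in this runner requires a simulated input")
    lr_db <- generate_lr_database(truth, config$communication$n_decoys,
                                  seed = config$seed)
    ann <- annotate_modules(modules, truth$markers)
    imap <- build_interaction_network(modules, ann, lr_db)
    ranks <- rank_interacting_cell_types(imap)
    write_lr_database(lr_db, out("lr_database.tsv"))
    utils::write.table(imap$edges, out("lr_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n")
    write_matrix_tsv(imap$counts, out("interaction_counts.tsv"),
                     "source")
    utils::write.table(ranks, out("cell_type_ranks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n")
    record("communication", config$communication,
           c(out("lr_database.tsv"), out("lr_edges.tsv"),
             out("interaction_counts.tsv"), out("cell_type_ranks.tsv")))
  }, error = function(e) fail("communication", e))

  # --- trajectory ------------------------------------------------------
  if (!is.null(config$trajectory)) tryCatch({
    coords <- embed_cells(lx, seed = config$seed)
    labels <- cluster_snn(coords, k = config$trajectory$k,
                          seed = config$seed)
    root <- config$trajectory$root
    if (is.null(root))
      root <- select_root_cluster(labels, expr_meta(lx))
    lineages <- infer_lineages(coords, labels, root)
    pt <- lapply(lineages, compute_pseudotime, coords = coords,
                 labels = labels)
    write_matrix_tsv(round(coords, 10), out("embedding.tsv"), "cell")
    write_named_tsv(labels, out("clusters.tsv"), "cell", "cluster")
    jsonlite::write_json(lineages, out("lineages.json"), digits = NA,
                         pretty = TRUE)
    pt_m <- do.call(cbind, pt)
    colnames(pt_m) <- paste0("lineage", seq_along(pt))
    write_matrix_tsv(round(pt_m, 10), out("pseudotime.tsv"), "cell")
    dyn_files <- character(0)
    if (!is.null(eig)) {
      dyn <- do.call(rbind, lapply(rownames(eig), function(m) {
        d <- module_dynamics(eig, pt[[1L]], m,
                             span = config$trajectory$span,
                             n_perm = 200, seed = config$seed)
        data.frame(module = m, direction = d$direction,
                   trend = round(d$trend, 10),
                   stringsAsFactors = FALSE)
      }))
      utils::write.table(dyn, out("module_dynamics.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, eol = "\n")
      dyn_files <- out("module_dynamics.tsv")
    }
    record("trajectory",
           list(k = config$trajectory$k, root = root,
                span = config$trajectory$span),
           c(out("embedding.tsv"), out("clusters.tsv"),
             out("lineages.json"), out("pseudotime.tsv"), dyn_files))
  }, error = function(e) fail("trajectory", e))

  # --- classification --------------------------------------------------
  if (!is.null(config$classification)) tryCatch({
    meta <- expr_meta(lx)
    lab_col <- config$classification$label_col
    if (is.null(meta) || !lab_col %in% colnames(meta))
      stop("no '", lab_col, "' column in cell metadata")
    imp <- rank_feature_importance(t(eig), meta[[lab_col]],
                                   n_trees = config$classification$n_trees,
                                   seed = config$seed)
    idf <- imp$importance
    idf$mean_decrease_accuracy <- round(idf$mean_decrease_accuracy, 10)
    utils::write.table(idf, out("module_importance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n")
    record("classification",
           list(n_trees = config$classification$n_trees,
                label_col = lab_col,
                oob_accuracy = round(imp$oob_accuracy, 10)),
           out("module_importance.tsv"))
  }, error = function(e) fail("classification", e))

  # --- biomarker -------------------------------------------------------
  if (!is.null(config$proteome)) tryCatch({
    pr <- generate_proteome(config$proteome$groups,
                            config$proteome$effects,
                            noise_sd = config$proteome$noise_sd,
                            seed = config$seed)
    screen <- severity_vs_diagnosis_screen(pr$proteome,
                                           config$proteome$diagnosis_split,
                                           config$proteome$severity_split)
    screen$auc_diagnosis <- round(screen$auc_diagnosis, 10)
    screen$auc_severity <- round(screen$auc_severity, 10)
    utils::write.table(screen, out("biomarker_screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n")
    record("biomarker", list(noise_sd = config$proteome$noise_sd),
           out("biomarker_screen.tsv"))
  }, error = function(e) fail("biomarker", e))

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Demonstration pipeline configuration
#'
#' A compact fully synthetic heart-like configuration exercising every
#' pipeline stage in seconds: four cell types (fibroblast, cardiomyocyte,
#' endothelial, immune) each driving its own co-expression module, planted
#' LR pairs with fibroblasts as the hub, decoy LR pairs among background
#' genes, and a four-group proteome with a diagnosis-strong and a
#' severity-strong marker.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return a [pipeline_config()].
#' @export
demo_pipeline_config <- function(out_dir, seed = 1) {
  sim <- synthetic_config(
    n_genes = 260, n_cells = 240,
    modules = replicate(4, list(size = 40, activity_sd = 1),
                        simplify = FALSE),
    cell_types = list(
      list(name = "fibroblast", n_cells = 60, marker_genes = 5,
           active_modules = 1L),
      list(name = "cardiomyocyte", n_cells = 60, marker_genes = 5,
           active_modules = 2L, condition = "case"),
      list(name = "endothelial", n_cells = 60, marker_genes = 5,
           active_modules = 3L),
      list(name = "immune", n_cells = 60, marker_genes = 5,
           active_modules = 4L, condition = "case")),
    lr_plan = data.frame(
      source = c("fibroblast", "fibroblast", "fibroblast", "cardiomyocyte",
                 "endothelial", "immune"),
      target = c("cardiomyocyte", "endothelial", "fibroblast", "fibroblast",
                 "immune", "fibroblast")),
    noise_sd = 0.3, seed = seed)
  pipeline_config(
    out_dir = out_dir, seed = seed, sim = sim,
    qc = list(min_genes = 10, min_value = 1, min_cells = 1),
    network = list(power = 6, min_size = 20),
    communication = list(n_decoys = 5),
    trajectory = list(k = 10),
    classification = list(n_trees = 200),
    proteome = list(
      groups = c(control = 60, nonadvanced = 25, advanced = 15),
      effects = list(
        bnp_like = c(nonadvanced = 3, advanced = 3.5),
        igfbp7_like = c(nonadvanced = 0.8, advanced = 3)),
      noise_sd = 1,
      diagnosis_split = list(negative = "control",
                             positive = c("nonadvanced", "advanced")),
      severity_split = list(negative = "nonadvanced",
                            positive = "advanced")))
}
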