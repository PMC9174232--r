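# Ligand-receptor communication: cell-type annotation of modules, the LR
# co-expression map, the directed cell-type interaction network, and
# hypergeometric gene-set enrichment.

#' Annotate modules with cell types by marker overlap
#'
#' Each module is assigned the cell type whose marker set overlaps its gene
#' content the most (e.g. Col1a1/Dcn/Lum for fibroblasts, Myl2/Myl4/Myh6/
#' Myh7 for cardiomyocytes). Ties and zero overlap give "unannotated".
#' Marker sets must be disjoint across cell types.
#'
#' @param assignment a `module_set` or named gene -> module vector.
#' @param markers named list: cell type -> character vector of marker genes.
#' @return object of class `cell_type_annotation`: list with `annotation`
#'   (module -> cell type or "unannotated") and `evidence` (module ->
#'   matched markers).
#' @export
annotate_modules <- function(assignment, markers) {
  asg <- if (inherits(assignment, "module_set")) assignment$assignment
         else assignment
  if (!length(markers)) stop("empty marker list")
  all_mk <- unlist(markers, use.names = FALSE)
  if (anyDuplicated(all_mk))
    stop("marker sets overlap across cell types")
  mods <- sort(unique(asg[asg != "unassigned"]))
  mods <- mods[order(as_module_rank(mods))]
  annotation <- stats::setNames(rep("unannotated", length(mods)), mods)
  evidence <- stats::setNames(vector("list", length(mods)), mods)
  for (m in mods) {
    genes <- names(asg)[asg == m]
    ov <- vapply(markers, function(mk) length(intersect(genes, mk)), 0L)
    top <- max(ov)
    if (top > 0 && sum(ov == top) == 1) {
      ct <- names(markers)[which.max(ov)]
      annotation[m] <- ct
      evidence[[m]] <- intersect(genes, markers[[ct]])
    }
  }
  structure(list(annotation = annotation, evidence = evidence),
            class = "cell_type_annotation")
}

#' @export
print.cell_type_annotation <- function(x, ...) {
  cat("cell_type_annotation:\n")
  for (m in names(x$annotation))
    cat("  ", m, " -> ", x$annotation[m],
        if (length(x$evidence[[m]]))
          paste0(" (", paste(x$evidence[[m]], collapse = ", "), ")") else "",
        "\n", sep = "")
  invisible(x)
}

#' Ligand-receptor co-expression map
#'
#' Restricts the expression matrix to genes present in the LR database,
#' embeds them in 2D by classical metric multidimensional scaling on
#' `1 - Pearson correlation` (deterministic), and emits correlation edges
#' between LR genes with correlation at or above `edge_cor_min`.
#'
#' @inheritParams gene_correlation
#' @param lr_db `lr_database` (data.frame with `ligand`, `receptor`).
#' @param edge_cor_min minimum correlation for an edge (default 0.5).
#' @param seed integer; kept for interface stability (classical MDS is
#'   deterministic).
#' @return list with `coords` (LR gene x 2 matrix) and `edges` (data.frame
#'   `gene_a`, `gene_b`, `correlation`).
#' @export
build_lr_map <- function(x, lr_db, edge_cor_min = 0.5, seed = 1) {
  v <- expr_values(x)
  lr_genes <- intersect(unique(c(lr_db$ligand, lr_db$receptor)), rownames(v))
  if (length(lr_genes) < 3)
    stop("fewer than 3 ligand/receptor genes present in the matrix")
  set.seed(seed)
  sub <- v[lr_genes, , drop = FALSE]
  cc <- gene_correlation(sub)
  d <- 1 - cc
  coords <- stats::cmdscale(stats::as.dist(d), k = 2)
  if (ncol(coords) < 2)  # degenerate geometry: pad with zeros
    coords <- cbind(coords, matrix(0, nrow(coords), 2 - ncol(coords)))
  rownames(coords) <- lr_genes
  colnames(coords) <- c("dim1", "dim2")
  idx <- which(upper.tri(cc) & cc >= edge_cor_min, arr.ind = TRUE)
  edges <- data.frame(gene_a = lr_genes[idx[, 1L]],
                      gene_b = lr_genes[idx[, 2L]],
                      correlation = cc[idx],
                      stringsAsFactors = FALSE)
  list(coords = coords, edges = edges)
}

#' Directed cell-type interaction network from LR pairs
#'
#' For every (ligand, receptor) pair in the database whose ligand falls in a
#' module annotated with cell type s and whose receptor falls in a module
#' annotated with cell type t, emits the directed edge s -> t. Genes that
#' are unassigned, absent, or in unannotated modules contribute no edge.
#' Autocrine edges (s = t) land on the diagonal of the counts matrix.
#'
#' @param assignment a `module_set` or named gene -> module vector.
#' @param annotation a `cell_type_annotation` from [annotate_modules()].
#' @param lr_db `lr_database` data.frame.
#' @return object of class `interaction_map`: list with `edges` (data.frame
#'   `ligand`, `receptor`, `source`, `target`) and `counts` (directed
#'   cell-type x cell-type integer matrix, source cell types in rows).
#' @export
build_interaction_network <- function(assignment, annotation, lr_db) {
  asg <- if (inherits(assignment, "module_set")) assignment$assignment
         else assignment
  ann <- annotation$annotation
  types <- sort(unique(ann[ann != "unannotated"]))
  gene_type <- function(g) {
    if (is.na(match(g, names(asg)))) return(NA_character_)
    m <- asg[[g]]
    if (m == "unassigned") return(NA_character_)
    ct <- ann[[m]]
    if (is.null(ct) || ct == "unannotated") NA_character_ else ct
  }
  src <- vapply(lr_db$ligand, gene_type, "")
  tgt <- vapply(lr_db$receptor, gene_type, "")
  keep <- !is.na(src) & !is.na(tgt)
  edges <- data.frame(ligand = lr_db$ligand[keep],
                      receptor = lr_db$receptor[keep],
                      source = src[keep], target = tgt[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
  counts <- matrix(0L, length(types), length(types),
                   dimnames = list(source = types, target = types))
  if (nrow(edges))
    for (i in seq_len(nrow(edges)))
      counts[edges$source[i], edges$target[i]] <-
        counts[edges$source[i], edges$target[i]] + 1L
  structure(list(edges = edges, counts = counts), class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat("interaction_map: ", nrow(x$edges), " LR edges among ",
      nrow(x$counts), " cell types\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Rank cell types by total interaction degree
#'
#' Orders cell types by row sum plus column sum of the directed interaction
#' counts (outgoing plus incoming LR edges), descending; ties break
#' alphabetically. The top-ranked type is the communication hub of the
#' tissue (cardiac fibroblasts, in the heart).
#'
#' @param counts square cell-type x cell-type matrix (an `interaction_map`
#'   is also accepted).
#' @return data.frame with `cell_type`, `degree_out`, `degree_in`,
#'   `degree_total`, ordered.
#' @export
rank_interacting_cell_types <- function(counts) {
  if (inherits(counts, "interaction_map")) counts <- counts$counts
  if (nrow(counts) != ncol(counts)) stop("'counts' must be square")
  out <- rowSums(counts)
  inc <- colSums(counts)
  tot <- out + inc
  ord <- order(-tot, rownames(counts))
  data.frame(cell_type = rownames(counts)[ord],
             degree_out = unname(out[ord]),
             degree_in = unname(inc[ord]),
             degree_total = unname(tot[ord]),
             stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric upper-tail test per annotation set (equivalent
#' to a one-sided Fisher's exact test on the 2x2 table), with
#' Benjamini-Hochberg adjustment across sets. Annotation sets are
#' intersected with the universe before testing.
#'
#' @param query character vector of genes, a subset of `universe`.
#' @param annotation_sets named list of gene sets.
#' @param universe character vector: the gene background.
#' @param alpha significance threshold recorded in the `significant` column.
#' @return data.frame with `set`, `set_size`, `overlap`, `p`, `adjusted_p`,
#'   `significant`, ordered by `p`.
#' @export
enrichment_test <- function(query, annotation_sets, universe, alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  universe <- unique(universe)
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stop("query contains genes outside the universe")
  res <- do.call(rbind, lapply(names(annotation_sets), function(nm) {
    s <- intersect(unique(annotation_sets[[nm]]), universe)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, length(s), length(universe) - length(s),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$adjusted_p <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$adjusted_p < alpha
  res <- res[order(res$p, res$set), ]
  rownames(res) <- NULL
  res
}
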