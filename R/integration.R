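#' Join binding calls with expression time courses
#'
#' Lossless outer join on gene id of the basal and stimulated consensus
#' binding heights and the replicate-averaged expression log2 ratios at
#' every (arm, timepoint). `binding_delta = height_stimulated -
#' height_basal` is the binding change used to rank genes; rows are sorted
#' by it (descending, `NA` last, ties by gene id).
#'
#' @param calls_basal,calls_stimulated Call tables from [call_condition()]
#'   (either may be `NULL`).
#' @param timecourse A `gene_timecourse` from [normalize_to_baseline()]
#'   (may be `NULL`).
#' @return A `data.frame` with `gene_id`, `height_basal`,
#'   `height_stimulated`, `binding_delta`, `passes_basal`,
#'   `passes_stimulated` and one `expr_<arm>_<time>h` column per design
#'   cell; genes absent from a source carry `NA`.
#' @export
build_integrated_table <- function(calls_basal, calls_stimulated,
                                   timecourse = NULL) {
  pick <- function(calls) {
    if (is.null(calls) || nrow(calls) == 0) {
      return(data.frame(gene_id = character(), height = numeric(),
                        passes = logical(), stringsAsFactors = FALSE))
    }
    if (anyDuplicated(calls$gene_id)) {
      stop("duplicate gene rows in a binding-call source")
    }
    data.frame(gene_id = calls$gene_id, height = calls$consensus_height,
               passes = calls$passes, stringsAsFactors = FALSE)
  }
  b <- pick(calls_basal)
  s <- pick(calls_stimulated)
  expr <- NULL
  if (!is.null(timecourse)) {
    des <- timecourse$design
    cells <- unique(des[, c("arm", "time_h")])
    cells <- cells[order(cells$arm, cells$time_h), , drop = FALSE]
    expr <- data.frame(gene_id = rownames(timecourse$log2ratio),
                       stringsAsFactors = FALSE)
    if (anyDuplicated(expr$gene_id)) {
      stop("duplicate gene rows in the expression source")
    }
    for (i in seq_len(nrow(cells))) {
      cols <- which(des$arm == cells$arm[i] & des$time_h == cells$time_h[i])
      expr[[sprintf("expr_%s_%gh", cells$arm[i], cells$time_h[i])]] <-
        rowMeans(timecourse$log2ratio[, cols, drop = FALSE])
    }
  }
  genes <- Reduce(union, list(b$gene_id, s$gene_id,
                              if (is.null(expr)) character() else expr$gene_id))
  out <- data.frame(gene_id = sort(genes), stringsAsFactors = FALSE)
  out$height_basal <- b$height[match(out$gene_id, b$gene_id)]
  out$height_stimulated <- s$height[match(out$gene_id, s$gene_id)]
  out$passes_basal <- b$passes[match(out$gene_id, b$gene_id)]
  out$passes_stimulated <- s$passes[match(out$gene_id, s$gene_id)]
  out$binding_delta <- out$height_stimulated - out$height_basal
  if (!is.null(expr)) {
    for (cn in setdiff(names(expr), "gene_id")) {
      out[[cn]] <- expr[[cn]][match(out$gene_id, expr$gene_id)]
    }
  }
  o <- order(-ifelse(is.na(out$binding_delta), -Inf, out$binding_delta),
             out$gene_id)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top genes by binding change
#'
#' First `k` rows of the integrated table under its binding-delta ordering
#' (descending, ties by gene id). Deterministic under ties.
#'
#' @param table An integrated table from [build_integrated_table()].
#' @param k Number of genes to keep (default 57, the conventional
#'   top-binding-change slice); clamped to the table size with a warning.
#' @return The first `k` rows.
#' @export
top_k <- function(table, k = 57) {
  if (k < 1) stop("'k' must be at least 1")
  if (k > nrow(table)) {
    warning("k exceeds table size; returning the full table")
    k <- nrow(table)
  }
  o <- order(-ifelse(is.na(table$binding_delta), -Inf, table$binding_delta),
             table$gene_id)
  out <- table[o, , drop = FALSE][seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher's exact (hypergeometric) gene-set over-representation
#'
#' For each gene set, the one-tailed over-representation p-value is the
#' hypergeometric upper tail `P(X >= overlap)` for drawing `|dataset|`
#' genes from a universe containing `|set|` set members. The pathway ratio
#' is `overlap / |set|` (set sizes counted after intersection with the
#' universe).
#'
#' @param dataset Character vector of selected genes (must lie within
#'   `universe`).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of all assayable genes.
#' @return A `data.frame` sorted by p-value: `set_name`, `overlap`,
#'   `set_size`, `dataset_size`, `universe_size`, `ratio`, `pvalue`,
#'   `neg_log10_p`.
#' @export
fisher_enrichment <- function(dataset, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  dataset <- unique(dataset)
  outside <- setdiff(dataset, universe)
  if (length(outside) > 0) {
    stop("dataset genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  if (is.null(names(sets))) names(sets) <- sprintf("set_%d", seq_along(sets))
  n_u <- length(universe)
  n_d <- length(dataset)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    ov <- length(intersect(dataset, s))
    k <- length(s)
    p <- if (k == 0) 1 else
      stats::phyper(ov - 1, k, n_u - k, n_d, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = k,
               dataset_size = n_d, universe_size = n_u,
               ratio = if (k == 0) NA_real_ else ov / k,
               pvalue = p, neg_log10_p = -log10(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pvalue, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
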