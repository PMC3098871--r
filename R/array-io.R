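#' Write ChIP probe tables to TSV, one file per array
#'
#' @param arrays A `chip_array_set`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a manifest `data.frame` with `path`, `condition`,
#'   `replicate`.
#' @export
write_chip_tables <- function(arrays, dir) {
  validate_chip_array_set(arrays)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  combos <- unique(arrays[, c("condition", "replicate")])
  paths <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sel <- arrays$condition == combos$condition[i] &
      arrays$replicate == combos$replicate[i]
    tab <- arrays[sel, c("probe_id", "gene_id", "offset_bp",
                         "ip_intensity", "mock_intensity")]
    paths[i] <- file.path(dir, sprintf("chip_%s_rep%s.tsv",
                                       combos$condition[i],
                                       combos$replicate[i]))
    utils::write.table(tab, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(data.frame(path = paths, condition = combos$condition,
                       replicate = combos$replicate,
                       stringsAsFactors = FALSE))
}

#' Read ChIP probe tables against a known layout
#'
#' Each file must be a TSV with header columns `probe_id`, `gene_id`,
#' `offset_bp`, `ip_intensity`, `mock_intensity`. Probes absent from the
#' layout are dropped with a warning (the drop count is attached as
#' attribute `"n_dropped"`); non-positive intensities are an error.
#'
#' @param manifest A `data.frame` with columns `path`, `condition`,
#'   `replicate` (as returned by [write_chip_tables()]).
#' @param layout The probe layout the tables must map onto.
#' @param verbose Emit per-file row counts as messages.
#' @return A `chip_array_set`.
#' @export
read_chip_tables <- function(manifest, layout,
                             verbose = getOption("tilepeak.verbose", FALSE)) {
  stopifnot(all(c("path", "condition", "replicate") %in% names(manifest)))
  out <- vector("list", nrow(manifest))
  n_dropped <- 0L
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$path[i]
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE),
      error = function(e) stop("empty or unreadable probe table: ", path)
    )
    need <- c("probe_id", "gene_id", "offset_bp", "ip_intensity",
              "mock_intensity")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
      stop(path, ": missing columns ", paste(miss, collapse = ", "))
    }
    if (nrow(tab) == 0) stop("empty probe table: ", path)
    alien <- !(tab$probe_id %in% layout$probe_id)
    if (any(alien)) {
      n_dropped <- n_dropped + sum(alien)
      warning(sum(alien), " unknown probe id(s) dropped from ", path)
      tab <- tab[!alien, , drop = FALSE]
    }
    if (any(!is.finite(tab$ip_intensity)) || any(tab$ip_intensity <= 0) ||
        any(!is.finite(tab$mock_intensity)) || any(tab$mock_intensity <= 0)) {
      stop(path, ": non-positive channel intensity")
    }
    tab$condition <- manifest$condition[i]
    tab$replicate <- manifest$replicate[i]
    if (verbose) message(sprintf("%s: %d probes", path, nrow(tab)))
    out[[i]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- validate_chip_array_set(res)
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Write binding-peak calls to a BED-like TSV
#'
#' Columns `gene_id`, `center_offset`, `height`, `llr`, `pvalue`,
#' `condition`, sorted by gene then condition. `llr` may be `NA` for
#' consensus-level calls.
#'
#' @param peaks A `data.frame` of per-replicate calls (the
#'   `"replicate_calls"` attribute of [call_condition()]) or consensus calls
#'   with columns mappable to the output.
#' @param path Output file path.
#' @return Invisibly, the written `data.frame`.
#' @export
write_peaks <- function(peaks, path) {
  get_col <- function(nms, default = NA) {
    for (nm in nms) if (nm %in% names(peaks)) return(peaks[[nm]])
    rep(default, nrow(peaks))
  }
  out <- data.frame(
    gene_id = get_col("gene_id"),
    center_offset = get_col(c("center_offset", "center", "consensus_center")),
    height = get_col(c("height", "consensus_height")),
    llr = get_col("llr", NA_real_),
    pvalue = get_col("pvalue", NA_real_),
    condition = get_col("condition", NA_character_),
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0) {
    if (any(!is.finite(out$center_offset)) || any(!is.finite(out$height))) {
      stop("peaks must have finite centers and heights")
    }
    out <- out[order(out$gene_id, out$condition), , drop = FALSE]
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a peak table written by [write_peaks()]
#'
#' @param path File path.
#' @return A `data.frame` with the six peak columns.
#' @export
read_peaks <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a motif matrix in TRANSFAC-count or UniPROBE-probability format
#'
#' The TRANSFAC dialect parses the count block between the `P0` header line
#' and the terminating `XX` (or `//`); counts are column-normalized to
#' frequencies. The UniPROBE dialect expects four lines starting with
#' `A:`, `C:`, `G:`, `T:` holding per-position probabilities (each position
#' must sum to 1 within 1e-6).
#'
#' @param path File path.
#' @param dialect `"transfac_counts"` or `"uniprobe_prob"`.
#' @param pseudocount Pseudocount for the log-odds transform.
#' @return A [motif_matrix()].
#' @export
read_motif_matrix <- function(path,
                              dialect = c("transfac_counts", "uniprobe_prob"),
                              pseudocount = 0.01) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  name <- basename(path)
  if (dialect == "transfac_counts") {
    p0 <- grep("^P0\\b", lines)
    if (length(p0) != 1L) stop("no P0 header line in ", path)
    hdr <- strsplit(trimws(lines[p0]), "\\s+")[[1]][-1]
    if (!identical(toupper(hdr[1:4]), c("A", "C", "G", "T"))) {
      stop("P0 header must list columns A C G T")
    }
    id <- grep("^ID\\s+", lines, value = TRUE)
    if (length(id) > 0) name <- sub("^ID\\s+", "", id[1])
    rows <- list()
    for (ln in lines[-seq_len(p0)]) {
      if (grepl("^(XX|//)", ln)) break
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 5L) stop("ragged row in count block: '", ln, "'")
      v <- suppressWarnings(as.numeric(f[2:5]))
      if (any(is.na(v))) stop("non-numeric counts in row: '", ln, "'")
      if (any(v < 0)) stop("negative counts in row: '", ln, "'")
      rows[[length(rows) + 1L]] <- v
    }
    if (length(rows) == 0) stop("no count rows in ", path)
    counts <- t(do.call(rbind, rows)) # 4 x width
    rownames(counts) <- c("A", "C", "G", "T")
    cs <- colSums(counts)
    if (any(cs <= 0)) stop("count column sums to zero in ", path)
    freq <- sweep(counts, 2L, cs, "/")
  } else {
    freq <- matrix(NA_real_, 4L, 0L, dimnames = list(c("A", "C", "G", "T"),
                                                     NULL))
    vals <- list()
    for (b in c("A", "C", "G", "T")) {
      ln <- grep(paste0("^", b, "\\s*:"), lines, value = TRUE)
      if (length(ln) != 1L) stop("expected exactly one '", b, ":' line")
      v <- suppressWarnings(as.numeric(
        strsplit(trimws(sub("^.*?:", "", ln)), "\\s+")[[1]]
      ))
      if (any(is.na(v))) stop("non-numeric probabilities on '", b, ":' line")
      vals[[b]] <- v
    }
    w <- unique(vapply(vals, length, integer(1)))
    if (length(w) != 1L) stop("ragged probability rows in ", path)
    freq <- do.call(rbind, vals)
    if (any(freq < 0)) stop("negative probabilities in ", path)
    cs <- colSums(freq)
    if (any(cs <= 0)) stop("probability column sums to zero in ", path)
    if (any(abs(cs - 1) > 1e-6)) {
      stop("probability columns must sum to 1 (max deviation ",
           format(max(abs(cs - 1))), ")")
    }
    freq <- sweep(freq, 2L, cs, "/")
  }
  motif_matrix(freq, pseudocount = pseudocount, name = name)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers around Biostrings; record ids are gene ids.
#'
#' @param x A [Biostrings::DNAStringSet] or named character vector.
#' @param path File path.
#' @return `read_fasta` returns a [Biostrings::DNAStringSet].
#' @export
write_fasta <- function(x, path) {
  if (!inherits(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read and write gene-set collections in GMT format
#'
#' GMT: one set per line, tab-separated: set name, description, members.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional per-set description strings.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("all gene sets must be named")
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields: '", ln, "'")
    sets[[f[1]]] <- f[-(1:2)]
  }
  sets
}

#' Write and read probe layouts as TSV
#'
#' @param layout A layout `data.frame` from [generate_layout()].
#' @param path File path.
#' @return `read_layout` returns the layout `data.frame`.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write and read one-color expression probe tables as long TSV
#'
#' Columns: `probe_id`, `gene_id`, `intensity`, `time_h`, `arm`,
#' `replicate`.
#'
#' @param em An [expr_matrix()].
#' @param path File path.
#' @return `read_expression_table` returns an [expr_matrix()].
#' @export
write_expression_table <- function(em, path) {
  stopifnot(inherits(em, "expr_matrix"))
  des <- em$design
  long <- do.call(rbind, lapply(seq_len(nrow(des)), function(a) {
    data.frame(
      probe_id = rownames(em$intensity),
      gene_id = em$probe_genes,
      intensity = em$intensity[, a],
      time_h = des$time_h[a], arm = des$arm[a], replicate = des$replicate[a],
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_table
#' @export
read_expression_table <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_id", "intensity", "time_h", "arm", "replicate")
  miss <- setdiff(need, names(long))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  des <- unique(long[, c("time_h", "arm", "replicate")])
  des <- des[order(des$arm, des$time_h, des$replicate), , drop = FALSE]
  des$array_id <- sprintf("%s_t%g_r%d", des$arm, des$time_h, des$replicate)
  probes <- unique(long$probe_id)
  mat <- matrix(NA_real_, length(probes), nrow(des),
                dimnames = list(probes, des$array_id))
  for (a in seq_len(nrow(des))) {
    sel <- long$time_h == des$time_h[a] & long$arm == des$arm[a] &
      long$replicate == des$replicate[a]
    sub <- long[sel, ]
    mat[match(sub$probe_id, probes), a] <- sub$intensity
  }
  genes <- long$gene_id[match(probes, long$probe_id)]
  expr_matrix(mat, des[, c("array_id", "time_h", "arm", "replicate")], genes)
}
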