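#' Cells-by-genes count container
#'
#' Validates and wraps a sparse non-negative integer count matrix together
#' with per-cell batch labels and optional cell-type / condition labels.
#' Batch labels are re-encoded to the contiguous integers `1..S` in order of
#' first appearance; the original labels are kept as `batch_levels`.
#'
#' @param counts matrix or `Matrix::sparseMatrix` of non-negative integers,
#'   cells in rows and genes in columns.
#' @param gene_ids character vector of unique gene identifiers (length =
#'   number of columns). Defaults to the column names of `counts`.
#' @param cell_ids character vector of unique cell identifiers (length =
#'   number of rows). Defaults to the row names of `counts`.
#' @param batch per-cell batch labels (any atomic type); a single batch is
#'   assumed when omitted.
#' @param cell_type optional per-cell cell-type labels.
#' @param condition optional per-cell condition labels (e.g. disease/control).
#' @return An object of class `sc_counts`: a list with elements `counts`
#'   (a `dgCMatrix`, cells x genes), `gene_ids`, `cell_ids`, `batch`
#'   (integer in `1..S`), `batch_levels`, `cell_type`, `condition`.
#' @examples
#' x <- sc_counts(rbind(c(1, 0), c(2, 2), c(0, 3)),
#'                gene_ids = c("g1", "g2"), cell_ids = c("c1", "c2", "c3"),
#'                batch = c("A", "B", "A"))
#' library_sizes(x)   # 1 4 3
#' @export
sc_counts <- function(counts, gene_ids = colnames(counts),
                      cell_ids = rownames(counts), batch = NULL,
                      cell_type = NULL, condition = NULL) {
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  vals <- counts@x
  if (any(vals < 0)) .stopf("negative count in matrix")
  if (any(vals != round(vals))) .stopf("non-integer count in matrix")
  d <- nrow(counts); v <- ncol(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(v))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(d))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != v)
    .stopf("gene_ids length (%d) != number of genes (%d)", length(gene_ids), v)
  if (length(cell_ids) != d)
    .stopf("cell_ids length (%d) != number of cells (%d)", length(cell_ids), d)
  if (anyDuplicated(gene_ids)) .stopf("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) .stopf("duplicate cell identifiers")
  if (is.null(batch)) batch <- rep(1L, d)
  if (length(batch) != d) .stopf("batch length (%d) != number of cells (%d)",
                                 length(batch), d)
  levels <- unique(batch)                     # first-appearance order
  batch_int <- match(batch, levels)
  if (!is.null(cell_type) && length(cell_type) != d)
    .stopf("cell_type length mismatch")
  if (!is.null(condition) && length(condition) != d)
    .stopf("condition length mismatch")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 batch = batch_int, batch_levels = as.character(levels),
                 cell_type = if (is.null(cell_type)) NULL else
                   as.character(cell_type),
                 condition = if (is.null(condition)) NULL else
                   as.character(condition)),
            class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("sc_counts: %d cells x %d genes, %d batch(es)%s\n",
              nrow(x$counts), ncol(x$counts), length(x$batch_levels),
              if (is.null(x$cell_type)) "" else
                sprintf(", %d cell type(s)", length(unique(x$cell_type)))))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' Subset cells of an sc_counts object
#' @param x an [sc_counts] object.
#' @param i cell index (integer or logical).
#' @param ... ignored.
#' @return an `sc_counts` with the selected cells; batch levels are kept so
#'   batch codes remain comparable across subsets.
#' @export
`[.sc_counts` <- function(x, i, ...) {
  structure(list(counts = x$counts[i, , drop = FALSE], gene_ids = x$gene_ids,
                 cell_ids = x$cell_ids[i],
                 batch = x$batch[i], batch_levels = x$batch_levels,
                 cell_type = x$cell_type[i], condition = x$condition[i]),
            class = "sc_counts")
}

#' Per-cell library sizes
#' @param x an [sc_counts] object.
#' @return integer-valued vector of per-cell total counts.
#' @export
library_sizes <- function(x) as.numeric(Matrix::rowSums(x$counts))

#' Read a count matrix with cell and gene annotation tables
#'
#' Reads either a Matrix Market coordinate file or a dense delimited text
#' matrix, together with one-identifier-per-row gene and cell tables.
#' The cell table may carry `batch`, `cell_type` and `condition` columns
#' (a header is auto-detected from the presence of those column names).
#'
#' @param path_matrix path to a `.mtx` Matrix Market file or a dense
#'   delimited text matrix (no header, no row names).
#' @param path_genes path to a delimited table whose first column holds gene
#'   identifiers.
#' @param path_cells path to a delimited table whose first column holds cell
#'   identifiers, optionally with `batch`/`cell_type`/`condition` columns.
#' @param mtx_orientation `"genes_by_cells"` (the common 10x convention;
#'   default) or `"cells_by_genes"`; dense matrices are always read as
#'   cells x genes.
#' @param sep field separator for the delimited files.
#' @return an [sc_counts] object.
#' @export
read_sc_counts <- function(path_matrix, path_genes, path_cells,
                           mtx_orientation = c("genes_by_cells",
                                               "cells_by_genes"),
                           sep = "\t") {
  mtx_orientation <- match.arg(mtx_orientation)
  for (p in c(path_matrix, path_genes, path_cells))
    if (!file.exists(p)) .stopf("file not found: %s", p)
  is_mm <- grepl("^%%MatrixMarket", readLines(path_matrix, n = 1L))
  if (is_mm) {
    m <- Matrix::readMM(path_matrix)
    if (mtx_orientation == "genes_by_cells") m <- Matrix::t(m)
  } else {
    m <- as.matrix(utils::read.table(path_matrix, sep = sep, header = FALSE))
    dimnames(m) <- NULL
  }
  gtab <- utils::read.table(path_genes, sep = sep, header = FALSE,
                            stringsAsFactors = FALSE)
  ctab_raw <- utils::read.table(path_cells, sep = sep, header = FALSE,
                                stringsAsFactors = FALSE)
  known <- c("cell_id", "batch", "cell_type", "condition")
  has_header <- any(tolower(as.character(ctab_raw[1L, ])) %in% known)
  if (has_header) {
    names(ctab_raw) <- tolower(as.character(ctab_raw[1L, ]))
    ctab <- ctab_raw[-1L, , drop = FALSE]
  } else {
    ctab <- ctab_raw
    names(ctab)[1L] <- "cell_id"
  }
  if (!"cell_id" %in% names(ctab)) names(ctab)[1L] <- "cell_id"
  if (nrow(gtab) != ncol(m))
    .stopf("gene table has %d rows but matrix has %d genes",
           nrow(gtab), ncol(m))
  if (nrow(ctab) != nrow(m))
    .stopf("cell table has %d rows but matrix has %d cells",
           nrow(ctab), nrow(m))
  sc_counts(m, gene_ids = gtab[[1L]], cell_ids = ctab$cell_id,
            batch = if ("batch" %in% names(ctab)) ctab$batch else NULL,
            cell_type = if ("cell_type" %in% names(ctab)) ctab$cell_type
              else NULL,
            condition = if ("condition" %in% names(ctab)) ctab$condition
              else NULL)
}

#' Write an sc_counts object to Matrix Market plus annotation tables
#'
#' Inverse of [read_sc_counts()]: writes the counts as a genes-by-cells
#' Matrix Market file plus tab-separated gene and cell tables.
#'
#' @param x an [sc_counts] object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_sc_counts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- file.path(dir, "matrix.mtx")
  pg <- file.path(dir, "genes.tsv")
  pc <- file.path(dir, "cells.tsv")
  Matrix::writeMM(Matrix::t(x$counts), pm)
  utils::write.table(data.frame(gene_id = x$gene_ids), pg, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- data.frame(cell_id = x$cell_ids,
                     batch = x$batch_levels[x$batch],
                     stringsAsFactors = FALSE)
  if (!is.null(x$cell_type)) meta$cell_type <- x$cell_type
  if (!is.null(x$condition)) meta$condition <- x$condition
  utils::write.table(meta, pc, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(c(matrix = pm, genes = pg, cells = pc))
}

#' Library-size normalization to per-cell gene frequencies
#'
#' Divides each cell's counts by its library size, yielding row-stochastic
#' relative expression profiles (the encoder input of the model).
#'
#' @param x an [sc_counts] object.
#' @param drop_empty drop cells with zero library size (default); when
#'   `FALSE`, a zero-library cell is an error.
#' @return a list with `profiles` (dense numeric matrix, rows summing to 1),
#'   `kept` (integer indices of retained cells) and `n_dropped`.
#' @examples
#' x <- sc_counts(rbind(c(2, 0, 2), c(1, 1, 2)))
#' normalize_profiles(x)$profiles[1, ]   # 0.5 0.0 0.5
#' @export
normalize_profiles <- function(x, drop_empty = TRUE) {
  n <- library_sizes(x)
  empty <- n == 0
  if (any(empty) && !drop_empty)
    .stopf("%d cell(s) have zero library size", sum(empty))
  if (any(empty))
    message(sprintf("dropping %d cell(s) with zero library size", sum(empty)))
  kept <- which(!empty)
  prof <- as.matrix(x$counts[kept, , drop = FALSE]) / n[kept]
  list(profiles = prof, kept = kept, n_dropped = sum(empty))
}

#' Align a dataset's genes to a reference gene list
#'
#' Reorders the columns of `target` to exactly `reference_genes`: common
#' genes are kept in reference order, reference genes absent from the target
#' are zero-filled (so a pretrained encoder's input dimension is preserved),
#' and target genes outside the reference are dropped. An optional two-column
#' ortholog map (target id, reference id) is applied first; many-to-many
#' rows are dropped and one-to-many conflicts resolved by first occurrence,
#' both with a message.
#'
#' @param target an [sc_counts] object.
#' @param reference_genes character vector of reference gene identifiers.
#' @param ortholog_map optional data.frame/matrix whose first two columns map
#'   target gene ids to reference gene ids.
#' @return an [sc_counts] with genes exactly `reference_genes`, plus
#'   attribute `coverage` = |common| / |reference|.
#' @export
align_to_reference <- function(target, reference_genes, ortholog_map = NULL) {
  reference_genes <- as.character(reference_genes)
  gids <- target$gene_ids
  if (!is.null(ortholog_map)) {
    om <- as.data.frame(ortholog_map, stringsAsFactors = FALSE)[, 1:2]
    names(om) <- c("from", "to")
    mm <- om$from %in% om$from[duplicated(om$from)] &
      om$to %in% om$to[duplicated(om$to)]
    # many-to-many: ambiguous in both directions
    amb_from <- unique(om$from[duplicated(om$from)])
    amb_to <- unique(om$to[duplicated(om$to)])
    m2m <- om$from %in% amb_from & om$to %in% amb_to
    if (any(m2m))
      message(sprintf("dropping %d many-to-many ortholog rows", sum(m2m)))
    om <- om[!m2m, , drop = FALSE]
    dup <- duplicated(om$from)
    if (any(dup))
      message(sprintf("resolving %d one-to-many ortholog rows by first occurrence",
                      sum(dup)))
    om <- om[!dup, , drop = FALSE]
    hit <- match(gids, om$from)
    gids <- ifelse(is.na(hit), gids, om$to[hit])
  }
  pos <- match(reference_genes, gids)   # first occurrence wins
  n_common <- sum(!is.na(pos))
  if (n_common == 0) .stopf("no common genes between target and reference")
  d <- nrow(target$counts)
  out <- Matrix::Matrix(0, d, length(reference_genes), sparse = TRUE)
  ok <- !is.na(pos)
  out[, ok] <- target$counts[, pos[ok], drop = FALSE]
  res <- sc_counts(out, gene_ids = reference_genes, cell_ids = target$cell_ids,
                   batch = target$batch_levels[target$batch],
                   cell_type = target$cell_type, condition = target$condition)
  attr(res, "coverage") <- n_common / length(reference_genes)
  res
}

#' Split cells into training and held-out sets
#'
#' @param x an [sc_counts] object.
#' @param fraction fraction of cells held out, in (0, 1). The held-out set
#'   has `round(fraction * D)` cells.
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return list with `train` and `held` [sc_counts] objects and the
#'   `held_idx` cell indices.
#' @export
holdout_split <- function(x, fraction = 0.1, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) .stopf("fraction must be in (0, 1)")
  d <- nrow(x$counts)
  n_held <- round(fraction * d)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  held_idx <- sort(sample.int(d, n_held))
  list(train = x[setdiff(seq_len(d), held_idx)], held = x[held_idx],
       held_idx = held_idx)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Sets smaller than `min_size` (after within-set
#' deduplication) are removed.
#'
#' @param path GMT file path.
#' @param min_size minimum retained set size (default 5).
#' @param on_duplicate `"error"` (default) or `"suffix"`, which deduplicates
#'   repeated set names by appending `.1`, `.2`, ...
#' @return a named list of character vectors of gene symbols, with
#'   attribute `source` = the file path.
#' @export
read_gmt <- function(path, min_size = 5L, on_duplicate = c("error", "suffix")) {
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    .stopf("malformed GMT line %d: fewer than 3 fields", bad[1L])
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    if (on_duplicate == "error") .stopf("duplicate gene-set name: %s",
                                        nm[duplicated(nm)][1L])
    nm <- make.unique(nm, sep = ".")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  sets <- sets[vapply(sets, length, 1L) >= min_size]
  attr(sets, "source") <- path
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog / gene-mapping table
#' @param path TSV with two columns (target id, reference id); a header is
#'   skipped if present (detected by non-reappearing first row).
#' @return data.frame with columns `from`, `to`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) .stopf("ortholog map must have two columns")
  first <- tolower(as.character(tab[1L, ]))
  if (any(first %in% c("from", "to", "target", "reference", "gene",
                       "ortholog")))
    tab <- tab[-1L, , drop = FALSE]
  data.frame(from = as.character(tab[[1L]]), to = as.character(tab[[2L]]),
             stringsAsFactors = FALSE)
}
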