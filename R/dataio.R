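#' Expression matrix for one regulatory layer
#'
#' Lightweight container for a single layer of molecular measurements:
#' a numeric matrix with analytes (antibodies, phosphosites or genes) in
#' rows and cell lines in columns, missing values allowed. Antibody layers
#' may carry an analyte-to-gene map used for cross-layer matching.
#'
#' @param values numeric matrix, analytes x cells, with unique dimnames.
#' @param layer one of `"protein"`, `"phospho"`, `"mrna"`.
#' @param analyte_gene optional named character vector mapping analyte id
#'   to gene symbol (names = analyte ids). For phospho layers an id of the
#'   form `GENE_pSITE` (e.g. `SRC_pY416`) implies its gene when no map is
#'   given.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, layer, analyte_gene = NULL) {
  layer <- match_layer(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must have analyte rownames and cell colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicated analyte id: %s",
          rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stopf("duplicated cell id: %s",
          colnames(values)[duplicated(colnames(values))][1L])
  if (any(is.infinite(values)))
    stopf("non-finite values present; only NA is allowed as missing")
  structure(list(values = values, layer = layer, analyte_gene = analyte_gene),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d analytes x %d cells (%.1f%% missing)\n",
              x$layer, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
analyte_ids <- function(x) rownames(x$values) %||% character(0)

#' @rdname expr_matrix
#' @export
cell_ids <- function(x) colnames(x$values) %||% character(0)

MISSING_TOKENS <- c("", "NA", "NaN", "nan", "null", "NULL", "na", "N/A")

#' Read an expression matrix from a delimited text file
#'
#' Accepts TSV or CSV (delimiter auto-detected from the header line) with
#' one header row of cell ids and one id column, or GCT 1.2 (the two GCT
#' header lines and the Description column are skipped). The tokens
#' `""`, `NA`, `NaN`, `null` (any case) all read as missing.
#'
#' @param path file path.
#' @param layer layer tag stored on the result.
#' @param orientation `"analytes_in_rows"` (default) or `"cells_in_rows"`,
#'   in which case the table is transposed after reading.
#' @param analyte_gene optional analyte-to-gene map (see [expr_matrix()]).
#' @return An `expr_matrix`.
#' @export
read_matrix <- function(path, layer,
                        orientation = c("analytes_in_rows", "cells_in_rows"),
                        analyte_gene = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  gct <- startsWith(first, "#1.2")
  skip <- if (gct) 2L else 0L
  header <- readLines(path, n = skip + 1L)[skip + 1L]
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE, skip = skip,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  ids <- tab[[1L]]
  drop <- 1L
  if (gct && ncol(tab) >= 2L && tolower(names(tab)[2L]) == "description")
    drop <- c(1L, 2L)
  body <- tab[, -drop, drop = FALSE]
  if (anyDuplicated(ids))
    stopf("duplicated analyte id '%s' in %s", ids[duplicated(ids)][1L], path)
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(ids, names(body)))
  for (j in seq_len(ncol(body))) {
    raw <- trimws(body[[j]])
    raw[raw %in% MISSING_TOKENS] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stopf("non-numeric value '%s' at row '%s', column '%s' in %s",
            raw[bad[1L]], ids[bad[1L]], names(body)[j], path)
    vals[, j] <- num
  }
  if (orientation == "cells_in_rows") vals <- t(vals)
  expr_matrix(vals, layer, analyte_gene = analyte_gene)
}

#' Write an expression matrix as TSV
#'
#' Analytes in rows, cell lines in columns, empty string for missing;
#' the inverse of [read_matrix()].
#'
#' @param m an `expr_matrix`.
#' @param path output file.
#' @export
write_matrix <- function(m, path) {
  v <- m$values
  out <- cbind(analyte = rownames(v),
               as.data.frame(format(v, trim = TRUE, digits = 15),
                             check.names = FALSE))
  out[out == "NA"] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-line annotation table
#'
#' CSV with columns `cell_line`, `tissue`, `tumor_class` (values
#' `primary`/`metastasis`/`NS`) and optional further columns (e.g.
#' mutation flags).
#'
#' @param path CSV file.
#' @return data.frame with one row per cell line.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_line", "tissue")
  if (!all(need %in% names(ann)))
    stopf("annotation file must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(ann$cell_line))
    stopf("duplicated cell_line '%s' in annotation",
          ann$cell_line[duplicated(ann$cell_line)][1L])
  ann
}

#' Drop analytes measured in too few cell lines
#'
#' Coverage filter: retains exactly the analytes with at least `min_cells`
#' non-missing values (boundary inclusive), preserving row order. The
#' pan-cancer RPPA pipeline uses `min_cells = 40` for mixture fitting and
#' `min_cells = 100` for distance analyses.
#'
#' @param m an `expr_matrix`.
#' @param min_cells minimum number of non-missing cells, >= 1.
#' @return filtered `expr_matrix` (possibly with zero rows).
#' @export
filter_analytes_by_coverage <- function(m, min_cells) {
  min_cells <- assert_count(min_cells, "min_cells")
  keep <- rowSums(!is.na(m$values)) >= min_cells
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  if (!is.null(m$analyte_gene))
    out$analyte_gene <- m$analyte_gene[names(m$analyte_gene) %in%
                                         rownames(out$values)]
  out
}

phospho_gene <- function(ids) sub("_p[STY].*$", "", ids)

analyte_gene_map <- function(m) {
  if (!is.null(m$analyte_gene)) return(m$analyte_gene)
  ids <- analyte_ids(m)
  if (m$layer == "phospho")
    return(stats::setNames(phospho_gene(ids), ids))
  if (m$layer == "mrna") return(stats::setNames(ids, ids))
  stats::setNames(ids, ids)
}

#' Match two layers on shared cell lines (and optionally genes)
#'
#' Restricts both matrices to the intersection of their cell ids, in
#' identical order. With `by = "gene"` the rows are additionally paired
#' through the antibody-to-gene map: each analyte of `a` whose mapped gene
#' is present among the analytes of `b` yields one row pair (many-to-one
#' mapping allowed, so several phospho-antibodies may pair with one mRNA
#' row); analytes without a mapping or without a partner are dropped and
#' their count reported via a message.
#'
#' @param a,b `expr_matrix` objects.
#' @param ann optional annotation data.frame; returned restricted to the
#'   shared cells.
#' @param by `"cell"` (default) or `"gene"`.
#' @return list with elements `a`, `b` (aligned `expr_matrix`), `ann`, and
#'   for gene matching `pairs` (data.frame `analyte_a`, `gene`,
#'   `analyte_b`, row-aligned with `a` and `b`).
#' @export
match_layers <- function(a, b, ann = NULL, by = c("cell", "gene")) {
  by <- match.arg(by)
  shared <- intersect(cell_ids(a), cell_ids(b))
  if (!is.null(ann)) shared <- intersect(shared, ann$cell_line)
  if (length(shared) == 0L) stopf("no shared cell ids between layers")
  a$values <- a$values[, shared, drop = FALSE]
  b$values <- b$values[, shared, drop = FALSE]
  out <- list(a = a, b = b)
  if (!is.null(ann))
    out$ann <- ann[match(shared, ann$cell_line), , drop = FALSE]
  if (by == "gene") {
    map <- analyte_gene_map(a)
    genes <- map[analyte_ids(a)]
    unmapped <- sum(is.na(genes))
    hit <- !is.na(genes) & genes %in% analyte_ids(b)
    if (unmapped > 0L || any(!hit))
      message(sprintf(
        "match_layers: dropped %d analytes without gene mapping and %d without partner in '%s'",
        unmapped, sum(!hit) - unmapped, b$layer))
    if (!any(hit)) stopf("no gene-matched analyte pairs")
    out$pairs <- data.frame(analyte_a = analyte_ids(a)[hit],
                            gene = unname(genes[hit]),
                            analyte_b = unname(genes[hit]),
                            stringsAsFactors = FALSE)
    out$a$values <- a$values[out$pairs$analyte_a, , drop = FALSE]
    bv <- b$values[out$pairs$analyte_b, , drop = FALSE]
    # rows are keyed by the antibody id so many-to-one pairs stay unique;
    # the mRNA row actually used is recorded in pairs$analyte_b
    rownames(bv) <- out$pairs$analyte_a
    out$b$values <- bv
  }
  out
}
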