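#' Bimodal coupling coefficient between two posterior vectors
#'
#' `r_b` is the Spearman correlation (average ranks for ties) between two
#' analytes' per-cell posterior probabilities of the high mixture
#' component, computed over the pairwise-complete cells. The p-value uses
#' the large-sample t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Pairs with fewer than `min_overlap` complete cells are not tested.
#'
#' @param pA,pB posterior vectors aligned on the same cell axis.
#' @param min_overlap minimum number of shared non-missing cells
#'   (default 30).
#' @return list with `r_b`, `n_overlap`, `p_value`, `tested` (FALSE when
#'   overlap is insufficient or a rank vector is constant, in which case
#'   `r_b` is NA).
#' @export
coupling_coefficient <- function(pA, pB, min_overlap = 30L) {
  if (length(pA) != length(pB)) stopf("posterior vectors must be aligned")
  ok <- !is.na(pA) & !is.na(pB)
  n <- sum(ok)
  if (n < min_overlap)
    return(list(r_b = NA_real_, n_overlap = n, p_value = NA_real_,
                tested = FALSE))
  ra <- rank(pA[ok]); rb <- rank(pB[ok])
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    return(list(r_b = NA_real_, n_overlap = n, p_value = NA_real_,
                tested = FALSE))
  r <- stats::cor(ra, rb)
  p <- if (abs(r) >= 1) 0 else {
    tv <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tv), df = n - 2)
  }
  list(r_b = r, n_overlap = n, p_value = p, tested = TRUE)
}

#' Coupling coefficients for many analyte pairs
#'
#' Computes `r_b` either for explicitly paired rows (`matched-gene`
#' pairing, e.g. the mRNA/protein pairs produced by
#' [match_layers()] with `by = "gene"`) or for the full cross table of two
#' posterior matrices (`all-pairs`; when `post_b` is omitted, all unordered
#' pairs within `post_a`).
#'
#' @param post_a,post_b posterior matrices (analytes x cells) on a common
#'   cell axis; rows of `post_b` default to `post_a`.
#' @param pairing `"matched-gene"` or `"all-pairs"`.
#' @param pairs for matched-gene pairing, a data.frame with columns
#'   `analyte_a`, `analyte_b`; defaults to rows sharing the same id.
#' @param min_overlap passed to [coupling_coefficient()].
#' @return data.frame with columns `analyte_a`, `analyte_b`, `r_b`,
#'   `n_overlap`, `p_value`.
#' @export
coupling_matrix <- function(post_a, post_b = NULL,
                            pairing = c("matched-gene", "all-pairs"),
                            pairs = NULL, min_overlap = 30L) {
  pairing <- match.arg(pairing)
  within <- is.null(post_b) && pairing == "all-pairs"
  if (is.null(post_b)) post_b <- post_a
  if (ncol(post_a) != ncol(post_b))
    stopf("posterior matrices must share the cell axis")
  if (pairing == "matched-gene") {
    if (is.null(pairs)) {
      shared <- intersect(rownames(post_a), rownames(post_b))
      pairs <- data.frame(analyte_a = shared, analyte_b = shared,
                          stringsAsFactors = FALSE)
    }
    if (nrow(pairs) == 0L) stopf("empty pairing")
    idx <- cbind(match(pairs$analyte_a, rownames(post_a)),
                 match(pairs$analyte_b, rownames(post_b)))
  } else {
    if (within) {
      cmb <- utils::combn(nrow(post_a), 2L)
      idx <- cbind(cmb[1L, ], cmb[2L, ])
    } else {
      idx <- as.matrix(expand.grid(seq_len(nrow(post_a)),
                                   seq_len(nrow(post_b))))
    }
  }
  res <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    cc <- coupling_coefficient(post_a[idx[k, 1L], ], post_b[idx[k, 2L], ],
                               min_overlap = min_overlap)
    res[[k]] <- data.frame(analyte_a = rownames(post_a)[idx[k, 1L]],
                           analyte_b = rownames(post_b)[idx[k, 2L]],
                           r_b = cc$r_b, n_overlap = cc$n_overlap,
                           p_value = cc$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build the thresholded, significance-filtered coupling network
#'
#' Adjusts the p-values of all *tested* pairs (Bonferroni family-wise
#' control by default, Benjamini-Hochberg optional) and keeps edges with
#' `|r_b| > r_threshold` (strict) and adjusted p below `alpha`. Nodes are
#' all supplied analytes, so isolated nodes are retained. Callers are
#' expected to restrict the input to bimodal, high-diversity analytes
#' (see [classify_switches()]).
#'
#' @param edges edge table from [coupling_matrix()].
#' @param r_threshold absolute coupling cutoff (default 0.3).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param correction `"bonferroni"` or `"BH"`.
#' @param nodes optional character vector of node ids (defaults to every
#'   analyte appearing in `edges`).
#' @param node_attrs optional data.frame of per-node attributes with an
#'   `analyte` column (e.g. `pi_high`, `switch_class`).
#' @return An object of class `coupling_network`: list with `graph`
#'   (igraph, undirected, edge attributes `r_b`, `p_value`, `p_adjusted`),
#'   `edges` (kept edges incl. `p_adjusted`), `edges_tested` (all tested
#'   edges with adjusted p), `nodes`.
#' @export
build_network <- function(edges, r_threshold = 0.3, alpha = 0.05,
                          correction = c("bonferroni", "BH"),
                          nodes = NULL, node_attrs = NULL) {
  correction <- match.arg(correction)
  tested <- edges[!is.na(edges$r_b) & !is.na(edges$p_value), , drop = FALSE]
  tested$p_adjusted <- stats::p.adjust(tested$p_value, method = correction)
  keep <- tested[abs(tested$r_b) > r_threshold &
                   tested$p_adjusted < alpha, , drop = FALSE]
  nodes <- nodes %||% unique(c(edges$analyte_a, edges$analyte_b))
  g <- igraph::graph_from_data_frame(
    keep[, c("analyte_a", "analyte_b", "r_b", "p_value", "p_adjusted")],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  if (!is.null(node_attrs)) {
    ix <- match(nodes, node_attrs$analyte)
    for (col in setdiff(names(node_attrs), "analyte"))
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][ix])
  }
  structure(list(graph = g, edges = keep, edges_tested = tested,
                 nodes = nodes),
            class = "coupling_network")
}

#' @export
print.coupling_network <- function(x, ...) {
  cat(sprintf("coupling_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Leading-eigenvector community detection on the coupling network
#'
#' Runs Newman's leading-eigenvector modularity method on the *unweighted*
#' adjacency (the network is already thresholded on `|r_b|`; negative
#' couplings enter as unsigned edges). Isolated nodes become singleton
#' communities. The eigen solver is seeded internally so memberships are
#' deterministic.
#'
#' @param net a `coupling_network`.
#' @return named integer vector: node -> community id.
#' @export
detect_communities <- function(net) {
  with_seed(1L, {
    cl <- igraph::cluster_leading_eigen(net$graph, weights = NA)
  })
  memb <- igraph::membership(cl)
  stats::setNames(as.integer(memb), names(memb))
}
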