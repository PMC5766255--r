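# Score-based causal structure learning over analytes.
#
# The local score of node v with parent set P is the penalised Gaussian
# log-likelihood
#   S(v | P) = -(n/2) * ln(RSS_v / n) - c * (|P| + 1) * ln(n) / 2
# with c the penalty discount; c = 1 recovers BIC/2 up to constants, the
# pipeline default c = 4 yields sparser graphs. All scores are computed
# from the centred scatter matrix, so the search never touches the raw
# data after initialisation.

local_score <- function(C, n, v, parents, c) {
  rss <- if (length(parents) == 0L) C[v, v] else {
    C[v, v] - drop(crossprod(C[parents, v],
                             solve(C[parents, parents, drop = FALSE],
                                   C[parents, v])))
  }
  rss <- max(rss, 1e-12)
  -(n / 2) * log(rss / n) - c * (length(parents) + 1) * log(n) / 2
}

# is there a directed path from a to b? (adjacency list of children)
has_path <- function(children, a, b) {
  seen <- logical(length(children))
  stack <- a
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v == b) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, children[[v]])
  }
  FALSE
}

#' Greedy penalised-score search for a causal network
#'
#' Two-phase score-based structure search with the penalised Gaussian
#' score (see source header): the forward phase repeatedly adds the
#' single edge with the largest score improvement, subject to acyclicity
#' and to `depth` (the largest parent set considered jointly when
#' re-evaluating a node's local score); the backward phase greedily
#' deletes edges while the total score improves. The resulting DAG is
#' reported as its pattern (CPDAG): compelled edges directed, reversible
#' edges undirected.
#'
#' Because the search walks DAG space, the gain of adding `x -> y` ties
#' (up to float noise) with `y -> x` whenever neither node has parents
#' yet; committing to an arbitrary orientation can strand the search in a
#' triangle-completing local optimum around colliders. The search
#' therefore runs `n_restarts` passes with randomized tie-breaking among
#' score-equivalent moves and returns the best-scoring result (the first
#' pass breaks ties deterministically, so `n_restarts = 1` is fully
#' greedy).
#'
#' @param data cells x analytes numeric matrix, no missing values (use
#'   coverage filtering / imputation first).
#' @param penalty_discount multiplier `c` on the BIC complexity penalty
#'   (default 4).
#' @param depth maximum parent-set size explored (default 3).
#' @param n_restarts search passes with randomized tie-breaking.
#' @param seed integer seed for the tie-breaking stream (local RNG).
#' @return An object of class `causal_graph`: list with `nodes`, `edges`
#'   (data.frame `from`, `to`, `orientation` in directed/undirected),
#'   `dag` (one score-maximising DAG of the class), `score`, `params`.
#' @export
greedy_search <- function(data, penalty_discount = 4, depth = 3L,
                          n_restarts = 5L, seed = 1L) {
  data <- as.matrix(data)
  if (anyNA(data)) stopf("greedy_search requires complete data")
  nodes <- colnames(data) %||% paste0("V", seq_len(ncol(data)))
  colnames(data) <- nodes
  sds <- apply(data, 2L, stats::sd)
  if (any(sds == 0))
    stopf("constant analyte: %s", nodes[which(sds == 0)][1L])
  n <- nrow(data); p <- ncol(data)
  if (n <= p) warnf("fewer samples (%d) than analytes (%d)", n, p)
  depth <- assert_count(depth, "depth")
  C <- crossprod(scale(data, center = TRUE, scale = FALSE))
  cc <- penalty_discount
  n_restarts <- assert_count(n_restarts, "n_restarts")

  run_search <- function(jitter) {
    parents <- rep(list(integer(0)), p)
    children <- rep(list(integer(0)), p)
    sc <- vapply(seq_len(p), function(v) local_score(C, n, v, integer(0), cc),
                 0)
    gain_col <- function(y) {
      # gain[x, y]: score change of adding x -> y given current Pa(y);
      # NA = structurally ineligible
      g <- rep(NA_real_, p)
      if (length(parents[[y]]) >= depth) return(g)
      base <- sc[y]
      for (x in seq_len(p)) {
        if (x == y || x %in% parents[[y]] || y %in% parents[[x]]) next
        g[x] <- local_score(C, n, y, c(parents[[y]], x), cc) - base
      }
      g
    }
    gain <- vapply(seq_len(p), gain_col, numeric(p))

    repeat { # forward
      cand <- which(!is.na(gain) & gain > 1e-10)
      if (length(cand) == 0L) break
      # score-equivalent orientations tie up to float noise; quantize so
      # jittered runs can explore either orientation
      key <- signif(gain[cand], 6)
      ord <- if (jitter) cand[order(-key, stats::runif(length(cand)))]
             else cand[order(-key, cand)]
      accepted <- FALSE
      for (k in ord) {
        x <- (k - 1L) %% p + 1L
        y <- (k - 1L) %/% p + 1L
        if (has_path(children, y, x)) next # would create a cycle
        parents[[y]] <- c(parents[[y]], x)
        children[[x]] <- c(children[[x]], y)
        sc[y] <- sc[y] + gain[k]
        gain[, y] <- gain_col(y)
        accepted <- TRUE
        break
      }
      if (!accepted) break
    }

    repeat { # backward
      best <- NULL; bestd <- 1e-10
      for (y in seq_len(p)) {
        for (x in parents[[y]]) {
          d <- local_score(C, n, y, setdiff(parents[[y]], x), cc) - sc[y]
          if (d > bestd) { bestd <- d; best <- c(x, y) }
        }
      }
      if (is.null(best)) break
      x <- best[1L]; y <- best[2L]
      parents[[y]] <- setdiff(parents[[y]], x)
      children[[x]] <- setdiff(children[[x]], y)
      sc[y] <- sc[y] + bestd
    }
    list(parents = parents, score = sum(sc), sc = sc)
  }

  best <- with_seed(seed, {
    res <- run_search(jitter = FALSE)
    for (r in seq_len(n_restarts - 1L)) {
      alt <- run_search(jitter = TRUE)
      if (alt$score > res$score + 1e-9) res <- alt
    }
    res
  })
  parents <- best$parents
  sc <- best$sc

  dag <- do.call(rbind, lapply(seq_len(p), function(y)
    if (length(parents[[y]]))
      data.frame(from = nodes[parents[[y]]], to = nodes[y],
                 stringsAsFactors = FALSE)))
  if (is.null(dag))
    dag <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  edges <- dag_to_pattern(parents, nodes)
  structure(list(nodes = nodes, edges = edges, dag = dag,
                 score = sum(sc),
                 params = list(penalty_discount = penalty_discount,
                               depth = depth, n = n)),
            class = "causal_graph")
}

# Chickering's order-and-label algorithm: compelled vs reversible edges
# of the equivalence class of a DAG given as a parent list.
dag_to_pattern <- function(parents, nodes) {
  p <- length(parents)
  nedge <- sum(lengths(parents))
  if (nedge == 0L)
    return(data.frame(from = character(), to = character(),
                      orientation = character(), stringsAsFactors = FALSE))
  # topological order
  indeg <- lengths(parents)
  children <- rep(list(integer(0)), p)
  for (y in seq_len(p)) for (x in parents[[y]])
    children[[x]] <- c(children[[x]], y)
  topo <- integer(0)
  avail <- which(indeg == 0L)
  indeg2 <- indeg
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    topo <- c(topo, v)
    for (w in children[[v]]) {
      indeg2[w] <- indeg2[w] - 1L
      if (indeg2[w] == 0L) avail <- c(avail, w)
    }
  }
  rank <- integer(p); rank[topo] <- seq_len(p)
  # order edges: by topological rank of the child, then by *descending*
  # rank of the parent
  el <- do.call(rbind, lapply(seq_len(p), function(y)
    if (length(parents[[y]])) cbind(parents[[y]], y)))
  ord <- order(rank[el[, 2L]], -rank[el[, 1L]])
  el <- el[ord, , drop = FALSE]
  lab <- rep(NA_character_, nrow(el)) # "compelled" / "reversible"
  eid <- function(x, y) which(el[, 1L] == x & el[, 2L] == y)
  while (anyNA(lab)) {
    i <- which(is.na(lab))[1L]
    x <- el[i, 1L]; y <- el[i, 2L]
    done <- FALSE
    for (w in parents[[x]]) {
      if (lab[eid(w, x)] %in% "compelled") {
        if (!(w %in% parents[[y]])) {
          lab[el[, 2L] == y] <- "compelled"
          done <- TRUE
          break
        } else lab[eid(w, y)] <- "compelled"
      }
    }
    if (done) next
    zs <- setdiff(parents[[y]], x)
    if (any(!(zs %in% c(parents[[x]], x)) & zs != x)) {
      sel <- el[, 2L] == y & is.na(lab)
      lab[sel] <- "compelled"
      lab[i] <- "compelled"
    } else {
      sel <- el[, 2L] == y & is.na(lab)
      lab[sel] <- "reversible"
      lab[i] <- "reversible"
    }
  }
  out <- data.frame(from = nodes[el[, 1L]], to = nodes[el[, 2L]],
                    orientation = ifelse(lab == "compelled", "directed",
                                         "undirected"),
                    stringsAsFactors = FALSE)
  # canonical order for undirected edges
  sw <- out$orientation == "undirected" & out$from > out$to
  tmp <- out$from[sw]; out$from[sw] <- out$to[sw]; out$to[sw] <- tmp
  rownames(out) <- NULL
  out
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf(
    "causal_graph: %d nodes, %d edges (%d directed), score %.2f\n",
    length(x$nodes), nrow(x$edges),
    sum(x$edges$orientation == "directed"), x$score))
  invisible(x)
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Bootstrap ensemble of causal networks
#'
#' Resamples cells with replacement `M` times, reruns [greedy_search()]
#' on each replicate and accumulates, per node pair, the fraction of
#' replicates containing the edge in any orientation and in each specific
#' orientation. Replicates that fail (e.g. a resampled constant column)
#' are skipped and logged; at least 90% of `M` must succeed.
#'
#' @param data cells x analytes matrix, complete.
#' @param M number of replicates (pipeline default 200).
#' @param seed integer seed.
#' @param penalty_discount,depth passed to [greedy_search()].
#' @return An object of class `bootstrap_ensemble`: list with `M`,
#'   `n_success`, `edge_freq` (data.frame `a`, `b`, `freq_any`,
#'   `freq_a_to_b`, `freq_b_to_a`, `freq_undirected`),
#'   `avg_connectivity`, `nodes`.
#' @export
bootstrap_ensemble <- function(data, M = 200L, seed = 1L,
                               penalty_discount = 4, depth = 3L) {
  data <- as.matrix(data)
  M <- assert_count(M, "M")
  nodes <- colnames(data) %||% paste0("V", seq_len(ncol(data)))
  colnames(data) <- nodes
  counts <- new.env(parent = emptyenv())
  nedges <- integer(0)
  nfail <- 0L
  with_seed(seed, {
    for (m in seq_len(M)) {
      ix <- sample.int(nrow(data), nrow(data), replace = TRUE)
      g <- tryCatch(greedy_search(data[ix, , drop = FALSE],
                                  penalty_discount = penalty_discount,
                                  depth = depth),
                    error = function(e) NULL)
      if (is.null(g)) { nfail <- nfail + 1L; next }
      nedges <- c(nedges, nrow(g$edges))
      if (nrow(g$edges)) {
        keys <- edge_key(g$edges$from, g$edges$to)
        for (j in seq_len(nrow(g$edges))) {
          k <- keys[j]
          cur <- counts[[k]] %||% c(any = 0, fwd = 0, rev = 0, und = 0)
          cur["any"] <- cur["any"] + 1
          e <- g$edges[j, ]
          if (e$orientation == "undirected") cur["und"] <- cur["und"] + 1
          else if (e$from <= e$to) cur["fwd"] <- cur["fwd"] + 1
          else cur["rev"] <- cur["rev"] + 1
          counts[[k]] <- cur
        }
      }
    }
  })
  nsucc <- M - nfail
  if (nfail > 0L)
    message(sprintf("bootstrap_ensemble: %d of %d replicates failed",
                    nfail, M))
  if (nsucc < 0.9 * M)
    stopf("too many failed replicates (%d of %d)", nfail, M)
  keys <- ls(counts)
  ef <- if (length(keys)) {
    ab <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    cm <- t(vapply(keys, function(k) counts[[k]], numeric(4)))
    data.frame(a = ab[, 1L], b = ab[, 2L],
               freq_any = cm[, "any"] / nsucc,
               freq_a_to_b = cm[, "fwd"] / nsucc,
               freq_b_to_a = cm[, "rev"] / nsucc,
               freq_undirected = cm[, "und"] / nsucc,
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(a = character(), b = character(), freq_any = numeric(),
                    freq_a_to_b = numeric(), freq_b_to_a = numeric(),
                    freq_undirected = numeric(), stringsAsFactors = FALSE)
  structure(list(M = M, n_success = nsucc, edge_freq = ef,
                 avg_connectivity = if (length(nedges)) mean(nedges) else 0,
                 nodes = nodes),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf(
    "bootstrap_ensemble: M=%d (%d ok), %d edges seen, avg connectivity %.1f\n",
    x$M, x$n_success, nrow(x$edge_freq), x$avg_connectivity))
  invisible(x)
}

causal_igraph <- function(g) {
  dir <- g$edges[g$edges$orientation == "directed", , drop = FALSE]
  und <- g$edges[g$edges$orientation == "undirected", , drop = FALSE]
  el <- rbind(dir[, c("from", "to")],
              und[, c("from", "to")],
              stats::setNames(und[, c("to", "from")], c("from", "to")))
  igraph::graph_from_data_frame(el, directed = TRUE,
                                vertices = data.frame(name = g$nodes))
}

#' Node centralities of a causal graph
#'
#' Betweenness is computed on the directed graph with unit edge lengths
#' (undirected pattern edges enter as reciprocal arcs); subgraph
#' centrality is the diagonal of the matrix exponential of the undirected
#' adjacency; in/out degree count directed (compelled) edges only.
#'
#' @param g a `causal_graph`.
#' @return data.frame `node`, `betweenness`, `subgraph_centrality`,
#'   `in_degree`, `out_degree`.
#' @export
centralities <- function(g) {
  ig <- causal_igraph(g)
  btw <- igraph::betweenness(ig, directed = TRUE)
  A <- matrix(0, length(g$nodes), length(g$nodes),
              dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    A[cbind(g$edges$from, g$edges$to)] <- 1
    A[cbind(g$edges$to, g$edges$from)] <- 1
  }
  ev <- eigen(A, symmetric = TRUE)
  subc <- rowSums(ev$vectors^2 %*% diag(exp(ev$values), nrow(A)))
  dir <- g$edges[g$edges$orientation == "directed", , drop = FALSE]
  indeg <- table(factor(dir$to, g$nodes))
  outdeg <- table(factor(dir$from, g$nodes))
  data.frame(node = g$nodes,
             betweenness = as.numeric(btw[g$nodes]),
             subgraph_centrality = subc,
             in_degree = as.integer(indeg[g$nodes]),
             out_degree = as.integer(outdeg[g$nodes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Causal neighbourhood of target analytes with tissue-wise correlations
#'
#' Extracts the induced subgraph on the targets and their first
#' neighbours (any edge orientation) and, for every edge of that
#' subgraph, the Pearson correlation of the two analytes within each
#' tissue contributing at least `min_tissue_cells` cells with both values
#' observed.
#'
#' @param g a `causal_graph`.
#' @param targets character vector of analyte ids present in `g`.
#' @param data cells x analytes matrix (missing allowed) used for the
#'   correlations.
#' @param tissues per-cell tissue labels aligned with `data` rows.
#' @param min_tissue_cells minimum complete cells per tissue (default 10).
#' @return list with `nodes`, `edges` (subgraph edge table) and
#'   `tissue_cor` (data.frame `from`, `to`, `tissue`, `n`, `r`).
#' @export
causal_neighborhood <- function(g, targets, data = NULL, tissues = NULL,
                                min_tissue_cells = 10L) {
  unknown <- setdiff(targets, g$nodes)
  if (length(unknown)) stopf("unknown target: %s", unknown[1L])
  touch <- g$edges$from %in% targets | g$edges$to %in% targets
  nbrs <- unique(c(targets, g$edges$from[touch], g$edges$to[touch]))
  sub <- g$edges[g$edges$from %in% nbrs & g$edges$to %in% nbrs, ,
                 drop = FALSE]
  out <- list(nodes = nbrs, edges = sub)
  if (!is.null(data) && !is.null(tissues) && nrow(sub)) {
    tc <- list()
    for (j in seq_len(nrow(sub))) {
      a <- sub$from[j]; b <- sub$to[j]
      for (tis in unique(tissues)) {
        sel <- tissues == tis & !is.na(data[, a]) & !is.na(data[, b])
        if (sum(sel) < min_tissue_cells) next
        tc[[length(tc) + 1L]] <- data.frame(
          from = a, to = b, tissue = tis, n = sum(sel),
          r = stats::cor(data[sel, a], data[sel, b]),
          stringsAsFactors = FALSE)
      }
    }
    out$tissue_cor <- if (length(tc)) do.call(rbind, tc) else
      data.frame(from = character(), to = character(), tissue = character(),
                 n = integer(), r = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Compare two bootstrap ensembles by edge frequency
#'
#' Correlates the `freq_any` edge frequencies of two ensembles over the
#' union of edges present in either, restricted to node pairs within the
#' shared node set (edges absent from one ensemble contribute 0).
#'
#' @param eA,eB `bootstrap_ensemble` objects with overlapping node sets.
#' @return list with `pearson`, `spearman`, `n_edges`, `table` (the
#'   merged frequency table).
#' @export
compare_ensembles <- function(eA, eB) {
  shared <- intersect(eA$nodes, eB$nodes)
  if (length(shared) == 0L) stopf("no shared nodes")
  fa <- eA$edge_freq[eA$edge_freq$a %in% shared & eA$edge_freq$b %in% shared, ]
  fb <- eB$edge_freq[eB$edge_freq$a %in% shared & eB$edge_freq$b %in% shared, ]
  keys <- union(edge_key(fa$a, fa$b), edge_key(fb$a, fb$b))
  if (length(keys) == 0L)
    return(list(pearson = NA_real_, spearman = NA_real_, n_edges = 0L,
                table = NULL))
  va <- stats::setNames(rep(0, length(keys)), keys)
  vb <- va
  va[edge_key(fa$a, fa$b)] <- fa$freq_any
  vb[edge_key(fb$a, fb$b)] <- fb$freq_any
  ok <- length(keys) > 1L && stats::sd(va) > 0 && stats::sd(vb) > 0
  list(pearson = if (ok) stats::cor(va, vb) else NA_real_,
       spearman = if (ok) stats::cor(va, vb, method = "spearman")
                  else NA_real_,
       n_edges = length(keys),
       table = data.frame(edge = keys, freq_a = as.numeric(va),
                          freq_b = as.numeric(vb),
                          stringsAsFactors = FALSE))
}
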