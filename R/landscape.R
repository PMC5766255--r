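#' Pairwise-complete Euclidean distances between cell lines
#'
#' `d[i, j]` is the plain Euclidean distance computed over the features
#' (analytes) observed in both cells; no rescaling by the number of shared
#' features is applied by default (set `rescale = TRUE` to multiply each
#' squared distance by `n_features / n_shared`, which removes the bias of
#' unequal feature counts). Pairs sharing fewer than `min_complete`
#' features are missing.
#'
#' @param m an [expr_matrix()] (or a plain analytes x cells matrix).
#' @param min_complete minimum number of shared features per pair.
#' @param rescale rescale squared distances to the full feature count.
#' @return An object of class `dist_matrix`: list with `d` (symmetric
#'   matrix, zero diagonal), `n_features_used`, `cell_ids`.
#' @export
pairwise_distance <- function(m, min_complete = 1L, rescale = FALSE) {
  x <- if (inherits(m, "expr_matrix")) m$values else m
  if (is.null(colnames(x))) colnames(x) <- paste0("cell", seq_len(ncol(x)))
  obs <- !is.na(x)
  empty <- colSums(obs) == 0L
  if (any(empty))
    warnf("pairwise_distance: %d cells have no observed features",
          sum(empty))
  x0 <- x; x0[!obs] <- 0
  mm <- obs * 1
  cross <- crossprod(x0)               # sum_f xi xj over shared features
  ps <- crossprod(x0^2, mm)            # sum_f xi^2 where xj observed
  nshared <- crossprod(mm)
  d2 <- ps + t(ps) - 2 * cross
  d2[d2 < 0] <- 0                      # numerical noise
  if (rescale) d2 <- d2 * nrow(x) / nshared
  d2[nshared < min_complete] <- NA
  d <- sqrt(d2)
  diag(d) <- 0
  structure(list(d = d, n_features_used = nshared, cell_ids = colnames(x)),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d cells (%.1f%% pairs missing)\n",
              length(x$cell_ids), 100 * mean(is.na(x$d))))
  invisible(x)
}

#' Combine two distance matrices with equal total weight
#'
#' Each matrix is divided by the sum of its non-missing entries before
#' adding, so both data types contribute equally regardless of scale:
#' `combined = d1/S1 + d2/S2`. Pairs missing in either input are missing.
#'
#' @param d1,d2 `dist_matrix` objects over identical cell axes.
#' @return combined `dist_matrix`.
#' @export
combine_distances <- function(d1, d2) {
  if (!identical(d1$cell_ids, d2$cell_ids))
    stopf("distance matrices must share the cell axis")
  s1 <- sum(d1$d, na.rm = TRUE)
  s2 <- sum(d2$d, na.rm = TRUE)
  if (s1 == 0 || s2 == 0) stopf("zero total distance")
  d <- d1$d / s1 + d2$d / s2
  structure(list(d = d,
                 n_features_used = pmin(d1$n_features_used,
                                        d2$n_features_used),
                 cell_ids = d1$cell_ids),
            class = "dist_matrix")
}

#' Leave-one-out k-nearest-neighbour tissue classification
#'
#' Each cell is classified by majority vote among its `k` nearest other
#' cells (ties broken by the class of the nearest neighbour among the tied
#' classes). Cells with no finite distance to any other cell are excluded
#' with a warning.
#'
#' @param d a `dist_matrix`.
#' @param tissues per-cell tissue labels aligned with `d$cell_ids`.
#' @param k neighbourhood size (default 3).
#' @return list with `accuracy`, `confusion` (true x predicted counts),
#'   `predictions` (data.frame `cell`, `tissue`, `predicted`).
#' @export
knn_loocv_tissue <- function(d, tissues, k = 3L) {
  n <- length(d$cell_ids)
  if (n < k + 1L) stopf("need at least k+1 cells")
  if (length(tissues) != n) stopf("tissues must align with cells")
  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    di <- d$d[i, ]; di[i] <- NA
    ok <- which(!is.na(di))
    if (length(ok) == 0L) next
    nb <- ok[order(di[ok])][seq_len(min(k, length(ok)))]
    votes <- table(tissues[nb])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1L) top else {
      # nearest neighbour among tied classes decides
      tissues[nb[tissues[nb] %in% top][1L]]
    }
  }
  excl <- is.na(pred)
  if (any(excl))
    warnf("knn_loocv_tissue: %d cells excluded (no finite distances)",
          sum(excl))
  acc <- mean(pred[!excl] == tissues[!excl])
  conf <- table(true = tissues[!excl], predicted = pred[!excl])
  list(accuracy = acc, confusion = conf,
       predictions = data.frame(cell = d$cell_ids, tissue = tissues,
                                predicted = pred, stringsAsFactors = FALSE))
}

# within-cluster dispersion W_k of Tibshirani's Gap statistic:
# sum over clusters of (pairwise squared distances) / (2 n_r)
gap_wk <- function(d2, cl) {
  w <- 0
  for (g in unique(cl)) {
    ix <- which(cl == g)
    if (length(ix) > 1L) w <- w + sum(d2[ix, ix]) / (2 * length(ix))
  }
  w
}

#' Gap statistic over average-linkage tree cuts
#'
#' Cuts the average-linkage hierarchical clustering of the data into
#' `k = 1..k_max` clusters and compares `ln W_k` (within-cluster sum of
#' pairwise squared distances, normalised per cluster size) with its
#' expectation under `B` uniform reference datasets drawn over the
#' observed range of each feature. The chosen number of clusters is the
#' smallest `k` with `Gap(k) >= Gap(k+1) - s_{k+1}`.
#'
#' @param x cells x features numeric matrix, complete.
#' @param k_max largest number of clusters considered (>= 2).
#' @param B number of reference datasets (default 50).
#' @param seed integer seed for the reference draws.
#' @return list with `k` (chosen), `gap`, `s`, `logW`, `logW_ref`
#'   (B x k_max matrix of reference `ln W`).
#' @export
gap_statistic <- function(x, k_max, B = 50L, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("degenerate input: need at least 2 points")
  if (anyNA(x)) stopf("gap_statistic requires complete data")
  k_max <- assert_count(k_max, "k_max", min = 2L)
  ks <- seq_len(k_max)
  wk_of <- function(xx) {
    d2 <- as.matrix(stats::dist(xx))^2
    hc <- stats::hclust(stats::as.dist(sqrt(d2)), method = "average")
    vapply(ks, function(k) gap_wk(d2, stats::cutree(hc, k)), 0)
  }
  logW <- log(wk_of(x))
  rng <- apply(x, 2L, range)
  logW_ref <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      xr <- apply(rng, 2L, function(r) stats::runif(nrow(x), r[1L], r[2L]))
      log(wk_of(xr))
    }, numeric(k_max)))
  })
  gap <- colMeans(logW_ref) - logW
  s <- apply(logW_ref, 2L, stats::sd) * sqrt(1 + 1 / B)
  k <- k_max
  for (kk in seq_len(k_max - 1L)) {
    if (gap[kk] >= gap[kk + 1L] - s[kk + 1L]) { k <- kk; break }
  }
  list(k = k, gap = gap, s = s, logW = logW, logW_ref = logW_ref)
}

#' Regress one distance matrix on another and rank tissues by residual
#'
#' Ordinary least squares of the vectorised upper triangle of `d_target`
#' on that of `d_predictor` (pairs present in both). The residuals
#' quantify how much farther (or closer) two cell lines are in the target
#' layer than their distance in the predictor layer would predict. Tissues
#' are ranked by the mean residual of their within-tissue pairs.
#'
#' @param d_target,d_predictor `dist_matrix` objects on identical cells.
#' @param top_n how many highest/lowest residual pairs to report.
#' @param tissues optional per-cell tissue labels for the tissue ranking.
#' @return list with `residuals` (data.frame `cell_a`, `cell_b`,
#'   `d_target`, `d_pred`, `residual`), `top`, `bottom`, `fit`
#'   (coefficients), and `tissue_ranking` when tissues are given.
#' @export
distance_regression <- function(d_target, d_predictor, top_n = 100L,
                                tissues = NULL) {
  if (!identical(d_target$cell_ids, d_predictor$cell_ids))
    stopf("distance matrices must share the cell axis")
  n <- length(d_target$cell_ids)
  ut <- which(upper.tri(d_target$d), arr.ind = TRUE)
  y <- d_target$d[ut]; z <- d_predictor$d[ut]
  ok <- !is.na(y) & !is.na(z)
  if (sum(ok) < 10L) stopf("fewer than 10 shared pairs")
  if (stats::sd(z[ok]) == 0) stopf("constant predictor distances")
  fit <- stats::lm.fit(cbind(1, z[ok]), y[ok])
  res <- data.frame(cell_a = d_target$cell_ids[ut[ok, 1L]],
                    cell_b = d_target$cell_ids[ut[ok, 2L]],
                    d_target = y[ok], d_pred = z[ok],
                    residual = fit$residuals, stringsAsFactors = FALSE)
  ord <- order(res$residual, decreasing = TRUE)
  out <- list(residuals = res,
              top = res[ord[seq_len(min(top_n, nrow(res)))], ],
              bottom = res[rev(ord)[seq_len(min(top_n, nrow(res)))], ],
              fit = stats::setNames(fit$coefficients,
                                    c("intercept", "slope")))
  if (!is.null(tissues)) {
    ta <- tissues[match(res$cell_a, d_target$cell_ids)]
    tb <- tissues[match(res$cell_b, d_target$cell_ids)]
    within <- res[ta == tb, ]
    wt <- ta[ta == tb]
    mr <- tapply(within$residual, wt, mean)
    out$tissue_ranking <- data.frame(tissue = names(sort(mr,
                                                         decreasing = TRUE)),
                                     mean_residual = as.numeric(sort(mr,
                                                         decreasing = TRUE)),
                                     stringsAsFactors = FALSE)
  }
  out
}

# iterative rank-k SVD imputation (svdImpute-style)
svd_impute <- function(x, rank = 5L, tol = 1e-6, max_iter = 100L) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  mu <- colMeans(x, na.rm = TRUE)
  xi <- x
  for (j in seq_len(ncol(x))) xi[miss[, j], j] <- mu[j]
  rank <- min(rank, dim(x) - 1L)
  for (it in seq_len(max_iter)) {
    sv <- svd(xi, nu = rank, nv = rank)
    rec <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    delta <- max(abs(rec[miss] - xi[miss]), 0)
    xi[miss] <- rec[miss]
    if (delta < tol) break
  }
  xi
}

#' Two-dimensional embedding of the cell-line landscape
#'
#' Thin wrapper over standard implementations: `"pca"` centres and scales
#' each feature to unit variance (missing values imputed by iterative
#' rank-5 SVD) and returns the first two principal components; `"tsne"`
#' runs Barnes-Hut t-SNE with the given perplexity and iteration count on
#' the (SVD-imputed) data. Coordinates are deterministic given `seed`.
#'
#' @param x cells x features matrix (missing allowed).
#' @param method `"pca"` or `"tsne"`.
#' @param perplexity t-SNE perplexity (default 30).
#' @param iterations t-SNE iterations (default 5000).
#' @param seed integer seed.
#' @return data.frame `cell`, `x`, `y`.
#' @export
embed_cells <- function(x, method = c("pca", "tsne"), perplexity = 30,
                        iterations = 5000L, seed = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  cells <- rownames(x) %||% paste0("cell", seq_len(nrow(x)))
  xi <- svd_impute(x)
  keep <- apply(xi, 2L, stats::sd) > 0
  xi <- scale(xi[, keep, drop = FALSE])
  co <- with_seed(seed, {
    if (method == "pca") {
      pc <- stats::prcomp(xi, center = FALSE, scale. = FALSE)
      pc$x[, 1:2]
    } else {
      perplexity <- min(perplexity, floor((nrow(xi) - 1) / 3))
      Rtsne::Rtsne(xi, dims = 2L, perplexity = perplexity,
                   max_iter = as.integer(iterations),
                   check_duplicates = FALSE)$Y
    }
  })
  data.frame(cell = cells, x = co[, 1L], y = co[, 2L],
             stringsAsFactors = FALSE)
}
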