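#' Fit a two-component Gaussian mixture to one analyte by EM
#'
#' Fits `pi * N(mu_high, sigma_high^2) + (1 - pi) * N(mu_low, sigma_low^2)`
#' by expectation-maximization with restarts, and the one-component
#' Gaussian in closed form (sample mean, maximum-likelihood SD). Components
#' are relabeled so `mu_low <= mu_high`. BICs use
#' `BIC = k * ln(n) - 2 * loglik` with k = 2 (one component) and k = 5
#' (two components), so `delta_bic = bic1 - bic2 > 2` favours bimodality.
#'
#' The first restart is initialised from a 2-means partition of the
#' values; the remaining `n_restarts - 1` from random partitions. Component
#' variances are floored at `1e-3` times the sample variance to keep the
#' likelihood bounded. EM stops when the log-likelihood improves by less
#' than `1e-8` or after `max_iter` iterations; the best final
#' log-likelihood across restarts wins.
#'
#' @param x numeric vector of one analyte's measurements; NAs are allowed
#'   and propagate to the posteriors. At least 10 finite values and a
#'   positive sample SD are required.
#' @param n_restarts number of EM starts (default 10).
#' @param seed integer seed for the restarts (local RNG stream).
#' @param analyte_id optional id stored on the fit.
#' @param max_iter maximum EM iterations per restart.
#' @param tol absolute log-likelihood convergence tolerance.
#' @return An object of class `mixture_fit` with fields `mu_low`,
#'   `mu_high`, `sigma_low`, `sigma_high`, `pi_high`, `loglik2`, `loglik1`,
#'   `bic2`, `bic1`, `delta_bic`, `posteriors` (aligned with `x`, NA where
#'   `x` is missing), `n_used`, `converged`, `n_restarts_used`.
#' @export
fit_gmm2 <- function(x, n_restarts = 10L, seed = NULL, analyte_id = NA_character_,
                     max_iter = 1000L, tol = 1e-8) {
  ok <- is.finite(x)
  v <- x[ok]
  n <- length(v)
  if (n < 10L) stopf("degenerate analyte '%s': fewer than 10 finite values",
                     analyte_id)
  if (stats::sd(v) == 0) stopf("degenerate analyte '%s': constant input",
                               analyte_id)
  n_restarts <- assert_count(n_restarts, "n_restarts")

  # one-component model, closed form (MLE variance)
  mu0 <- mean(v)
  s0 <- sqrt(mean((v - mu0)^2))
  loglik1 <- sum(stats::dnorm(v, mu0, s0, log = TRUE))
  bic1 <- 2 * log(n) - 2 * loglik1

  floor_var <- 1e-3 * stats::var(v)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      z <- if (r == 1L) {
        km <- suppressWarnings(stats::kmeans(v, centers = 2L, nstart = 1L))
        as.numeric(km$cluster == which.max(km$centers))
      } else {
        zi <- stats::rbinom(n, 1L, 0.5)
        if (all(zi == zi[1L])) zi[sample.int(n, 1L)] <- 1L - zi[1L]
        as.numeric(zi)
      }
      fit <- .em_gmm2_cpp(v, z, floor_var, as.integer(max_iter), tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  # relabel so the "high" component has the larger mean
  if (best$mu[1L] > best$mu[2L]) {
    best$mu <- rev(best$mu); best$s2 <- rev(best$s2)
    best$pi2 <- 1 - best$pi2
    best$post <- 1 - best$post
  }
  posteriors <- rep(NA_real_, length(x))
  posteriors[ok] <- best$post
  structure(list(analyte_id = analyte_id,
                 mu_low = best$mu[1L], mu_high = best$mu[2L],
                 sigma_low = sqrt(best$s2[1L]), sigma_high = sqrt(best$s2[2L]),
                 pi_high = best$pi2,
                 loglik2 = best$loglik, loglik1 = loglik1,
                 bic2 = 5 * log(n) - 2 * best$loglik, bic1 = bic1,
                 delta_bic = bic1 - (5 * log(n) - 2 * best$loglik),
                 posteriors = posteriors, n_used = n,
                 converged = best$converged,
                 n_restarts_used = n_restarts),
            class = "mixture_fit")
}

# EM core: z is the initial responsibility of component 2 (the putative
# high component); returns unlabeled components.
em_gmm2 <- function(v, z, floor_var, max_iter, tol) {
  n <- length(v)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # M step
    w2 <- sum(z); w1 <- n - w2
    if (w2 < 1e-10 || w1 < 1e-10) { # collapsed component: reseed split
      z <- as.numeric(v > stats::median(v))
      w2 <- sum(z); w1 <- n - w2
    }
    mu1 <- sum((1 - z) * v) / w1
    mu2 <- sum(z * v) / w2
    s21 <- max(sum((1 - z) * (v - mu1)^2) / w1, floor_var)
    s22 <- max(sum(z * (v - mu2)^2) / w2, floor_var)
    pi2 <- w2 / n
    # E step (log space)
    l1 <- log1p(-pi2) - 0.5 * log(2 * pi * s21) - (v - mu1)^2 / (2 * s21)
    l2 <- log(pi2) - 0.5 * log(2 * pi * s22) - (v - mu2)^2 / (2 * s22)
    m <- pmax(l1, l2)
    lse <- m + log(exp(l1 - m) + exp(l2 - m))
    z <- exp(l2 - lse)
    ll <- sum(lse)
    if (is.finite(ll) && ll - ll_old < tol && it > 1L) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mu = c(mu1, mu2), s2 = c(s21, s22), pi2 = pi2, loglik = ll_old,
       post = z, converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit %s: mu %.3f/%.3f sd %.3f/%.3f pi_high %.3f dBIC %.2f (%s)\n",
    x$analyte_id, x$mu_low, x$mu_high, x$sigma_low, x$sigma_high,
    x$pi_high, x$delta_bic,
    if (is_bimodal(x)) "bimodal" else "unimodal"))
  invisible(x)
}

#' Bimodality call from a mixture fit
#'
#' An analyte is bimodal when the BIC difference between the one- and
#' two-component models exceeds 2 (strict: `delta_bic = 2` is unimodal).
#'
#' @param fit a `mixture_fit`.
#' @return logical flag.
#' @export
is_bimodal <- function(fit) {
  isTRUE(fit$delta_bic > 2)
}

#' Posterior probability of the high component
#'
#' Bayes' rule under the fitted mixture:
#' `p(x) = pi * phi(x; mu_high, sigma_high) / f(x)` with `f` the mixture
#' density. The probability of the low component is `1 - p`.
#'
#' @param fit a `mixture_fit`.
#' @param x numeric vector of measurement values.
#' @return vector of probabilities in \[0,1\] (NA where `x` is NA).
#' @export
posterior_high <- function(fit, x) {
  l2 <- log(fit$pi_high) +
    stats::dnorm(x, fit$mu_high, fit$sigma_high, log = TRUE)
  l1 <- log1p(-fit$pi_high) +
    stats::dnorm(x, fit$mu_low, fit$sigma_low, log = TRUE)
  m <- pmax(l1, l2)
  exp(l2 - (m + log(exp(l1 - m) + exp(l2 - m))))
}

#' Fit mixtures to every analyte of a layer
#'
#' Applies [fit_gmm2()] row-wise; analytes with fewer than `min_cells`
#' finite values or zero variance are skipped with a message. Restart
#' seeds are derived from `seed` per analyte so that the result does not
#' depend on fitting order.
#'
#' @param m an [expr_matrix()].
#' @param n_restarts,seed passed to [fit_gmm2()].
#' @param min_cells minimum coverage for an analyte to be fitted
#'   (default 40, the RPPA coverage filter).
#' @return named list of `mixture_fit` objects (class `mixture_fits`).
#' @export
fit_layer <- function(m, n_restarts = 10L, seed = 1L, min_cells = 40L) {
  ids <- analyte_ids(m)
  fits <- stats::setNames(vector("list", length(ids)), ids)
  skipped <- character(0)
  for (i in seq_along(ids)) {
    v <- m$values[i, ]
    if (sum(is.finite(v)) < max(10L, min_cells) ||
        stats::sd(v, na.rm = TRUE) == 0) {
      skipped <- c(skipped, ids[i])
      next
    }
    fits[[i]] <- fit_gmm2(v, n_restarts = n_restarts,
                          seed = if (is.null(seed)) NULL else seed + i,
                          analyte_id = ids[i])
  }
  if (length(skipped))
    message(sprintf("fit_layer: skipped %d low-coverage/degenerate analytes",
                    length(skipped)))
  structure(fits[!vapply(fits, is.null, TRUE)], class = "mixture_fits")
}

#' Posterior matrix from a set of fits
#'
#' @param fits a `mixture_fits` list.
#' @return matrix analytes x cells of posterior probabilities of the high
#'   component (NA where the measurement was missing).
#' @export
posterior_matrix <- function(fits) {
  do.call(rbind, lapply(fits, `[[`, "posteriors"))
}

#' Tidy per-analyte fit table
#'
#' @param fits a `mixture_fits` list.
#' @return data.frame, one row per fitted analyte.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(analyte = f$analyte_id, mu_low = f$mu_low, mu_high = f$mu_high,
               sigma_low = f$sigma_low, sigma_high = f$sigma_high,
               pi_high = f$pi_high, delta_bic = f$delta_bic,
               is_bimodal = is_bimodal(f), n_used = f$n_used,
               converged = f$converged, stringsAsFactors = FALSE)))
}

shannon_entropy <- function(labels) {
  q <- table(labels) / length(labels)
  q <- q[q > 0]
  -sum(q * log(q))
}

#' Tissue entropies of the low and high mixture components
#'
#' Cells are assigned to the low component when their posterior `p < 0.5`
#' and to the high component when `p >= 0.5`; the Shannon entropy (natural
#' log) of the tissue frequencies is computed within each group. Cells
#' with missing posterior are excluded. An empty group has entropy 0 (with
#' a warning): a switch populated from a single tissue side scores minimum
#' diversity either way.
#'
#' @param posteriors per-cell posterior probabilities of the high
#'   component.
#' @param tissues per-cell tissue labels, aligned with `posteriors`.
#' @return named numeric vector `c(entropy_low, entropy_high)`, in nats.
#' @export
tissue_entropy <- function(posteriors, tissues) {
  if (length(posteriors) != length(tissues))
    stopf("posteriors and tissues must be aligned")
  keep <- !is.na(posteriors)
  if (!any(keep)) stopf("all posteriors missing")
  p <- posteriors[keep]; tis <- tissues[keep]
  lo <- tis[p < 0.5]; hi <- tis[p >= 0.5]
  ent <- function(g, which) {
    if (length(g) == 0L) {
      warnf("tissue_entropy: empty %s group, entropy set to 0", which)
      return(0)
    }
    shannon_entropy(g)
  }
  c(entropy_low = ent(lo, "low"), entropy_high = ent(hi, "high"))
}

#' Classify bimodal switches by tissue diversity and balance
#'
#' For every fitted analyte: the bimodality flag, tissue entropies of the
#' low/high groups and their minimum, the tissue-diversity tertile of that
#' minimum (breakpoints computed over the bimodal analytes only; the low
#' tertile is the tissue-confounded stratum excluded downstream), and the
#' common/rare label: common when the minor mixing weight
#' `min(pi_high, 1 - pi_high)` exceeds 1/4, rare otherwise (boundary
#' exactly 1/4 is rare). Non-bimodal analytes get `switch_class = "none"`
#' and no tertile.
#'
#' @param fits a `mixture_fits` list.
#' @param tissues per-cell tissue labels aligned with the cells the fits
#'   were computed on.
#' @return data.frame with columns `analyte`, `is_bimodal`, `entropy_low`,
#'   `entropy_high`, `min_entropy`, `diversity_tertile`, `switch_class`.
#' @export
classify_switches <- function(fits, tissues) {
  tab <- lapply(fits, function(f) {
    bi <- is_bimodal(f)
    ent <- suppressWarnings(tissue_entropy(f$posteriors, tissues))
    data.frame(analyte = f$analyte_id, is_bimodal = bi,
               entropy_low = ent[["entropy_low"]],
               entropy_high = ent[["entropy_high"]],
               min_entropy = min(ent),
               minor_pi = min(f$pi_high, 1 - f$pi_high),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  nbi <- sum(tab$is_bimodal)
  if (nbi < 3L) stopf("need at least 3 bimodal analytes for tertiles, got %d",
                      nbi)
  br <- stats::quantile(tab$min_entropy[tab$is_bimodal], c(1, 2) / 3)
  tert <- rep(NA_character_, nrow(tab))
  tert[tab$is_bimodal] <- ifelse(
    tab$min_entropy[tab$is_bimodal] <= br[1L], "low",
    ifelse(tab$min_entropy[tab$is_bimodal] <= br[2L], "medium", "high"))
  tab$diversity_tertile <- tert
  tab$switch_class <- ifelse(!tab$is_bimodal, "none",
                             ifelse(tab$minor_pi > 0.25, "common", "rare"))
  tab$minor_pi <- NULL
  tab
}
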