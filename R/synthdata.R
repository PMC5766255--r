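#' Specify a planted bimodal switch module
#'
#' A switch is a latent binary state shared by all cells: with probability
#' `pi_high` a cell occupies the high state. Every member analyte (across
#' the requested layers) copies the module state with probability
#' `coupling_rho` and flips it otherwise, then draws its value from
#' `N(mu_low + state * delta_mu * sigma, sigma^2)`. `tissue_bias` replaces
#' the global `pi_high` with per-tissue probabilities, which creates the
#' tissue-confounded (low-diversity) switches the entropy filter is meant
#' to catch.
#'
#' @param id switch (module) id; doubles as the gene symbol linking layers.
#' @param layers subset of `c("protein","phospho","mrna")`.
#' @param pi_high probability of the high latent state, strictly in (0,1).
#' @param delta_mu separation of the component means in units of `sigma`
#'   (>= 0; 0 degenerates to a single Gaussian and is recorded as
#'   non-bimodal truth).
#' @param sigma within-component SD, > 0.
#' @param coupling_rho probability that a member analyte's state agrees
#'   with the module state, in \[0.5, 1\].
#' @param tissue_bias optional named numeric vector tissue -> P(high);
#'   tissues absent from the map fall back to `pi_high`.
#' @param n_analytes number of member analytes per layer: a single count
#'   or a named vector along `layers` (module size; planted community
#'   structure for the coupling network).
#' @param n_anti number of those members (per layer) that copy the
#'   *complement* of the module state with probability `coupling_rho`
#'   (anti-coupled members; the negative arm of a signature).
#' @param mu_low mean of the low component.
#' @return An object of class `switch_spec`.
#' @export
switch_spec <- function(id, layers = c("protein", "mrna"), pi_high = 0.5,
                        delta_mu = 4, sigma = 1, coupling_rho = 0.95,
                        tissue_bias = NULL, n_analytes = 1L, n_anti = 0L,
                        mu_low = 0) {
  layers <- match.arg(layers, LAYERS, several.ok = TRUE)
  if (!(pi_high > 0 && pi_high < 1)) stopf("pi_high must be in (0,1)")
  if (delta_mu < 0) stopf("delta_mu must be >= 0")
  if (sigma <= 0) stopf("sigma must be > 0")
  if (coupling_rho < 0.5 || coupling_rho > 1)
    stopf("coupling_rho must be in [0.5, 1]")
  if (length(n_analytes) == 1L && is.null(names(n_analytes)))
    n_analytes <- stats::setNames(rep(as.integer(n_analytes), length(layers)),
                                  layers)
  if (!all(layers %in% names(n_analytes)))
    stopf("n_analytes must name every layer of the switch")
  if (length(n_anti) == 1L && is.null(names(n_anti)))
    n_anti <- stats::setNames(rep(as.integer(n_anti), length(layers)), layers)
  if (any(n_anti[layers] > n_analytes[layers]))
    stopf("n_anti cannot exceed n_analytes")
  structure(list(id = id, layers = layers, pi_high = pi_high,
                 delta_mu = delta_mu, sigma = sigma,
                 coupling_rho = coupling_rho, tissue_bias = tissue_bias,
                 n_analytes = n_analytes, n_anti = n_anti, mu_low = mu_low),
            class = "switch_spec")
}

switch_analyte_ids <- function(sw, layer) {
  k <- sw$n_analytes[[layer]]
  base <- if (layer == "phospho") paste0(sw$id, "_pY", 100 + seq_len(k))
          else if (k == 1L) sw$id else paste0(sw$id, ".", seq_len(k))
  base
}

#' Simulate a matched multi-layer cell-line dataset with planted truth
#'
#' Generates one expression matrix per layer over a common cell-line axis
#' with tissue structure, planted bimodal switch modules
#' (see [switch_spec()]), additional unimodal analytes, and missingness
#' completely at random per layer. All randomness comes from `seed`;
#' the same seed reproduces the dataset bit-identically.
#'
#' Unimodal analytes are drawn `N(b_t, 1)` where the per-analyte tissue
#' baselines `b_t ~ N(0, tissue_effect_sd^2)` emulate lineage structure
#' (set `tissue_effect_sd = 0` for exchangeable tissues).
#'
#' @param n_cells number of cell lines.
#' @param tissues named integer vector of tissue sizes (must sum to
#'   `n_cells`).
#' @param switches list of `switch_spec` objects.
#' @param n_unimodal number of unimodal analytes added to every layer.
#' @param missing_rate per-layer missing-completely-at-random rate in
#'   \[0, 1).
#' @param seed integer seed.
#' @param layers layers to generate; defaults to the union of the switch
#'   layers (or protein+mrna when there are no switches).
#' @param tissue_effect_sd SD of per-tissue baseline shifts of unimodal
#'   analytes.
#' @return An object of class `simulated_dataset`: list with `matrices`
#'   (named list of [expr_matrix()]), `annotations` (data.frame
#'   `cell_line`, `tissue`, `tumor_class`), `truth` (latent module states,
#'   per-analyte bimodality flags and module memberships, per-analyte
#'   coupling sign) and `seed`.
#' @export
simulate_multilayer <- function(n_cells, tissues, switches = list(),
                                n_unimodal = 50L, missing_rate = 0,
                                seed = 1L, layers = NULL,
                                tissue_effect_sd = 1) {
  n_cells <- assert_count(n_cells, "n_cells")
  if (length(tissues) == 0L || is.null(names(tissues)))
    stopf("'tissues' must be a non-empty named vector of sizes")
  if (sum(tissues) != n_cells)
    stopf("tissue sizes (%d) must sum to n_cells (%d)", sum(tissues), n_cells)
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("missing_rate must be in [0, 1)")
  if (is.null(layers)) {
    layers <- unique(unlist(lapply(switches, `[[`, "layers")))
    if (length(layers) == 0L) layers <- c("protein", "mrna")
  }
  with_seed(seed, {
    cells <- sprintf("CL%04d", seq_len(n_cells))
    tissue <- rep(names(tissues), times = tissues)
    ann <- data.frame(cell_line = cells, tissue = tissue,
                      tumor_class = sample(c("primary", "metastasis", "NS"),
                                           n_cells, replace = TRUE,
                                           prob = c(0.6, 0.3, 0.1)),
                      stringsAsFactors = FALSE)

    state <- matrix(0L, length(switches), n_cells,
                    dimnames = list(vapply(switches, `[[`, "", "id"), cells))
    mats <- stats::setNames(vector("list", length(layers)), layers)
    truth_rows <- list()
    for (ly in layers) mats[[ly]] <- list()

    for (si in seq_along(switches)) {
      sw <- switches[[si]]
      p <- rep(sw$pi_high, n_cells)
      if (!is.null(sw$tissue_bias)) {
        hitb <- tissue %in% names(sw$tissue_bias)
        p[hitb] <- sw$tissue_bias[tissue[hitb]]
      }
      s <- stats::rbinom(n_cells, 1L, p)
      state[si, ] <- s
      for (ly in sw$layers) {
        ids <- switch_analyte_ids(sw, ly)
        k <- length(ids)
        anti <- seq_len(k) > (k - sw$n_anti[[ly]])
        for (j in seq_len(k)) {
          agree <- stats::rbinom(n_cells, 1L, sw$coupling_rho)
          base <- if (anti[j]) 1L - s else s
          a_state <- ifelse(agree == 1L, base, 1L - base)
          vals <- stats::rnorm(n_cells, sw$mu_low +
                                 a_state * sw$delta_mu * sw$sigma, sw$sigma)
          mats[[ly]][[ids[j]]] <- vals
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            analyte = ids[j], layer = ly, module = sw$id,
            is_bimodal = sw$delta_mu > 0, sign = if (anti[j]) -1L else 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
    for (ly in layers) {
      for (j in seq_len(n_unimodal)) {
        id <- sprintf("BG%s%03d", toupper(substr(ly, 1, 1)), j)
        b <- stats::rnorm(length(tissues), 0, tissue_effect_sd)
        names(b) <- names(tissues)
        mats[[ly]][[id]] <- stats::rnorm(n_cells, b[tissue], 1)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          analyte = id, layer = ly, module = NA_character_,
          is_bimodal = FALSE, sign = 0L, stringsAsFactors = FALSE)
      }
      v <- do.call(rbind, mats[[ly]])
      colnames(v) <- cells
      if (missing_rate > 0)
        v[matrix(stats::runif(length(v)) < missing_rate, nrow(v))] <- NA
      gene_map <- NULL
      if (ly %in% c("protein", "phospho")) {
        ids <- rownames(v)
        gene <- sub("_pY[0-9]+$", "", sub("\\.[0-9]+$", "", ids))
        gene[startsWith(ids, "BG")] <- NA
        gene_map <- stats::setNames(gene, ids)
      }
      mats[[ly]] <- expr_matrix(v, ly, analyte_gene = gene_map)
    }
    truth <- list(latent_state = state,
                  analytes = do.call(rbind, truth_rows),
                  modules = vapply(switches, `[[`, "", "id"),
                  dag = NULL, seed = as.integer(seed))
    structure(list(matrices = mats, annotations = ann, truth = truth,
                   seed = as.integer(seed)),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d cells, %d tissues, layers: %s (seed %d)\n",
              nrow(x$annotations), length(unique(x$annotations$tissue)),
              paste(names(x$matrices), collapse = ", "), x$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' One TSV per layer (analytes x cells, empty cell = missing), the
#' annotation table as CSV and the planted truth as JSON.
#'
#' @param sd a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ly in names(sd$matrices))
    write_matrix(sd$matrices[[ly]], file.path(dir, paste0(ly, ".tsv")))
  utils::write.csv(sd$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- sd$truth
  truth$latent_state <- apply(truth$latent_state, 1L, identity,
                              simplify = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Simulate data from a linear-Gaussian structural equation model
#'
#' Each variable equals the weighted sum of its parents plus independent
#' Gaussian noise, generated in topological order of the supplied DAG.
#' Serves as ground truth for the causal structure-learning module.
#'
#' @param dag data.frame with columns `from`, `to`, `weight` (zero rows
#'   allowed). Must be acyclic.
#' @param n_samples number of rows to draw.
#' @param noise_sd noise SD: a scalar or a named vector over variables.
#' @param seed integer seed.
#' @param nodes optional character vector of variable names (to include
#'   isolated variables and fix column order); defaults to the nodes of
#'   `dag`.
#' @return list with `data` (n_samples x variables matrix), `dag`,
#'   `order` (the topological order used) and `seed`.
#' @export
simulate_sem <- function(dag, n_samples, noise_sd = 1, seed = 1L,
                         nodes = NULL) {
  n_samples <- assert_count(n_samples, "n_samples")
  if (any(noise_sd <= 0)) stopf("noise_sd must be positive")
  if (is.null(dag) || nrow(dag) == 0L)
    dag <- data.frame(from = character(), to = character(),
                      weight = numeric())
  nodes <- nodes %||% unique(c(dag$from, dag$to))
  if (length(nodes) == 0L) stopf("empty DAG and no 'nodes' given")
  # Kahn's algorithm; leftover nodes mean a cycle
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  tt <- table(dag$to)
  indeg[names(tt)] <- as.integer(tt)
  order <- character(0)
  avail <- names(indeg)[indeg == 0L]
  indeg <- indeg[indeg > 0L]
  edges <- dag
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    out <- edges$to[edges$from == v]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) { avail <- c(avail, w); indeg <- indeg[names(indeg) != w] }
    }
    edges <- edges[edges$from != v, , drop = FALSE]
  }
  if (length(order) < length(nodes)) stopf("'dag' contains a cycle")
  if (length(noise_sd) == 1L)
    noise_sd <- stats::setNames(rep(noise_sd, length(nodes)), nodes)
  with_seed(seed, {
    x <- matrix(0, n_samples, length(nodes), dimnames = list(NULL, nodes))
    for (v in order) {
      par <- dag[dag$to == v, , drop = FALSE]
      mu <- if (nrow(par)) x[, par$from, drop = FALSE] %*% par$weight else 0
      x[, v] <- mu + stats::rnorm(n_samples, 0, noise_sd[[v]])
    }
    list(data = x, dag = dag, order = order, seed = as.integer(seed))
  })
}
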