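# shared fixtures and independent oracles

# small expression matrix with controllable missingness
toy_matrix <- function(n_analytes = 5, n_cells = 8, layer = "protein",
                       missing = 0, seed = 42) {
  set.seed(seed)
  v <- matrix(rnorm(n_analytes * n_cells), n_analytes, n_cells,
              dimnames = list(paste0("P", seq_len(n_analytes)),
                              paste0("CL", seq_len(n_cells))))
  if (missing > 0) v[matrix(runif(length(v)) < missing, n_analytes)] <- NA
  expr_matrix(v, layer)
}

# adjusted Rand index, computed from the contingency table (independent
# of any clustering package)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# brute-force pairwise-complete Euclidean distance (triple loop oracle)
brute_pairwise_dist <- function(x, min_complete = 1) {
  n <- ncol(x)
  d <- matrix(NA_real_, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    if (sum(ok) >= min_complete)
      d[i, j] <- sqrt(sum((x[ok, i] - x[ok, j])^2))
  }
  diag(d) <- 0
  d
}

# bimodal posterior matrix from planted binary states: states copied per
# analyte with agreement prob rho, values at separation delta, posteriors
# via an exact symmetric two-component fit
planted_posteriors <- function(states, n_analytes, rho = 0.95, delta = 6,
                               seed = 1, anti = rep(FALSE, n_analytes)) {
  set.seed(seed)
  n <- length(states)
  post <- matrix(NA_real_, n_analytes, n,
                 dimnames = list(paste0("G", seq_len(n_analytes)), NULL))
  for (i in seq_len(n_analytes)) {
    base <- if (anti[i]) 1 - states else states
    s <- ifelse(rbinom(n, 1, rho) == 1, base, 1 - base)
    x <- rnorm(n, delta * s)
    post[i, ] <- dnorm(x, delta) / (dnorm(x, 0) + dnorm(x, delta))
  }
  post
}

# canonical unordered skeleton of a causal graph
skeleton_of <- function(g) {
  if (nrow(g$edges) == 0L) return(character(0))
  sort(paste(pmin(g$edges$from, g$edges$to),
             pmax(g$edges$from, g$edges$to), sep = "|"))
}

# minimal CLI scenario file
demo_scenario <- function(dir, n_cells = 80) {
  f <- file.path(dir, "scenario.yaml")
  writeLines(c(
    sprintf("n_cells: %d", n_cells),
    "tissues: {t1: 40, t2: 40}",
    "n_unimodal: 4",
    "missing_rate: 0.05",
    "switches:",
    "  - id: CDH1",
    "    layers: [protein, mrna]",
    "    delta_mu: 5",
    "    coupling_rho: 0.95",
    "  - id: CLDN7",
    "    layers: [protein, mrna]",
    "    delta_mu: 5",
    "    pi_high: 0.35",
    "  - id: RAB25",
    "    layers: [protein, mrna]",
    "    delta_mu: 5",
    "    pi_high: 0.6"), f)
  f
}
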