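#' Derive an anchor-coupled transcript signature
#'
#' Computes the bimodal coupling coefficient between one anchor analyte
#' (typically E-cadherin protein) and every transcript, and keeps the
#' transcripts with `|r_b| > threshold` (strict). Positively coupled
#' members form the positive arm (epithelial-like when the anchor is
#' E-cadherin), negatively coupled ones the negative arm
#' (mesenchymal-like). Members are sorted by `|r_b|` descending. The
#' operation is anchor-generic: any bimodal analyte can anchor a
#' signature.
#'
#' @param anchor_fit the anchor's [fit_gmm2()] result; must be bimodal.
#' @param mrna_posteriors posterior matrix (transcripts x cells) aligned
#'   on the anchor's cell axis.
#' @param threshold absolute coupling cutoff (default 0.5).
#' @param min_overlap minimum pairwise-complete cells per transcript.
#' @return An object of class `gene_signature`: list with `anchor`,
#'   `threshold` and `members` (data.frame `gene`, `r_b`, `arm`).
#' @export
derive_signature <- function(anchor_fit, mrna_posteriors, threshold = 0.5,
                             min_overlap = 30L) {
  if (!is_bimodal(anchor_fit))
    stopf("anchor '%s' is not bimodal (delta_bic = %.2f)",
          anchor_fit$analyte_id, anchor_fit$delta_bic)
  pa <- anchor_fit$posteriors
  if (length(pa) != ncol(mrna_posteriors))
    stopf("anchor posteriors and transcript matrix must share the cell axis")
  rbv <- vapply(seq_len(nrow(mrna_posteriors)), function(i)
    coupling_coefficient(pa, mrna_posteriors[i, ],
                         min_overlap = min_overlap)$r_b, 0)
  keep <- which(!is.na(rbv) & abs(rbv) > threshold)
  members <- data.frame(gene = rownames(mrna_posteriors)[keep],
                        r_b = rbv[keep],
                        arm = ifelse(rbv[keep] > 0, "positive", "negative"),
                        stringsAsFactors = FALSE)
  members <- members[order(-abs(members$r_b)), ]
  rownames(members) <- NULL
  structure(list(anchor = anchor_fit$analyte_id, threshold = threshold,
                 members = members),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf(
    "gene_signature anchored on %s (|r_b| > %g): %d members (%d+/%d-)\n",
    x$anchor, x$threshold, nrow(x$members),
    sum(x$members$arm == "positive"), sum(x$members$arm == "negative")))
  invisible(x)
}

#' Call cells discordant between mRNA and protein state
#'
#' Assigns each cell a high-confidence state per layer from the mixture
#' posteriors: `high` when the posterior of the high component is
#' `>= 1 - conf`, `low` when `<= conf`, otherwise `uncertain`
#' (default `conf = 0.1`, i.e. p < 0.1 confidence tails). Cells missing
#' either posterior are dropped. The discordant set of interest is
#' `(+-)`: mRNA high, protein low.
#'
#' @param mrna_posterior,protein_posterior aligned per-cell posterior
#'   vectors for one gene's transcript and protein.
#' @param conf confidence tail, must be < 0.5.
#' @param cells optional cell ids.
#' @return list with `calls` (data.frame `cell_id`, `posterior_mrna`,
#'   `posterior_protein`, `mrna_state`, `protein_state`), `summary`
#'   (state x state count table) and `discordant_high_mrna` (cell ids of
#'   the (+-) set).
#' @export
call_discordant <- function(mrna_posterior, protein_posterior, conf = 0.1,
                            cells = NULL) {
  if (conf >= 0.5) stopf("conf must be < 0.5")
  if (length(mrna_posterior) != length(protein_posterior))
    stopf("posterior vectors must be aligned")
  cells <- cells %||% (names(mrna_posterior) %||%
                         paste0("cell", seq_along(mrna_posterior)))
  ok <- !is.na(mrna_posterior) & !is.na(protein_posterior)
  state <- function(p) ifelse(p >= 1 - conf, "high",
                              ifelse(p <= conf, "low", "uncertain"))
  calls <- data.frame(cell_id = cells[ok],
                      posterior_mrna = mrna_posterior[ok],
                      posterior_protein = protein_posterior[ok],
                      mrna_state = state(mrna_posterior[ok]),
                      protein_state = state(protein_posterior[ok]),
                      stringsAsFactors = FALSE)
  lv <- c("low", "high", "uncertain")
  summ <- table(mrna = factor(calls$mrna_state, lv),
                protein = factor(calls$protein_state, lv))
  list(calls = calls, summary = summ,
       discordant_high_mrna = calls$cell_id[calls$mrna_state == "high" &
                                              calls$protein_state == "low"])
}

#' Export a signature as up/down gene lists
#'
#' In `induce` mode the returned `up` list is the negative arm and `down`
#' the positive arm (perturbations pushing cells away from the anchor-high
#' state, e.g. EMT induction for an E-cadherin anchor); `reverse` swaps
#' the lists. Gene symbols are deduplicated and uppercased. When `path`
#' is given, writes `<path>_up.txt` / `<path>_down.txt` (newline-delimited)
#' and `<path>.gmt` with one line per arm.
#'
#' @param sig a `gene_signature`.
#' @param direction `"induce"` or `"reverse"`.
#' @param path optional output file prefix.
#' @return list with character vectors `up` and `down`.
#' @export
export_updown <- function(sig, direction = c("induce", "reverse"),
                          path = NULL) {
  direction <- match.arg(direction)
  if (nrow(sig$members) == 0L) stopf("empty signature")
  pos <- unique(toupper(sig$members$gene[sig$members$arm == "positive"]))
  neg <- unique(toupper(sig$members$gene[sig$members$arm == "negative"]))
  if (length(pos) == 0L) warnf("positive arm is empty")
  if (length(neg) == 0L) warnf("negative arm is empty")
  out <- if (direction == "induce") list(up = neg, down = pos)
         else list(up = pos, down = neg)
  if (!is.null(path)) {
    writeLines(out$up, paste0(path, "_up.txt"))
    writeLines(out$down, paste0(path, "_down.txt"))
    gmt <- c(paste(c(paste0(sig$anchor, "_positive_arm"), "switchmix", pos),
                   collapse = "\t"),
             paste(c(paste0(sig$anchor, "_negative_arm"), "switchmix", neg),
                   collapse = "\t"))
    writeLines(gmt, paste0(path, ".gmt"))
  }
  out
}
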