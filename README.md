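# switchmix

Pan-cancer cell-line panels mix dozens of tissue lineages, and many
proteins and transcripts are not normally distributed across such panels:
they behave like **switches**, with a low- and a high-expression
subpopulation. Switch-like ("bimodal") expression of E-cadherin, Claudin-7
or Rab25 marks the epithelial–mesenchymal transition (EMT); switch-like
LCK marks blood lineage, a confound rather than a transition. `switchmix`
implements the full analysis pipeline for matched RPPA
(protein/phosphosite) and transcriptomic (mRNA) cell-line data:

1. **Bimodality detection** — per analyte, a two-component Gaussian
   mixture fitted by EM is compared with a single Gaussian by BIC.
2. **Tissue-diversity filtering** — Shannon entropy of the tissue
   composition of the low/high components; tissue-confounded switches
   land in the low-entropy tertile and are excluded.
3. **Bimodal coupling networks** — Spearman correlation of posterior
   probabilities within and across layers, thresholded and
   significance-filtered, with leading-eigenvector communities.
4. **Anchor signatures & discordance** — transcripts coupled to an anchor
   protein (e.g. E-cadherin) split into positive/negative arms;
   high-confidence mRNA-high/protein-low cells flagged.
5. **Landscape analyses** — pairwise-complete Euclidean distances,
   equal-weight layer combination, 3-NN tissue classification, Gap
   statistic, distance regression residuals, PCA/t-SNE embeddings.
6. **Causal modeling** — greedy penalised-BIC structure search with
   bootstrap edge frequencies, centralities and causal neighbourhoods.
7. **Synthetic data** — a generator of multi-layer datasets with planted
   switches, modules, tissue structure and missingness, plus a
   linear-Gaussian SEM sampler, so every stage is testable against
   ground truth.

## The model

For analyte $g$ with values $x_1,\dots,x_n$ across cell lines,

$$x_i \sim \pi\,\mathcal N(\mu_\text{high},\sigma_\text{high}^2) +
(1-\pi)\,\mathcal N(\mu_\text{low},\sigma_\text{low}^2),$$

fitted by EM with restarts. With $\mathrm{BIC}=k\ln n-2\ell$, the analyte
is **bimodal** iff $\Delta\mathrm{BIC}=\mathrm{BIC}_1-\mathrm{BIC}_2>2$.
Each cell gets the posterior probability of the high component,
$p_i = \pi\varphi_\text{high}(x_i)/f(x_i)$. The **bimodal coupling
coefficient** of two analytes is
$r_b = \mathrm{Spearman}(p^{(1)}, p^{(2)})$ over pairwise-complete cells.
Switches are **common** when the minor mixing weight
$\min(\pi,1-\pi)>1/4$, rare otherwise. Tissue diversity of a switch is
$H=-\sum_t q_t\ln q_t$ over the tissue frequencies $q_t$ of the cells in
each component; the lower tertile of $\min(H_\text{low},H_\text{high})$
is excluded from network analyses. Causal structure is learned by a
two-phase greedy search on the penalised Gaussian score
$S(v\mid P)= -\tfrac n2\ln(\mathrm{RSS}_v/n) - c(|P|+1)\tfrac{\ln n}2$
(penalty discount $c=4$, depth 3) and reported as a CPDAG with
bootstrap ($M=200$) edge frequencies.

## Worked example

```r
library(switchmix)
switches <- list(
  switch_spec("CDH1",  layers = c("protein", "mrna"), delta_mu = 5,
              coupling_rho = 0.95),
  switch_spec("CLDN7", layers = c("protein", "mrna"), delta_mu = 5,
              pi_high = 0.35),
  switch_spec("LCK",   layers = "protein", delta_mu = 5, coupling_rho = 1,
              tissue_bias = c(blood = 0.9, breast = 0, lung = 0, skin = 0)))
d <- simulate_multilayer(300, c(breast = 90, lung = 90, skin = 60, blood = 60),
                         switches, n_unimodal = 30, missing_rate = 0.05,
                         seed = 42)
fits <- fit_layer(d$matrices$protein, seed = 1)
fits[["CDH1"]]
#> mixture_fit CDH1: mu -0.081/4.972 sd 0.964/1.024 pi_high 0.441 dBIC 169.06 (bimodal)
```

The planted CDH1 switch is recovered: component means near 0 and 5
(`delta_mu = 5`), balanced mixing weight, decisive ΔBIC. Tissue-diversity
classification separates the genuine switches from the blood-only LCK
confound:

```r
cls <- classify_switches(fits, d$annotations$tissue)
cls[cls$analyte %in% c("CDH1", "CLDN7", "LCK"), ]
#>   analyte is_bimodal entropy_low entropy_high min_entropy diversity_tertile switch_class
#> 1    CDH1       TRUE        1.36       1.3719      1.3644              high       common
#> 2   CLDN7       TRUE        1.36       1.3685      1.3637            medium       common
#> 3     LCK       TRUE        1.16       0.0936      0.0936               low         rare
```

LCK's high component is almost exclusively blood (entropy 0.09 nats), so
it falls into the low-diversity tertile and is excluded downstream.
Cross-layer coupling recovers the planted mRNA–protein coordination:

```r
mfits <- fit_layer(d$matrices$mrna, seed = 2)
coupling_matrix(posterior_matrix(fits), posterior_matrix(mfits),
                pairing = "matched-gene")
#>   analyte_a analyte_b   r_b n_overlap  p_value
#> 1      CDH1      CDH1 0.597       263 7.86e-27
#> 2     CLDN7     CLDN7 0.631       275 6.48e-32

derive_signature(fits[["CDH1"]], posterior_matrix(mfits), threshold = 0.5)
#> gene_signature anchored on CDH1 (|r_b| > 0.5): 1 members (1+/0-)
```

With `coupling_rho = 0.95` the expected posterior correlation is about
$(2\rho-1)^2 = 0.81$ before mixture-assignment noise; the observed
$r_b \approx 0.6$ passes the $|r_b|>0.5$ signature cutoff, and only the
planted transcript enters the anchor signature.

## Command line

```sh
inst/cli/switchmix simulate --scenario inst/extdata/scenario_demo.yaml \
    --seed 7 --out data/
inst/cli/switchmix fit-bimodal --matrix data/protein.tsv --layer protein \
    --min-cells 40 --annotations data/annotations.csv --out out/prot
inst/cli/switchmix couple --posteriors-a out/prot_posteriors.tsv \
    --pairing all-pairs --out out/edges.tsv
inst/cli/switchmix network --edges out/edges.tsv --out out/net
inst/cli/switchmix causal --matrix data/protein.tsv --penalty-discount 4 \
    --depth 3 --bootstrap 200 --seed 7 --out out/causal
```

All subcommands are seeded and byte-reproducible.

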