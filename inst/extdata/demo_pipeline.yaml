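# Demo configuration for the full synthetic pipeline.
# Sized to finish in well under a minute; see the methods vignette for the
# meaning of every block.
seed: 1
outdir: alleleaugment_demo
alpha: 0.05
rnaseq:
  n_genes: 1200
gsea:
  n_sets: 12
  n_enriched_sets: 4
  nperm: 500
interactome:
  n_background: 80
  n_contaminant: 20
  n_exclusive_dh: 11
  n_preferential_dh: 20
conformer:
  n_models: 10
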