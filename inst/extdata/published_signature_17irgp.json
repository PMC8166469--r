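{
  "schema_version": 1,
  "pairs": [
    {
      "gene_a": "CXCL14",
      "gene_b": "BST2",
      "coefficient": -0.317773355
    },
    {
      "gene_a": "RBP1",
      "gene_b": "STC2",
      "coefficient": -0.626943874
    },
    {
      "gene_a": "RBP7",
      "gene_b": "PTGS2",
      "coefficient": 0.257688669
    },
    {
      "gene_a": "RBP7",
      "gene_b": "ARG2",
      "coefficient": 0.225331574
    },
    {
      "gene_a": "APOD",
      "gene_b": "IL17RB",
      "coefficient": 0.051156463
    },
    {
      "gene_a": "GNAI1",
      "gene_b": "GRP",
      "coefficient": -0.241838021
    },
    {
      "gene_a": "CCL4",
      "gene_b": "INHBB",
      "coefficient": -0.186143574
    },
    {
      "gene_a": "ABCC4",
      "gene_b": "GRP",
      "coefficient": -0.283312773
    },
    {
      "gene_a": "ARG2",
      "gene_b": "GRP",
      "coefficient": -0.373230092
    },
    {
      "gene_a": "CCR7",
      "gene_b": "INHBB",
      "coefficient": -0.306426565
    },
    {
      "gene_a": "CD86",
      "gene_b": "IL7",
      "coefficient": 0.278377096
    },
    {
      "gene_a": "C5AR1",
      "gene_b": "NR3C2",
      "coefficient": 0.181534979
    },
    {
      "gene_a": "INHBB",
      "gene_b": "PDGFC",
      "coefficient": 0.49522553
    },
    {
      "gene_a": "STC2",
      "gene_b": "HNF4G",
      "coefficient": 0.289767508
    },
    {
      "gene_a": "IL10RA",
      "gene_b": "TNFRSF11A",
      "coefficient": 0.122165447
    },
    {
      "gene_a": "RORC",
      "gene_b": "PRKCQ",
      "coefficient": -0.36374509
    },
    {
      "gene_a": "TNFRSF11A",
      "gene_b": "LCK",
      "coefficient": -0.34173988
    }
  ],
  "cutoff": -0.464,
  "metadata": {
    "name": "colon_cancer_17irgp",
    "description": "Published 17 immune-related gene-pair prognostic signature for colon cancer (26 immune genes); risk = sum(coefficient * pair score), high risk when risk > cutoff",
    "risk_cutoff_source": "time-dependent ROC, Youden-optimal",
    "n_pairs": 17,
    "n_genes": 26
  }
}
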