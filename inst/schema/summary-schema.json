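{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mplaclone pipeline summary",
  "type": "object",
  "required": [
    "n_patients", "n_lesions", "n_events", "n_calls",
    "n_gene_mutation_calls", "clonality_counts", "clonality_percent",
    "concordance", "percent_discordant", "percent_matched", "architecture",
    "vaf_medians", "spectrum_totals", "gene_cis", "seed"
  ],
  "properties": {
    "n_patients": {"type": "integer"},
    "n_lesions": {"type": "integer"},
    "n_events": {"type": "integer"},
    "n_calls": {"type": "integer"},
    "n_gene_mutation_calls": {"type": "integer"},
    "clonality_counts": {"type": "object"},
    "clonality_percent": {"type": "object"},
    "concordance": {"type": "object"},
    "percent_discordant": {"type": "number"},
    "percent_matched": {"type": "number"},
    "architecture": {"type": "object"},
    "vaf_medians": {"type": "object"},
    "spectrum_totals": {"type": "object"},
    "smoking_spectrum_p": {"type": "number"},
    "gene_cis": {"type": "array"},
    "egfr_subtype_ctr_p": {"type": "object"},
    "seed": {"type": "integer"}
  }
}
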