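{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "hapmark run report",
  "type": "object",
  "required": ["enrichment", "gated", "gene_rosters", "overlap",
               "deg_fraction", "shared_genes", "negative_checks",
               "skipped", "provenance"],
  "properties": {
    "enrichment": {
      "type": "object",
      "itemRequired": ["cell_type", "mark", "x", "mu", "sigma", "z",
                       "p_z", "p_emp", "degenerate", "per_block_counts",
                       "bins", "config", "null_counts"]
    },
    "gated": {"type": "array"},
    "gene_rosters": {"type": "object"},
    "overlap": {"type": "object"},
    "deg_fraction": {"type": "object"},
    "shared_genes": {"type": "array"},
    "negative_checks": {"type": "object"},
    "skipped": {"type": "array"},
    "provenance": {
      "type": "object",
      "itemRequired": ["seed", "alpha", "iterations", "gating",
                       "package_version", "input_md5"]
    }
  }
}
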