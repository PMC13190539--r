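{
  "$id": "methtier-report",
  "title": "methtier analysis report",
  "schema_version": "1.0",
  "type": "object",
  "required": [
    "schema_version", "package_version", "seeds", "provenance", "n",
    "cohort_summary", "mixture", "unsupervised_cutoff_pct",
    "unsupervised_cutoff_rounded", "supervised_cutoff_pct", "scan", "rule",
    "tiers", "warnings", "incomplete"
  ],
  "properties": {
    "schema_version": { "type": "string" },
    "package_version": { "type": "string" },
    "seeds": { "type": "object" },
    "provenance": { "type": "string" },
    "n": { "type": ["number", "integer"] },
    "cohort_summary": { "type": "object" },
    "mixture": { "type": "object" },
    "unsupervised_cutoff_pct": { "type": "number" },
    "unsupervised_cutoff_rounded": { "type": ["number", "integer"] },
    "supervised_cutoff_pct": { "type": "number" },
    "scan": { "type": "object" },
    "rule": { "type": "object" },
    "tiers": { "type": ["object", "array"] },
    "overlap": { "type": ["object", "null"] },
    "cpg_comparison": { "type": ["object", "array", "null"] },
    "final_aft": { "type": ["object", "null"] },
    "survival": { "type": ["object", "null"] },
    "warnings": { "type": ["array", "string", "null"] },
    "incomplete": { "type": "boolean" }
  }
}
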