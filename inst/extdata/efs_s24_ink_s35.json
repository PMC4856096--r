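{
  "comment": "Two-pathway pollen-killer network: INK (chr5) dominantly activates the S35 killer (chr1); EFS (chr2) dominantly suppresses the S24 killer (chr5). Positions are synthetic placeholders consistent with published map locations; survival_s for S35 derives from the male transmission frequency k = 0.89 (s = 1/k - 1).",
  "loci": [
    { "name": "S35", "chrom": "chr1", "pos_bp": 3060000, "role": "killer" },
    { "name": "INK", "chrom": "chr5", "pos_bp": 1300000, "role": "partner" },
    { "name": "S24", "chrom": "chr5", "pos_bp": 1000000, "role": "killer" },
    { "name": "EFS", "chrom": "chr2", "pos_bp": 26000000, "role": "partner" }
  ],
  "systems": [
    {
      "killer": "S35", "partner": "INK",
      "partner_mode": "activator", "targeted_allele": "J",
      "survival_s": 0.1236, "collateral_c": 0.0
    },
    {
      "killer": "S24", "partner": "EFS",
      "partner_mode": "suppressor", "targeted_allele": "J",
      "survival_s": 0.05, "collateral_c": 0.1
    }
  ]
}
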