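{
  "provenance": "Subgroup case/control counts transcribed from the published cohort study's printed tables (analysis cohort of 3533 nulliparous participants, 132 with gestational diabetes). Parent rows give subgroup counts; children give counts within the parent. PRS top/bottom 25% refer to polygenic-score quartile extremes; METs cut at 450 MET.min/wk.",
  "total": {"cases": 132, "controls": 3401},
  "family_history": {
    "cases": 45, "controls": 591,
    "children": {
      "prs_bottom25": [9, 129],
      "prs_top25": [16, 172],
      "mets_ge450": [21, 377],
      "mets_lt450": [24, 214]
    }
  },
  "age_ge35": {
    "cases": 33, "controls": 332,
    "children": {
      "prs_bottom25": [6, 88],
      "prs_top25": [14, 78],
      "mets_ge450": [18, 237],
      "mets_lt450": [15, 95]
    }
  },
  "bmi_ge25": {
    "cases": 85, "controls": 1368,
    "children": {
      "prs_bottom25": [12, 347],
      "prs_top25": [34, 337],
      "mets_ge450": [45, 854],
      "mets_lt450": [40, 514]
    }
  },
  "prs_bottom25": {
    "cases": 20, "controls": 863,
    "children": {
      "mets_lt450": [8, 264],
      "mets_ge450": [12, 599]
    }
  },
  "prs_top25": {
    "cases": 55, "controls": 829,
    "children": {
      "mets_lt450": [31, 278],
      "mets_ge450": [24, 551]
    }
  },
  "mets_ge450": {
    "cases": 74, "controls": 2291,
    "children": {
      "prs_bottom25": [12, 599],
      "prs_top25": [24, 551]
    }
  },
  "mets_lt450": {
    "cases": 58, "controls": 1110,
    "children": {
      "prs_bottom25": [8, 264],
      "prs_top25": [31, 278]
    }
  }
}
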