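{
  "dataset": "table2_bbd",
  "note": "Reference values reported alongside the published 17-run dataset; used read-only in tests, never as inputs to fitting.",
  "regression_equation": {
    "provenance": "regression_equation",
    "intercept": 27.522,
    "linear": {"A": 4.575, "B": 1.95, "C": 1.665},
    "interaction_printed": {"AB": 0.73, "AC": 1.66, "BC": -0.17},
    "quadratic_printed": {"A2": -7.681, "B2": -3.511, "C2": -3.341},
    "caveat": "The printed AB/AC signs and the B2 digits do not reproduce the predicted-yield column; the least-squares fit (AB=-0.730, AC=-1.660, B2=-3.551) does."
  },
  "predicted_yield": {
    "provenance": "design_table",
    "values": [9.035, 19.645, 14.395, 22.085, 8.6, 21.07, 15.25, 21.08,
               16.845, 21.085, 20.515, 24.075, 27.522, 27.522, 27.522, 27.522, 27.522]
  },
  "anova": {
    "provenance": "anova_table",
    "model":      {"SS": 614.36, "df": 9, "MS": 68.26, "F": 3.84, "p": 0.0451},
    "A":          {"SS": 167.45, "df": 1, "F": 9.41, "p": 0.0181},
    "B":          {"SS": 30.42,  "df": 1, "F": 1.71},
    "C":          {"SS": 22.18,  "df": 1, "F": 1.25},
    "AB":         {"SS": 2.13,   "df": 1, "F": 0.1198},
    "AC":         {"SS": 11.02,  "df": 1, "F": 0.6193},
    "BC":         {"SS": 0.1156, "df": 1, "F": 0.0065},
    "A2":         {"SS": 248.41, "df": 1, "F": 13.96},
    "B2":         {"SS": 53.09,  "df": 1, "F": 2.98},
    "C2":         {"SS": 47.0,   "df": 1, "F": 2.64},
    "residual":   {"SS": 124.59, "df": 7, "MS": 17.8},
    "lack_of_fit":{"SS": 86.51,  "df": 3, "MS": 28.84, "F": 3.03, "p": 0.1561},
    "pure_error": {"SS": 38.08,  "df": 4, "MS": 9.52},
    "cor_total":  {"SS": 738.95, "df": 16}
  },
  "reported_optima": {
    "provenance": "validation_table",
    "RSM":   {"pH": 5.997, "enzyme_pct": 3.825, "time_min": 79.895, "predicted": 27.95, "actual": 28.54, "reported_sq_err": 0.3410},
    "BP":    {"pH": 5.287, "enzyme_pct": 3.801, "time_min": 59.269, "predicted": 27.71, "actual": 28.12, "reported_sq_err": 0.1616},
    "GA-BP": {"pH": 5.248, "enzyme_pct": 3.0,   "time_min": 70.153, "predicted": 28.42, "actual": 28.35, "reported_sq_err": 0.0049}
  },
  "alternate_level_table": {
    "provenance": "level_table",
    "note": "A second printed level table (enzyme 2/3/4 %, time 20/40/60 min) contradicts the run-level data; the run-level levels (enzyme 1.5/3/4.5, time 40/60/80) are used throughout.",
    "pH": [4, 5, 6],
    "enzyme_pct": [2, 3, 4],
    "time_min": [20, 40, 60]
  }
}
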