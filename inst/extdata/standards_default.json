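{
  "_comment": "Per-parameter scoring standard T, ideal value C_ideal, and exceedance limit for %SES. Units mg/L except pH (unitless). T for pH is the upper drinking bound 8.5 with ideal 7; Ca, Mg and K carry documented placeholder limits (no drinking standard lists them directly). Every value can be overridden in a user standards file.",
  "pH":    {"T": 8.5,  "C_ideal": 7, "limit": 8.5},
  "TDS":   {"T": 1000, "C_ideal": 0, "limit": 1000},
  "TH":    {"T": 450,  "C_ideal": 0, "limit": 450},
  "Ca":    {"T": 200,  "C_ideal": 0, "limit": 200},
  "Na":    {"T": 200,  "C_ideal": 0, "limit": 200},
  "Mg":    {"T": 150,  "C_ideal": 0, "limit": 150},
  "K":     {"T": 12,   "C_ideal": 0, "limit": 12},
  "Fe":    {"T": 0.3,  "C_ideal": 0, "limit": 0.3},
  "HCO3":  {"T": 250,  "C_ideal": 0, "limit": 250},
  "SO4":   {"T": 250,  "C_ideal": 0, "limit": 250},
  "Cl":    {"T": 250,  "C_ideal": 0, "limit": 250},
  "NO3_N": {"T": 20,   "C_ideal": 0, "limit": 20},
  "F":     {"T": 1.0,  "C_ideal": 0, "limit": 1.0},
  "NO2_N": {"T": 1.0,  "C_ideal": 0, "limit": 1.0}
}
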