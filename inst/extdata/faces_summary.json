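{
  "comment": "Published summary statistics for the seven-exposure air-pollution/pesticide mixture: per-exposure marginal summaries (concentration units as printed) and the Spearman rank correlation among all pairs.",
  "exposures": ["C", "MeBr", "OP", "O3", "NO2", "PM25", "PM10"],
  "units": {
    "C": "1e6 kg/3km2", "MeBr": "1e6 kg/3km2", "OP": "1e6 kg/3km2",
    "O3": "ppb", "NO2": "ppb", "PM25": "ug/m3", "PM10": "ug/m3"
  },
  "marginals": {
    "C":    {"mean": 0.15,  "sd": 0.33,  "min": 0.00,  "q25": 0.00,  "median": 0.00,  "q75": 0.15,  "max": 2.35},
    "MeBr": {"mean": 3.88,  "sd": 9.90,  "min": 0.00,  "q25": 0.00,  "median": 0.00,  "q75": 0.00,  "max": 48.92},
    "OP":   {"mean": 0.93,  "sd": 1.08,  "min": 0.00,  "q25": 0.00,  "median": 1.11,  "q75": 1.17,  "max": 5.40},
    "O3":   {"mean": 0.04,  "sd": 0.01,  "min": 0.01,  "q25": 0.03,  "median": 0.04,  "q75": 0.04,  "max": 0.06},
    "NO2":  {"mean": 15.48, "sd": 3.26,  "min": 9.49,  "q25": 12.64, "median": 14.42, "q75": 17.96, "max": 23.07},
    "PM25": {"mean": 16.35, "sd": 9.80,  "min": 6.66,  "q25": 10.14, "median": 11.23, "q75": 18.20, "max": 40.21},
    "PM10": {"mean": 37.89, "sd": 10.68, "min": 19.55, "q25": 30.30, "median": 32.49, "q75": 47.23, "max": 65.94}
  },
  "spearman": {
    "order": ["C", "MeBr", "OP", "O3", "NO2", "PM25", "PM10"],
    "upper": {
      "C":    {"MeBr": 0.27, "OP": 0.12,  "O3": 0.09,  "NO2": 0.08,  "PM25": 0.06,  "PM10": 0.01},
      "MeBr": {"OP": -0.08, "O3": 0.02,  "NO2": 0.07,  "PM25": -0.03, "PM10": -0.13},
      "OP":   {"O3": 0.53,  "NO2": -0.53, "PM25": -0.38, "PM10": -0.24},
      "O3":   {"NO2": -0.63, "PM25": -0.54, "PM10": -0.22},
      "NO2":  {"PM25": 0.88, "PM10": 0.72},
      "PM25": {"PM10": 0.67}
    }
  },
  "zero_mass": {"C": 0.65, "MeBr": 0.80, "OP": 0.30, "O3": 0.0, "NO2": 0.0, "PM25": 0.0, "PM10": 0.0}
}
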