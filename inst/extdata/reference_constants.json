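{
  "version": "1.0",
  "note": "Printed constants of the published Bangladesh (1974-2022) and Sri Lanka (1990-2020) census analyses; stored verbatim, never computed. Table cells whose inputs were never published are fixtures for comparison only, not reproduction targets.",
  "adjusted_params": {"r": 0.0374286, "K": 225062093.9465337, "N0": 76398000},
  "initial_fitted": {"K": 230343677.2780429, "r": 0.0356036},
  "initial_verhulst": {"K": 230343707.2780429, "r": 0.036006736285777},
  "adjusted_verhulst": {"K": 230305033.7788595, "r": 0.036182814238104},
  "census_2022": {"initial": 165158616, "adjusted": 170000000},
  "sri_lanka_2020": 21413249,
  "epoch_year": 1974,
  "census_years": [1974, 1981, 1991, 2001, 2011, 2022],
  "stability": {
    "psi": 0.06283730012,
    "eta": 0.17494684266,
    "alpha": 0.5,
    "b": 10,
    "normalization": 1,
    "note": "psi as printed is not exactly r + 2 r N0/K of the printed parameters (that evaluates to 0.06283910012); eta follows exactly from the printed psi."
  },
  "scheme_tables": {
    "bd_initial": {
      "census": 165158616.0,
      "logistic": 164250406.1566,
      "predictor_corrector": 164250406.1568,
      "fractional_order": 164082545.7138,
      "multiscaling": 165158616.0541,
      "percent_errors": {"logistic": "0.55%", "predictor_corrector": "0.55%", "fractional_order": "0.65%", "multiscaling": "0.3e-7%"}
    },
    "bd_adjusted": {
      "census": 170000000.0,
      "logistic": 170145565.0601,
      "predictor_corrector": 170145565.0603,
      "fractional_order": 169990102.5184,
      "multiscaling": 170000000.0009,
      "percent_errors": {"logistic": "0.09%", "predictor_corrector": "0.09%", "fractional_order": "0.006%", "multiscaling": "0.5e-9%"}
    },
    "sri_lanka": {
      "census": 21413249,
      "logistic": 21438307.51789,
      "predictor_corrector": 21438307.51789,
      "fractional_order": 21426601.72682,
      "multiscaling": 21413249.35605,
      "percent_errors": {"logistic": "0.12%", "predictor_corrector": "0.12%", "fractional_order": "0.06%", "multiscaling": "0.2e-5%"}
    }
  },
  "fps_table": {
    "r0": [0.0374286, 0.03, 0.02, 0.01],
    "fps_million": [216.887, 212.776, 204.131, 190.396],
    "horizon_year": 2080
  },
  "table2_flagged": {
    "ambiguous": true,
    "note": "The multiscale amplitude table is typographically garbled for the adjusted-census row; the raw strings are kept verbatim with one candidate parse. Units of delta (absolute vs fraction of K0) were never stated.",
    "initial": {"epsilon": 0.1, "delta": 0.2, "Delta": 0.002120635},
    "adjusted": {"raw": "0.70.00160095945", "epsilon_candidate": 0.7, "delta_candidate": 0.0016009594, "Delta_candidate": null}
  }
}
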