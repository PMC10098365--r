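{
  "comment": "Synthetic seed-population fixtures. Cardinal temperatures follow the published morph/seedlot estimates; SDs, theta_warm, ER lag, dormancy fractions and temperature grids are model design choices documented in the methods vignette.",
  "seed_params": {
    "black_AR_1": {
      "tBase": 8.0, "thetaCold50": 144.0, "sigmaTheta": 30.0,
      "tc50": 35.0, "sigmaTc": 2.0, "thetaWarm": 99.0,
      "pViable": 0.63, "erLag50": 0.75, "erLagShape": 0.25,
      "label": "after-ripened black seeds, seedlot #1",
      "temperatures": [13, 15, 17, 19, 22, 25, 28, 31, 34]
    },
    "brown_1": {
      "tBase": 10.0, "thetaCold50": 150.0, "sigmaTheta": 25.0,
      "tc50": 31.0, "sigmaTc": 0.75, "thetaWarm": 46.875,
      "pViable": 0.63, "erLag50": 0.75, "erLagShape": 0.25,
      "label": "brown seeds, seedlot #1",
      "temperatures": [13, 15, 17, 19, 22, 25, 27, 28, 29]
    },
    "black_2": {
      "tBase": 10.5, "thetaCold50": 120.0, "sigmaTheta": 15.0,
      "tc50": 33.5, "sigmaTc": 1.5, "thetaWarm": 120.0,
      "pViable": 0.63, "erLag50": 0.75, "erLagShape": 0.25,
      "label": "freshly harvested black seeds, seedlot #2",
      "temperatures": [13, 15, 17, 19, 22, 25, 28, 31, 34]
    },
    "brown_2": {
      "tBase": 10.5, "thetaCold50": 115.0, "sigmaTheta": 15.0,
      "tc50": 33.5, "sigmaTc": 1.5, "thetaWarm": 115.0,
      "pViable": 0.63, "erLag50": 0.75, "erLagShape": 0.25,
      "label": "brown seeds, seedlot #2",
      "temperatures": [13, 15, 17, 19, 22, 25, 28, 31, 34]
    }
  },
  "dormancy_states": {
    "FH_black_1": { "fNd": 0.112, "fNpd": 0.513, "fDpd": 0.375 }
  },
  "treatment_rules": {
    "scarifiedFraction": 0.78, "fluridoneGaIncrement": 0.05,
    "abaLagSlope": 0.15
  },
  "scoring_days": 45
}
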