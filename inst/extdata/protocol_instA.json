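{
  "version": "1.0",
  "name": "prostate-60Gy20F-instA",
  "institution": "instA",
  "prescription": 60,
  "prescriptions": {
    "PTV60": 60,
    "PTV57.5": 57.5,
    "PTV48": 48
  },
  "goals": [
    {
      "roi": "PTV48",
      "priority": "P1",
      "goal_type": "conformality_max",
      "target": 46.8,
      "units": "Gy",
      "distance": 1.5
    },
    {
      "roi": "PTV60",
      "priority": "P2",
      "goal_type": "min_dose",
      "target": 98.7,
      "units": "%Presc,PTV"
    },
    {
      "roi": "PTV60",
      "priority": "P2",
      "goal_type": "max_dose",
      "target": 101.7,
      "units": "%Presc,PTV"
    },
    {
      "roi": "PTV60",
      "priority": "P2",
      "goal_type": "median_max",
      "target": 99.5,
      "units": "%Presc,PTV"
    },
    {
      "roi": "PTV57.5",
      "priority": "P2",
      "goal_type": "min_dose",
      "target": 98.7,
      "units": "%Presc,PTV"
    },
    {
      "roi": "PTV57.5",
      "priority": "P2",
      "goal_type": "max_dose",
      "target": 102.5,
      "units": "%Presc,PTV"
    },
    {
      "roi": "PTV48",
      "priority": "P2",
      "goal_type": "min_dose",
      "target": 97.3,
      "units": "%Presc,PTV"
    },
    {
      "roi": "PTV48",
      "priority": "P2",
      "goal_type": "max_dose",
      "target": 104.9,
      "units": "%Presc,PTV"
    },
    {
      "roi": "Rectum",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 3.5,
      "dose_level": 23.4
    },
    {
      "roi": "Rectum",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 3.5,
      "dose_level": 31.5
    },
    {
      "roi": "Rectum",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 0.044,
      "dose_level": 39.6
    },
    {
      "roi": "Rectum",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 0.088,
      "dose_level": 47.7
    },
    {
      "roi": "Rectum",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 29.9,
      "dose_level": 51.8
    },
    {
      "roi": "Rectum",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 3.5,
      "dose_level": 55.9
    },
    {
      "roi": "Rectum",
      "priority": "P3",
      "goal_type": "max_dose",
      "target": 60,
      "units": "Gy",
      "weighting_factor": 0.586
    },
    {
      "roi": "Rectum",
      "priority": "P3",
      "goal_type": "mean_dose",
      "target": 5,
      "units": "Gy",
      "weighting_factor": 5.84
    },
    {
      "roi": "Bladder",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 0.316,
      "dose_level": 30
    },
    {
      "roi": "Bladder",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 0.316,
      "dose_level": 39.6
    },
    {
      "roi": "Bladder",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 0.316,
      "dose_level": 47.7
    },
    {
      "roi": "Bladder",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 0.316,
      "dose_level": 51.8
    },
    {
      "roi": "Bladder",
      "priority": "P3",
      "goal_type": "dv_max",
      "target": 0,
      "units": "%Vol",
      "weighting_factor": 0.316,
      "dose_level": 55.9
    },
    {
      "roi": "Bladder",
      "priority": "P3",
      "goal_type": "max_dose",
      "target": 54,
      "units": "Gy",
      "weighting_factor": 0.316
    },
    {
      "roi": "Bladder",
      "priority": "P3",
      "goal_type": "mean_dose",
      "target": 5,
      "units": "Gy",
      "weighting_factor": 3.73
    },
    {
      "roi": "External",
      "priority": "P3",
      "goal_type": "dose_falloff_external",
      "target": 0,
      "units": "Gy",
      "weighting_factor": 204,
      "falloff": {
        "high_dose": 60,
        "low_dose": 30,
        "gradient": 50
      }
    },
    {
      "roi": "PTV57.5",
      "priority": "P3",
      "goal_type": "dose_falloff_intra",
      "target": 0,
      "units": "Gy",
      "weighting_factor": 10.7,
      "falloff": {
        "high_dose": 54,
        "low_dose": 54,
        "gradient": 75
      }
    },
    {
      "roi": "PTV48",
      "priority": "P3",
      "goal_type": "dose_falloff_intra",
      "target": 0,
      "units": "Gy",
      "weighting_factor": 29.8,
      "falloff": {
        "high_dose": 54.6,
        "low_dose": 45.6,
        "gradient": 75
      }
    }
  ]
}
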