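{
  "meta": {
    "description": "Base epidemiological inputs for the proximal-caries microsimulation",
    "currency_year": 2020
  },
  "age": {
    "start": 12,
    "factor": 2,
    "exp_base": 2.7
  },
  "prevalence": {
    "low": {
      "E2": 0.14,
      "D1": 0.025,
      "D2": 0.005
    },
    "high_multiplier": {
      "E2": 2.14,
      "D1": 1.66,
      "D2": 1.66
    }
  },
  "accuracy": {
    "visual_tactile": {
      "sensitivity": {
        "E2": {
          "kind": "point",
          "low": 0,
          "mode": 0,
          "high": 0
        },
        "D1": {
          "kind": "point",
          "low": 0,
          "mode": 0,
          "high": 0
        },
        "advanced": {
          "kind": "triangular",
          "low": 0.27,
          "mode": 0.311,
          "high": 0.353
        }
      },
      "specificity": {
        "E2": {
          "kind": "point",
          "low": 1,
          "mode": 1,
          "high": 1
        },
        "D1": {
          "kind": "point",
          "low": 1,
          "mode": 1,
          "high": 1
        },
        "advanced": {
          "kind": "triangular",
          "low": 0.892,
          "mode": 0.922,
          "high": 0.945
        }
      }
    },
    "radiograph_meta": {
      "sensitivity": {
        "E2": {
          "kind": "triangular",
          "low": 0.21,
          "mode": 0.24,
          "high": 0.26
        },
        "D1": {
          "kind": "triangular",
          "low": 0.24,
          "mode": 0.36,
          "high": 0.49
        },
        "advanced": {
          "kind": "triangular",
          "low": 0.59,
          "mode": 0.64,
          "high": 0.7
        }
      },
      "specificity": {
        "E2": {
          "kind": "triangular",
          "low": 0.95,
          "mode": 0.97,
          "high": 0.98
        },
        "D1": {
          "kind": "triangular",
          "low": 0.89,
          "mode": 0.94,
          "high": 0.97
        },
        "advanced": {
          "kind": "triangular",
          "low": 0.97,
          "mode": 0.98,
          "high": 0.98
        }
      }
    },
    "radiograph_primary": {
      "sensitivity": {
        "E2": {
          "kind": "triangular",
          "low": 0.19,
          "mode": 0.36,
          "high": 0.65
        },
        "D1": {
          "kind": "triangular",
          "low": 0.19,
          "mode": 0.36,
          "high": 0.65
        },
        "advanced": {
          "kind": "triangular",
          "low": 0.59,
          "mode": 0.64,
          "high": 0.7
        }
      },
      "specificity": {
        "E2": {
          "kind": "triangular",
          "low": 0.69,
          "mode": 0.91,
          "high": 0.98
        },
        "D1": {
          "kind": "triangular",
          "low": 0.69,
          "mode": 0.91,
          "high": 0.98
        },
        "advanced": {
          "kind": "triangular",
          "low": 0.97,
          "mode": 0.98,
          "high": 0.98
        }
      }
    },
    "radiograph_ai": {
      "sensitivity": {
        "E2": {
          "kind": "point",
          "low": 0.68,
          "mode": 0.68,
          "high": 0.68
        },
        "D1": {
          "kind": "point",
          "low": 0.68,
          "mode": 0.68,
          "high": 0.68
        },
        "advanced": {
          "kind": "point",
          "low": 0.58,
          "mode": 0.58,
          "high": 0.58
        }
      },
      "specificity": {
        "E2": {
          "kind": "point",
          "low": 0.86,
          "mode": 0.86,
          "high": 0.86
        },
        "D1": {
          "kind": "point",
          "low": 0.86,
          "mode": 0.86,
          "high": 0.86
        },
        "advanced": {
          "kind": "point",
          "low": 0.96,
          "mode": 0.96,
          "high": 0.96
        }
      }
    }
  },
  "development": {
    "multiplier": {
      "kind": "uniform",
      "low": 1.24,
      "mode": 1.26,
      "high": 1.29
    },
    "E2": {
      "a": 0.57252,
      "b": -0.1472
    },
    "D1": {
      "a": 0.0426,
      "b": -0.0521
    },
    "D2": {
      "a": 0.024282,
      "b": -0.0521
    }
  },
  "progression": {
    "risk_multiplier": {
      "low": 2.13,
      "high": 2.63
    },
    "untreated": {
      "E2": {
        "c": 3.0984,
        "k": 1.343
      },
      "D1": {
        "c": 161.52,
        "k": 2.078
      },
      "D2": {
        "c": 161.52,
        "k": 2.078,
        "fixed_multiplier": 1.32
      }
    },
    "untreated_spread": {
      "kind": "uniform",
      "low": 0.87,
      "mode": 1,
      "high": 1.13
    },
    "infiltrated": {
      "E2": {
        "c": 0.4289,
        "k": 1.391,
        "spread": {
          "kind": "triangular",
          "low": 0.23,
          "mode": 1,
          "high": 5.15
        }
      },
      "D1": {
        "c": 68.869,
        "k": 2.078,
        "spread": {
          "kind": "triangular",
          "low": 0.23,
          "mode": 1,
          "high": 4.17
        }
      }
    }
  },
  "transitions": {
    "composite": {
      "p": {
        "kind": "point",
        "low": 0.016,
        "mode": 0.016,
        "high": 0.016
      },
      "alloc": {
        "composite": 0.45,
        "crown": 0.1,
        "repair": 0.1,
        "rct": 0.25,
        "extraction": 0.1
      }
    },
    "direct_capping": {
      "p": {
        "kind": "point",
        "low": 0.111,
        "mode": 0.111,
        "high": 0.111
      },
      "alloc": {
        "rct": 0.95,
        "extraction": 0.05
      }
    },
    "crown_vital": {
      "p": {
        "kind": "point",
        "low": 0.036,
        "mode": 0.036,
        "high": 0.036
      },
      "alloc": {
        "rct": 0.25,
        "recement": 0.15,
        "repair": 0.1,
        "recrown": 0.4,
        "extraction": 0.1
      }
    },
    "rct": {
      "p": {
        "kind": "point",
        "low": 0.021,
        "mode": 0.021,
        "high": 0.021
      },
      "alloc": {
        "nonsurg_retreat": 0.2,
        "surg_retreat": 0.3,
        "extraction": 0.5
      }
    },
    "crown_nonvital": {
      "p": {
        "kind": "point",
        "low": 0.029,
        "mode": 0.029,
        "high": 0.029
      },
      "alloc": {
        "recement": 0.2,
        "repair": 0.1,
        "recrown": 0.6,
        "extraction": 0.1
      }
    },
    "nonsurg_retreat": {
      "p": {
        "kind": "point",
        "low": 0.085,
        "mode": 0.085,
        "high": 0.085
      },
      "alloc": {
        "surg_retreat": 0.25,
        "extraction": 0.75
      }
    },
    "surg_retreat": {
      "p": {
        "kind": "point",
        "low": 0.061,
        "mode": 0.061,
        "high": 0.061
      },
      "alloc": {
        "extraction": 1
      }
    },
    "implant": {
      "p": {
        "kind": "point",
        "low": 0.01,
        "mode": 0.01,
        "high": 0.01
      },
      "alloc": {
        "refix": 0.6,
        "recrown": 0.2,
        "reimplant": 0.2
      }
    }
  },
  "clinical": {
    "pulp_exposure_d3": {
      "kind": "point",
      "low": 0.3,
      "mode": 0.3,
      "high": 0.3
    },
    "pulp_exposure_rerestoration": {
      "kind": "point",
      "low": 0.1,
      "mode": 0.1,
      "high": 0.1
    },
    "capping_fraction": {
      "kind": "point",
      "low": 0.95,
      "mode": 0.95,
      "high": 0.95
    },
    "replacement": {
      "kind": "point",
      "low": 0.8,
      "mode": 0.8,
      "high": 0.8
    }
  }
}
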