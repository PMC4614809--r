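{
  "schema_version": 1,
  "name": "synthetic_example",
  "femur_length": 1,
  "joint": {
    "center": [0, 0, 0],
    "dof_senses": {
      "FE": 1,
      "ABD": 1,
      "LAR": 1
    }
  },
  "muscles": [
    {
      "name": "IF",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.313508, 0.408303, -0.02425]
        },
        {
          "segment": "femur",
          "xyz": [0.016161, -0.398517, 0.046048]
        }
      ]
    },
    {
      "name": "CFB",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [0.554783, 0.043902, 0.044475]
        },
        {
          "segment": "femur",
          "xyz": [0.017957, -0.15104, -0.058622]
        }
      ]
    },
    {
      "name": "CFL",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [0.874932, -0.098705, 0.025943]
        },
        {
          "segment": "femur",
          "xyz": [0.01882, -0.432351, 0.059695]
        }
      ]
    },
    {
      "name": "PIFE1",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.390282, -0.374286, -0.021451]
        },
        {
          "segment": "pelvis",
          "xyz": [-0.093203, -0.630065, -0.182262]
        },
        {
          "segment": "femur",
          "xyz": [0.012493, -0.237344, 0.072423]
        }
      ]
    },
    {
      "name": "PIFE2",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.157942, -0.501915, -0.0346]
        },
        {
          "segment": "pelvis",
          "xyz": [-0.152071, -0.493935, -0.132974]
        },
        {
          "segment": "femur",
          "xyz": [0.064844, -0.181646, 0.058527]
        }
      ]
    },
    {
      "name": "PIFI1",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.434642, 0.330831, -0.033231]
        },
        {
          "segment": "femur",
          "xyz": [0.068943, -0.167236, 0.020484]
        }
      ]
    },
    {
      "name": "PIFI2",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.135711, 0.369059, 0.065272]
        },
        {
          "segment": "femur",
          "xyz": [0.085182, -0.276138, 0.058742]
        }
      ]
    },
    {
      "name": "ADD1",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.390799, -0.580289, -0.048413]
        },
        {
          "segment": "femur",
          "xyz": [-0.070394, -0.201359, 0.003987]
        }
      ]
    },
    {
      "name": "ADD2",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.36951, -0.58892, -0.114764]
        },
        {
          "segment": "femur",
          "xyz": [-0.022793, -0.212869, 0.110735]
        }
      ]
    },
    {
      "name": "ISTR",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [0.434141, -0.376436, -0.111405]
        },
        {
          "segment": "femur",
          "xyz": [0.03777, -0.221438, 0.061986]
        }
      ]
    },
    {
      "name": "ITBa",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.167674, 0.271186, 0.155965]
        },
        {
          "segment": "femur",
          "xyz": [0.032001, -0.741157, 0.045796]
        }
      ]
    },
    {
      "name": "ITBp",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [0.230584, 0.310861, -0.04467]
        },
        {
          "segment": "femur",
          "xyz": [-0.043173, -0.592601, 0.064798]
        }
      ]
    },
    {
      "name": "FTE",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [0.164027, -0.107037, -0.011466]
        },
        {
          "segment": "femur",
          "xyz": [0.020764, -0.595053, 0.010551]
        }
      ]
    },
    {
      "name": "FTI3",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [0.428755, -0.18598, -0.197462]
        },
        {
          "segment": "femur",
          "xyz": [-0.031011, -0.730692, -0.009891]
        }
      ]
    },
    {
      "name": "AMB",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.235318, 0.43108, 0.077245]
        },
        {
          "segment": "femur",
          "xyz": [-0.047433, -0.595424, -0.021536]
        }
      ]
    },
    {
      "name": "IFB",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.314187, 0.43, -0.009419]
        },
        {
          "segment": "femur",
          "xyz": [-0.0268, -0.20022, -0.050428]
        }
      ]
    },
    {
      "name": "IFMa",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.265937, 0.330496, 0.198474]
        },
        {
          "segment": "femur",
          "xyz": [0.04602, -0.203735, -0.058294]
        }
      ]
    },
    {
      "name": "IFMp",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [-0.403686, 0.302279, -0.078794]
        },
        {
          "segment": "femur",
          "xyz": [0.09093, -0.358111, 0.074914]
        }
      ]
    },
    {
      "name": "PIT",
      "points": [
        {
          "segment": "pelvis",
          "xyz": [0.494683, -0.371702, -0.093579]
        },
        {
          "segment": "femur",
          "xyz": [-0.061379, -0.239417, 0.108347]
        }
      ]
    }
  ],
  "metadata": {
    "taxon": "synthetic_example",
    "posture_class": "biped",
    "generator": "hiparm-synth-1",
    "seed": 2026
  }
}
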