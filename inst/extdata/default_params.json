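{
  "compound": {
    "name": "salvianolic acid A",
    "molecular_weight": 494.45,
    "fraction_unbound_plasma": 0.05,
    "blood_to_plasma_ratio": 0.6,
    "acid_pKa": 2.9,
    "logP": 2.6
  },
  "tissues": [
    {
      "tissue_name": "lung",
      "volume": 0.53,
      "blood_flow": 390,
      "kp": 0.227094134042346,
      "pstc": 1.66345735479055,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "heart",
      "volume": 0.33,
      "blood_flow": 15.6,
      "kp": 0.174237931909546,
      "pstc": 1.03573759826582,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "brain",
      "volume": 1.45,
      "blood_flow": 46.8,
      "kp": 0.0660666641436302,
      "pstc": 4.55096823480435,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "adipose",
      "volume": 14.5,
      "blood_flow": 19.5,
      "kp": 0.0541705073059476,
      "pstc": 45.5096823480435,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "muscle",
      "volume": 29,
      "blood_flow": 66.3,
      "kp": 0.079248528945629,
      "pstc": 91.0193646960869,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "skin",
      "volume": 3.4,
      "blood_flow": 19.5,
      "kp": 0.28808086914761,
      "pstc": 10.6712358609205,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "bone",
      "volume": 10,
      "blood_flow": 19.5,
      "kp": 0.106898437281054,
      "pstc": 31.3859878262369,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "gut",
      "volume": 1.65,
      "blood_flow": 23.4,
      "kp": 0.173681522650878,
      "pstc": 5.17868799132908,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "spleen",
      "volume": 0.19,
      "blood_flow": 5.85,
      "kp": 0.11403258223758,
      "pstc": 0.596333768698501,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "liver",
      "volume": 1.8,
      "blood_flow": 85.8,
      "kp": 0.101169540740177,
      "pstc": 5.64947780872264,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "kidney",
      "volume": 0.31,
      "blood_flow": 66.3,
      "kp": 0.146776677362705,
      "pstc": 0.972965622613343,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "reproductive",
      "volume": 0.13,
      "blood_flow": 1.95,
      "kp": 0.127711953759112,
      "pstc": 0.408017841741079,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "rest_of_body",
      "volume": 4,
      "blood_flow": 7.8,
      "kp": 0.116490661771053,
      "pstc": 12.5543951304947,
      "vascular_fraction": 0.05
    },
    {
      "tissue_name": "red_marrow",
      "volume": 1.17,
      "blood_flow": 11.7,
      "kp": 0.113480722969616,
      "pstc": 3.67216057566971,
      "vascular_fraction": 0.05
    }
  ],
  "transporters": [
    {
      "transporter_name": "OATP1B1",
      "vmax": 262944950.246516,
      "km": 144.835336906064,
      "direction": "uptake"
    },
    {
      "transporter_name": "P-gp",
      "vmax": 262944950.246516,
      "km": 144.835336906064,
      "direction": "efflux"
    }
  ],
  "cardiac_output": 390,
  "venous_volume": 3.7,
  "arterial_volume": 1.85,
  "systemic_linear_clearance": 0
}
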