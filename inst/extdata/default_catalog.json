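{
  "version": "1",
  "sets": [
    {
      "name": "chronic_kidney_disease",
      "codes": [
        {
          "system": "local",
          "code": "LC-CHRONIC-KIDNEY-DISEASE"
        }
      ],
      "synonyms": [
        "chronic kidney disease",
        "ckd"
      ]
    },
    {
      "name": "proteinuria",
      "codes": [
        {
          "system": "local",
          "code": "LC-PROTEINURIA"
        }
      ],
      "synonyms": [
        "proteinuria"
      ]
    },
    {
      "name": "microalbuminuria",
      "codes": [
        {
          "system": "local",
          "code": "LC-MICROALBUMINURIA"
        }
      ],
      "synonyms": [
        "microalbuminuria"
      ]
    },
    {
      "name": "cardiomyopathy",
      "codes": [
        {
          "system": "local",
          "code": "LC-CARDIOMYOPATHY"
        }
      ],
      "synonyms": [
        "cardiomyopathy",
        "hypertrophic cardiomyopathy"
      ]
    },
    {
      "name": "valvular_heart_disease",
      "codes": [
        {
          "system": "local",
          "code": "LC-VALVULAR-HEART-DISEASE"
        }
      ],
      "synonyms": [
        "heart valve disorder",
        "valvular heart disease"
      ]
    },
    {
      "name": "arrhythmia",
      "codes": [
        {
          "system": "local",
          "code": "LC-ARRHYTHMIA"
        }
      ],
      "synonyms": [
        "arrhythmia",
        "cardiac arrhythmia"
      ]
    },
    {
      "name": "stroke_ischemic",
      "codes": [
        {
          "system": "local",
          "code": "LC-STROKE-ISCHEMIC"
        }
      ],
      "synonyms": [
        "ischaemic stroke",
        "ischemic stroke",
        "stroke ischemic"
      ]
    },
    {
      "name": "transient_ischemic_attack",
      "codes": [
        {
          "system": "local",
          "code": "LC-TRANSIENT-ISCHEMIC-ATTACK"
        }
      ],
      "synonyms": [
        "tia",
        "transient ischaemic attack",
        "transient ischemic attack"
      ]
    },
    {
      "name": "acroparaesthesia",
      "codes": [
        {
          "system": "local",
          "code": "LC-ACROPARAESTHESIA"
        }
      ],
      "synonyms": [
        "acroparaesthesia",
        "acroparesthesia"
      ]
    },
    {
      "name": "angiokeratomas",
      "codes": [
        {
          "system": "local",
          "code": "LC-ANGIOKERATOMAS"
        }
      ],
      "synonyms": [
        "angiokeratoma",
        "angiokeratomas"
      ]
    },
    {
      "name": "hypohidrosis",
      "codes": [
        {
          "system": "local",
          "code": "LC-HYPOHIDROSIS"
        }
      ],
      "synonyms": [
        "hypohidrosis",
        "impaired sweating",
        "impaired sweating/hypohidrosis"
      ]
    },
    {
      "name": "heat_cold_intolerance",
      "codes": [
        {
          "system": "local",
          "code": "LC-HEAT-COLD-INTOLERANCE"
        }
      ],
      "synonyms": [
        "heat and cold intolerance",
        "heat and cold tolerance"
      ]
    },
    {
      "name": "corneal_whirling",
      "codes": [
        {
          "system": "local",
          "code": "LC-CORNEAL-WHIRLING"
        }
      ],
      "synonyms": [
        "corneal whirling"
      ]
    },
    {
      "name": "cornea_verticillata",
      "codes": [
        {
          "system": "local",
          "code": "LC-CORNEA-VERTICILLATA"
        }
      ],
      "synonyms": [
        "cornea verticillata",
        "cornea verticillate"
      ]
    },
    {
      "name": "corneal_lenticular_opacities",
      "codes": [
        {
          "system": "local",
          "code": "LC-CORNEAL-LENTICULAR-OPACITIES"
        }
      ],
      "synonyms": [
        "corneal and lenticular opacities",
        "corneal opacity",
        "lenticular opacity"
      ]
    },
    {
      "name": "retinal_vasculopathy",
      "codes": [
        {
          "system": "local",
          "code": "LC-RETINAL-VASCULOPATHY"
        }
      ],
      "synonyms": [
        "conjunctival vasculopathy",
        "retinal vasculopathy",
        "vasculopathy (retina, conjunctiva)"
      ]
    },
    {
      "name": "fabry_disease",
      "codes": [
        {
          "system": "local",
          "code": "LC-FABRY-DISEASE"
        }
      ],
      "synonyms": [
        "anderson-fabry disease",
        "fabry disease"
      ]
    },
    {
      "name": "familial_hypercholesterolaemia",
      "codes": [
        {
          "system": "local",
          "code": "LC-FAMILIAL-HYPERCHOLESTEROLAEMIA"
        },
        {
          "system": "SNOMED",
          "code": "398036000"
        }
      ],
      "synonyms": [
        "familial hypercholesterolaemia",
        "familial hypercholesterolemia"
      ]
    },
    {
      "name": "ascvd",
      "codes": [
        {
          "system": "local",
          "code": "LC-ASCVD"
        }
      ],
      "synonyms": [
        "angina",
        "coronary revascularisation",
        "coronary revascularization",
        "ischaemic stroke",
        "ischemic stroke",
        "myocardial infarction",
        "peripheral arterial disease",
        "unstable angina"
      ]
    }
  ]
}
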