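{
  "name": "bapt_v1",
  "criteria": [
    {
      "name": "comorbidity",
      "mode": "additive_subscore",
      "levels": [
        {
          "label": "minimal_impact",
          "points": 0
        },
        {
          "label": "hypertension",
          "points": 2
        },
        {
          "label": "dyslipidaemia",
          "points": 2
        },
        {
          "label": "nash",
          "points": 3
        },
        {
          "label": "albuminuria",
          "points": 3
        },
        {
          "label": "joint_pain",
          "points": 4
        },
        {
          "label": "reproductive_issues",
          "points": 4
        },
        {
          "label": "renal_impairment",
          "points": 5
        },
        {
          "label": "osa",
          "points": 7
        }
      ]
    },
    {
      "name": "duration",
      "mode": "single_select",
      "levels": [
        {
          "label": "gt8y",
          "points": 0
        },
        {
          "label": "4to8y",
          "points": 12
        },
        {
          "label": "lt4y",
          "points": 20
        }
      ]
    },
    {
      "name": "bmi",
      "mode": "single_select",
      "levels": [
        {
          "label": "35to40",
          "points": 0
        },
        {
          "label": "40to45",
          "points": 10
        },
        {
          "label": "45to50",
          "points": 13
        },
        {
          "label": "ge50",
          "points": 15
        }
      ]
    },
    {
      "name": "age",
      "mode": "single_select",
      "levels": [
        {
          "label": "ge50",
          "points": 0
        },
        {
          "label": "30to49",
          "points": 10
        },
        {
          "label": "18to29",
          "points": 15
        }
      ]
    },
    {
      "name": "risk",
      "mode": "single_select",
      "levels": [
        {
          "label": "factors4to5",
          "points": 0
        },
        {
          "label": "factors2to3",
          "points": 10
        },
        {
          "label": "factors0to1",
          "points": 20
        }
      ]
    }
  ]
}
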