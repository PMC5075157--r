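{
  "sets": [
    {
      "name": "pe",
      "kind": "diagnosis",
      "patterns": [
        "415.1x"
      ],
      "provenance": "Index pulmonary embolism diagnosis family (ICD-9-CM 415.1x truncation)"
    },
    {
      "name": "pe_complication",
      "kind": "diagnosis",
      "patterns": [
        "518.81",
        "785.51",
        "427.5",
        "416.8",
        "780.2"
      ],
      "provenance": "PE-related complication diagnoses qualifying a secondary-position PE: acute respiratory failure, cardiogenic shock, cardiac arrest, secondary pulmonary hypertension, syncope"
    },
    {
      "name": "pe_complication_procedure",
      "kind": "procedure",
      "patterns": [
        "99.10",
        "96.04",
        "96.05",
        "96.70-96.72"
      ],
      "provenance": "PE-related complication procedures: thrombolytic infusion, endotracheal intubation, mechanical ventilation"
    },
    {
      "name": "dvt",
      "kind": "diagnosis",
      "patterns": [
        "451.1x",
        "451.2",
        "451.81",
        "451.9",
        "453.1",
        "453.2",
        "453.3",
        "453.4x",
        "453.8x",
        "453.9"
      ],
      "provenance": "Deep vein thrombosis diagnoses used for recurrent-VTE ascertainment; widely used claims definition (editable)"
    },
    {
      "name": "myocardial_infarction",
      "kind": "diagnosis",
      "patterns": [
        "410.x",
        "412"
      ],
      "provenance": "Acute/old myocardial infarction; standard claims definition (not part of the AHRQ 29-comorbidity schema; editable)"
    },
    {
      "name": "chronic_lung_disease",
      "kind": "diagnosis",
      "patterns": [
        "490.x",
        "491.x",
        "492.x",
        "493.x",
        "494.x",
        "495.x",
        "496.x",
        "497.x",
        "498.x",
        "499.x",
        "500.x",
        "501.x",
        "502.x",
        "503.x",
        "504.x",
        "505.x",
        "506.4"
      ],
      "provenance": "AHRQ comorbidity schema: chronic pulmonary disease"
    },
    {
      "name": "stroke",
      "kind": "diagnosis",
      "patterns": [
        "430",
        "431",
        "433.01",
        "433.11",
        "433.21",
        "433.31",
        "433.81",
        "433.91",
        "434.01",
        "434.11",
        "434.91",
        "436"
      ],
      "provenance": "Acute cerebrovascular event; standard claims definition (not part of the AHRQ schema; editable)"
    },
    {
      "name": "prior_major_bleeding",
      "kind": "diagnosis",
      "patterns": [
        "432.x",
        "578.x",
        "569.3",
        "599.7",
        "786.3"
      ],
      "provenance": "Prior major bleeding (intracranial non-traumatic, gastrointestinal, genitourinary, hemoptysis); widely used claims bleeding definition (not part of the AHRQ schema; editable)"
    },
    {
      "name": "atrial_fibrillation",
      "kind": "diagnosis",
      "patterns": [
        "427.31",
        "427.32"
      ],
      "provenance": "Atrial fibrillation/flutter (not part of the AHRQ schema; editable)"
    },
    {
      "name": "cognitive_impairment",
      "kind": "diagnosis",
      "patterns": [
        "290.x",
        "294.x",
        "331.0",
        "331.1",
        "331.2",
        "797"
      ],
      "provenance": "Dementia and cognitive dysfunction (not part of the AHRQ schema; editable)"
    },
    {
      "name": "heart_failure",
      "kind": "diagnosis",
      "patterns": [
        "398.91",
        "402.01",
        "402.11",
        "402.91",
        "404.01",
        "404.03",
        "404.11",
        "404.13",
        "404.91",
        "404.93",
        "428.x"
      ],
      "provenance": "AHRQ comorbidity schema: congestive heart failure"
    },
    {
      "name": "renal_failure",
      "kind": "diagnosis",
      "patterns": [
        "403.01",
        "403.11",
        "403.91",
        "404.02",
        "404.12",
        "404.92",
        "585.x",
        "586",
        "V42.0",
        "V45.1",
        "V56.x"
      ],
      "provenance": "AHRQ comorbidity schema: renal failure"
    },
    {
      "name": "liver_disease",
      "kind": "diagnosis",
      "patterns": [
        "070.32",
        "070.33",
        "070.54",
        "456.0",
        "456.1",
        "456.2x",
        "571.x",
        "572.2",
        "572.3",
        "572.4",
        "572.8"
      ],
      "provenance": "AHRQ comorbidity schema: liver disease"
    },
    {
      "name": "coagulopathy",
      "kind": "diagnosis",
      "patterns": [
        "286.x",
        "287.1",
        "287.3",
        "287.4",
        "287.5"
      ],
      "provenance": "AHRQ comorbidity schema: coagulopathy"
    },
    {
      "name": "cancer",
      "kind": "diagnosis",
      "patterns": [
        "140.x",
        "141.x",
        "142.x",
        "143.x",
        "144.x",
        "145.x",
        "146.x",
        "147.x",
        "148.x",
        "149.x",
        "150.x",
        "151.x",
        "152.x",
        "153.x",
        "154.x",
        "155.x",
        "156.x",
        "157.x",
        "158.x",
        "159.x",
        "160.x",
        "161.x",
        "162.x",
        "163.x",
        "164.x",
        "165.x",
        "166.x",
        "167.x",
        "168.x",
        "169.x",
        "170.x",
        "171.x",
        "172.x",
        "174.x",
        "175.x",
        "176.x",
        "177.x",
        "178.x",
        "179.x",
        "180.x",
        "181.x",
        "182.x",
        "183.x",
        "184.x",
        "185.x",
        "186.x",
        "187.x",
        "188.x",
        "189.x",
        "190.x",
        "191.x",
        "192.x",
        "193.x",
        "194.x",
        "195.x",
        "196.x",
        "197.x",
        "198.x",
        "199.x",
        "200.x",
        "201.x",
        "202.x",
        "203.x",
        "204.x",
        "205.x",
        "206.x",
        "207.x",
        "208.x",
        "238.6"
      ],
      "provenance": "AHRQ comorbidity schema: lymphoma, metastatic cancer and solid tumor without metastasis (non-melanoma skin cancer 173.x excluded)"
    }
  ]
}
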