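{
  "activity": [
    {
      "column": "nurse_id",
      "type": "character",
      "required": true
    },
    {
      "column": "contract_id",
      "type": "character",
      "required": true
    },
    {
      "column": "case_id",
      "type": "character",
      "required": false
    },
    {
      "column": "unit_id",
      "type": "character",
      "required": true
    },
    {
      "column": "date",
      "type": "date",
      "required": true
    },
    {
      "column": "activity_type",
      "type": "enum:care|administrative|teaching|continuous_education|absence",
      "required": true
    },
    {
      "column": "setting",
      "type": "enum:inpatient|outpatient",
      "required": true
    }
  ],
  "nurses": [
    {
      "column": "nurse_id",
      "type": "character",
      "required": true
    },
    {
      "column": "contract_id",
      "type": "character",
      "required": true
    },
    {
      "column": "group",
      "type": "enum:1|2|3|4|5",
      "required": true
    }
  ],
  "working_hours": [
    {
      "column": "nurse_id",
      "type": "character",
      "required": true
    },
    {
      "column": "contract_id",
      "type": "character",
      "required": true
    },
    {
      "column": "date",
      "type": "date",
      "required": true
    },
    {
      "column": "start_time",
      "type": "clock",
      "required": true
    },
    {
      "column": "end_time",
      "type": "clock",
      "required": true
    }
  ],
  "movements": [
    {
      "column": "case_id",
      "type": "character",
      "required": true
    },
    {
      "column": "unit_id",
      "type": "character",
      "required": true
    },
    {
      "column": "event",
      "type": "enum:admission|discharge|transfer",
      "required": true
    },
    {
      "column": "date",
      "type": "date",
      "required": true
    },
    {
      "column": "time",
      "type": "clock",
      "required": true
    },
    {
      "column": "setting",
      "type": "enum:inpatient|outpatient",
      "required": true
    }
  ],
  "discharges": [
    {
      "column": "case_id",
      "type": "character",
      "required": true
    },
    {
      "column": "age_years",
      "type": "numeric",
      "required": true
    },
    {
      "column": "admission_date",
      "type": "date",
      "required": true
    },
    {
      "column": "discharge_date",
      "type": "date",
      "required": true
    },
    {
      "column": "main_dx",
      "type": "icd10",
      "required": true
    },
    {
      "column": "department",
      "type": "character",
      "required": true
    },
    {
      "column": "healthy_newborn",
      "type": "logical",
      "required": false
    }
  ]
}
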