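{
  "title": "all-classes demo template",
  "meta": {
    "record_id": "record_id",
    "enumerator_id": "enumerator_id",
    "survey_date": "survey_date"
  },
  "questions": [
    {
      "id": "consent",
      "rtype": "select_one",
      "prompt": "consent",
      "choices": [
        "yes",
        "no"
      ],
      "section": "main"
    },
    {
      "id": "gender",
      "rtype": "select_one",
      "prompt": "What is your gender?",
      "choices": [
        "male",
        "female"
      ],
      "relevance": {
        "op": "selected",
        "question": "consent",
        "option": "yes"
      },
      "section": "main"
    },
    {
      "id": "resp_dob",
      "rtype": "date",
      "prompt": "What is your birthday?",
      "relevance": {
        "op": "selected",
        "question": "consent",
        "option": "yes"
      },
      "section": "main"
    },
    {
      "id": "resp_age",
      "rtype": "integer",
      "prompt": "What is your age, in years?",
      "relevance": {
        "op": "selected",
        "question": "consent",
        "option": "yes"
      },
      "section": "main"
    },
    {
      "id": "household_size",
      "rtype": "integer",
      "prompt": "household_size",
      "relevance": {
        "op": "selected",
        "question": "consent",
        "option": "yes"
      },
      "section": "main"
    },
    {
      "id": "doctor_visits",
      "rtype": "integer",
      "prompt": "How many times have you seen a doctor in the past month?",
      "relevance": {
        "op": "selected",
        "question": "consent",
        "option": "yes"
      },
      "section": "main"
    },
    {
      "id": "advice_src",
      "rtype": "select_multiple",
      "prompt": "advice_src",
      "choices": [
        "clinic",
        "drugstore",
        "chw",
        "traditional",
        "other",
        "refused",
        "unknown"
      ],
      "relevance": {
        "op": "selected",
        "question": "consent",
        "option": "yes"
      },
      "section": "main"
    },
    {
      "id": "clinic_visit",
      "rtype": "select_one",
      "prompt": "Have you ever been to a health clinic?",
      "choices": [
        "yes",
        "no"
      ],
      "relevance": {
        "op": "selected",
        "question": "consent",
        "option": "yes"
      },
      "section": "main"
    },
    {
      "id": "branch_choice",
      "rtype": "select_one",
      "prompt": "Choose the next section",
      "choices": [
        "clinical",
        "skip_clinical"
      ],
      "relevance": {
        "op": "selected",
        "question": "consent",
        "option": "yes"
      },
      "section": "main"
    },
    {
      "id": "ever_birth",
      "rtype": "select_one",
      "prompt": "Have you ever given birth?",
      "choices": [
        "yes",
        "no"
      ],
      "relevance": {
        "op": "selected",
        "question": "consent",
        "option": "yes"
      },
      "section": "main"
    },
    {
      "id": "num_births_1",
      "rtype": "integer",
      "prompt": "How many times have you given birth?",
      "relevance": {
        "op": "and",
        "args": [
          {
            "op": "selected",
            "question": "consent",
            "option": "yes"
          },
          {
            "op": "selected",
            "question": "ever_birth",
            "option": "yes"
          }
        ]
      },
      "section": "main"
    },
    {
      "id": "postnatal_care",
      "rtype": "select_one",
      "prompt": "Did you receive postnatal care?",
      "choices": [
        "yes",
        "no"
      ],
      "relevance": {
        "op": "and",
        "args": [
          {
            "op": "selected",
            "question": "consent",
            "option": "yes"
          },
          {
            "op": "selected",
            "question": "ever_birth",
            "option": "yes"
          }
        ]
      },
      "required": true,
      "section": "main"
    },
    {
      "id": "num_births_2",
      "rtype": "integer",
      "prompt": "How many times have you given birth? (verification)",
      "relevance": {
        "op": "and",
        "args": [
          {
            "op": "selected",
            "question": "consent",
            "option": "yes"
          },
          {
            "op": "selected",
            "question": "ever_birth",
            "option": "yes"
          }
        ]
      },
      "section": "main"
    }
  ],
  "rules": [
    {
      "rule_id": "d1",
      "rule_class": "required_skip",
      "params": {
        "question": "postnatal_care"
      }
    },
    {
      "rule_id": "d2",
      "rule_class": "illogical_multi",
      "params": {
        "conditions": [
          {
            "question": "gender",
            "equals": "male"
          },
          {
            "question": "ever_birth",
            "equals": "yes"
          }
        ]
      }
    },
    {
      "rule_id": "d3",
      "rule_class": "illogical_single",
      "params": {
        "question": "advice_src",
        "exclusive": ["refused", "unknown"],
        "substantive": ["clinic", "drugstore", "chw", "traditional", "other"]
      }
    },
    {
      "rule_id": "d4",
      "rule_class": "redundancy",
      "params": {
        "qa": "num_births_1",
        "qb": "num_births_2",
        "comparator": "exact"
      }
    },
    {
      "rule_id": "d5",
      "rule_class": "manual_skip",
      "params": {
        "branch_question": "branch_choice",
        "cases": [
          {
            "when": {
              "question": "clinic_visit",
              "equals": "yes"
            },
            "correct": "clinical"
          },
          {
            "when": {
              "question": "clinic_visit",
              "equals": "no"
            },
            "correct": "skip_clinical"
          }
        ]
      }
    },
    {
      "rule_id": "d6",
      "rule_class": "minmax_removed",
      "params": {
        "question": "household_size",
        "min": 1,
        "max": 30
      }
    },
    {
      "rule_id": "d7",
      "rule_class": "manual_calc",
      "params": {
        "target": "resp_age",
        "derive": {
          "type": "age_years",
          "birthdate": "resp_dob"
        },
        "tolerance": 0
      }
    },
    {
      "rule_id": "d8",
      "rule_class": "invalid_type",
      "params": {
        "question": "doctor_visits",
        "expected": "integer"
      }
    }
  ]
}
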