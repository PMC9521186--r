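version: "1.0"
date_window:
  start: "2000-01-01"
  end: "2019-12-31"
code_systems:
  icd9_proc: "^\\d{2}\\.\\d{1,2}$"
  icd9_diag: "^[EV]?\\d{3}(\\.\\d{1,2})?$"
  atc: "^[A-Z]\\d{2}([A-Z]{2}(\\d{2})?)?$"
  aic: "^\\d{9}$"
  drg: "^\\d{3}$"
tables:
  hospital_discharge:
    mandatory: true
    fields:
      - {name: person_id, type: identifier}
      - {name: admission_date, type: date, window: true}
      - {name: discharge_date, type: date, window: true}
      - {name: hospital, type: category}
      - {name: drg, type: code, system: drg}
      - {name: diag1, type: code, system: icd9_diag}
      - {name: diag2, type: code, system: icd9_diag}
      - {name: diag3, type: code, system: icd9_diag}
      - {name: proc1, type: code, system: icd9_proc}
      - {name: proc2, type: code, system: icd9_proc}
      - {name: proc3, type: code, system: icd9_proc}
      - {name: proc4, type: code, system: icd9_proc}
      - {name: proc5, type: code, system: icd9_proc}
      - {name: proc6, type: code, system: icd9_proc}
  drug_dispensing:
    mandatory: true
    fields:
      - {name: person_id, type: identifier}
      - {name: dispensing_date, type: date, window: true}
      - {name: atc, type: code, system: atc}
      - {name: aic, type: code, system: aic}
      - {name: n_packages, type: quantity}
  inhabitant:
    mandatory: true
    fields:
      - {name: person_id, type: identifier}
      - {name: sex, type: category}
      - {name: birth_date, type: date, window: false}
      - {name: registration_start, type: date, window: false}
      - {name: registration_end, type: date, window: false}
  mortality:
    mandatory: true
    fields:
      - {name: person_id, type: identifier}
      - {name: death_date, type: date, window: true}
      - {name: cause_icd9, type: code, system: icd9_diag}
  emergency:
    mandatory: false
    fields:
      - {name: person_id, type: identifier}
      - {name: admission_date, type: date, window: true}
      - {name: discharge_date, type: date, window: true}
      - {name: reason, type: category}
  exemption:
    mandatory: false
    fields:
      - {name: person_id, type: identifier}
      - {name: exemption_code, type: category}
      - {name: start_date, type: date, window: true}
  outpatient:
    mandatory: false
    fields:
      - {name: person_id, type: identifier}
      - {name: test_date, type: date, window: true}
      - {name: test_code, type: category}
      - {name: lab, type: category}
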