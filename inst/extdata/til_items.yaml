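# Daily therapeutic-intensity-level (TIL) summary-score item table.
# Categories of ICP-directed therapy; each level maps to a point weight.
# The maximum achievable daily sum over all categories must equal 38, which
# is enforced when the table is loaded.
scale: til-summary
version: 1
items:
  - name: positioning
    levels:
      - {level: 0, points: 0, label: "flat"}
      - {level: 1, points: 1, label: "head elevation / reverse Trendelenburg"}
  - name: sedation
    levels:
      - {level: 0, points: 0, label: "none"}
      - {level: 1, points: 1, label: "low-dose sedation"}
      - {level: 2, points: 2, label: "high-dose sedation"}
      - {level: 3, points: 5, label: "metabolic suppression (barbiturate coma)"}
  - name: neuromuscular_blockade
    levels:
      - {level: 0, points: 0, label: "none"}
      - {level: 1, points: 3, label: "paralysis for ICP control"}
  - name: csf_drainage
    levels:
      - {level: 0, points: 0, label: "none"}
      - {level: 1, points: 2, label: "low-volume drainage (< 120 ml/day)"}
      - {level: 2, points: 3, label: "high-volume drainage"}
  - name: cpp_management
    levels:
      - {level: 0, points: 0, label: "none"}
      - {level: 1, points: 1, label: "fluid loading"}
      - {level: 2, points: 2, label: "low-dose vasopressor"}
      - {level: 3, points: 3, label: "high-dose vasopressor"}
  - name: ventilation
    levels:
      - {level: 0, points: 0, label: "normocapnia"}
      - {level: 1, points: 1, label: "mild hypocapnia"}
      - {level: 2, points: 2, label: "moderate hypocapnia"}
      - {level: 3, points: 4, label: "intensive hypocapnia"}
  - name: hyperosmolar_therapy
    levels:
      - {level: 0, points: 0, label: "none"}
      - {level: 1, points: 2, label: "low-dose mannitol or hypertonic saline"}
      - {level: 2, points: 3, label: "high-dose single agent"}
      - {level: 3, points: 6, label: "high-dose combined agents"}
  - name: temperature_control
    levels:
      - {level: 0, points: 0, label: "none"}
      - {level: 1, points: 1, label: "fever control"}
      - {level: 2, points: 2, label: "mild hypothermia (35-36 C)"}
      - {level: 3, points: 5, label: "deep hypothermia (< 35 C)"}
  - name: surgery
    levels:
      - {level: 0, points: 0, label: "none"}
      - {level: 1, points: 4, label: "mass-lesion evacuation"}
      - {level: 2, points: 8, label: "decompressive craniectomy"}
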