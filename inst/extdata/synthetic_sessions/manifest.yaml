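sessions:
- session_id: s01
  participant_id: p01
  script_version: 1
  duration: 600.0
  annotators:
  - s01_annotator1.txt
  - s01_annotator2.txt
  - s01_annotator3.txt
  devices:
  - s01_phone1.csv
  - s01_phone2.csv
- session_id: s02
  participant_id: p02
  script_version: 5
  duration: 600.0
  annotators:
  - s02_annotator1.txt
  - s02_annotator2.txt
  - s02_annotator3.txt
  devices:
  - s02_phone1.csv
  - s02_phone2.csv
- session_id: s03
  participant_id: p03
  script_version: 5
  duration: 600.0
  annotators:
  - s03_annotator1.txt
  - s03_annotator2.txt
  - s03_annotator3.txt
  devices:
  - s03_phone1.csv
  - s03_phone2.csv
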