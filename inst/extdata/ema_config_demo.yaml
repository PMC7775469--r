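user_id: user_id
timestamp: timestamp
# quote the labels: bare Y/N are YAML booleans
q1_map:
  "Y": 1
  "N": 0
vas_scale: [0, 100]
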