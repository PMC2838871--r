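{
  "name": "M32K25",
  "bond": 3.8,
  "fragments": [
    {"letter": "A", "phi1": 122.4, "phi2": 119.4, "theta": -164.2},
    {"letter": "B", "phi1": 129.8, "phi2": 135.6, "theta": -176.6},
    {"letter": "C", "phi1": 117.1, "phi2": 111.0, "theta": -142.2},
    {"letter": "D", "phi1": 118.4, "phi2": 126.9, "theta": -146.1},
    {"letter": "E", "phi1": 116.7, "phi2": 138.6, "theta": 168.7},
    {"letter": "F", "phi1": 115.6, "phi2": 112.9, "theta": -117.9},
    {"letter": "G", "phi1": 135.3, "phi2": 118.6, "theta": -148.5},
    {"letter": "H", "phi1": 120.1, "phi2": 114.3, "theta": -90.7},
    {"letter": "I", "phi1": 133.6, "phi2": 117.1, "theta": -120.8},
    {"letter": "J", "phi1": 115.9, "phi2": 91.4, "theta": -134.6},
    {"letter": "K", "phi1": 119.7, "phi2": 90.4, "theta": -105.9},
    {"letter": "L", "phi1": 110.0, "phi2": 90.8, "theta": -158.8},
    {"letter": "M", "phi1": 110.0, "phi2": 100.8, "theta": 177.0},
    {"letter": "N", "phi1": 90.1, "phi2": 138.2, "theta": 19.6},
    {"letter": "O", "phi1": 92.4, "phi2": 91.2, "theta": -127.4},
    {"letter": "P", "phi1": 91.8, "phi2": 96.7, "theta": -104.8},
    {"letter": "Q", "phi1": 95.9, "phi2": 117.7, "theta": 136.0},
    {"letter": "R", "phi1": 94.5, "phi2": 112.6, "theta": 115.0},
    {"letter": "S", "phi1": 96.3, "phi2": 94.7, "theta": 112.0},
    {"letter": "T", "phi1": 93.0, "phi2": 92.8, "theta": 83.1},
    {"letter": "U", "phi1": 91.4, "phi2": 90.7, "theta": 49.8},
    {"letter": "V", "phi1": 93.3, "phi2": 89.1, "theta": 68.3},
    {"letter": "W", "phi1": 93.8, "phi2": 105.2, "theta": 32.3},
    {"letter": "X", "phi1": 111.4, "phi2": 94.6, "theta": 21.8},
    {"letter": "Y", "phi1": 89.0, "phi2": 95.1, "theta": -54.4}
  ]
}
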