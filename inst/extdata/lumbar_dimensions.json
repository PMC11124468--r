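{
  "schema": "pedspine-dimensions-v1",
  "units": "mm",
  "dimension_names": ["AVBH", "PVBH", "SVBL", "IVBL", "SVBW", "MVBW", "IVBW"],
  "groups": [
    {
      "index": 1,
      "label": "newborn (0 yrs)",
      "specimen_count": 23,
      "levels": {
        "L1": [6.9, 7.2, 7.6, 7.7, 14.5, 15.1, 14.7],
        "L2": [7, 7.2, 7.6, 7.7, 14.6, 15.1, 14.6],
        "L3": [7.2, 7.2, 7.7, 7.7, 14.6, 15.2, 14.6],
        "L4": [7.1, 7.3, 7.8, 7.8, 14.8, 15.4, 14.9],
        "L5": [7, 7.3, 7.8, 7.8, 14.8, 15.4, 14.9]
      }
    },
    {
      "index": 2,
      "label": "infant (0-1 yrs)",
      "specimen_count": 12,
      "levels": {
        "L1": [8.4, 8.6, 9.4, 9.4, 17.3, 17.6, 17.2],
        "L2": [8.4, 8.6, 9.5, 9.6, 17.3, 17.8, 17.6],
        "L3": [8.5, 8.7, 9.5, 9.5, 17.4, 17.8, 17.4],
        "L4": [8.5, 8.7, 9.6, 9.6, 17.5, 17.9, 17.6],
        "L5": [8.4, 8.7, 9.6, 9.6, 17.6, 18, 17.7]
      }
    },
    {
      "index": 3,
      "label": "toddler (1-3 yrs)",
      "specimen_count": 9,
      "levels": {
        "L1": [11.7, 11.2, 17.4, 16.3, 28.9, 27.6, 27.2],
        "L2": [11.7, 11.1, 17.2, 16.3, 28.7, 27.4, 27.2],
        "L3": [12.1, 11.1, 17.5, 16.2, 29.2, 27.6, 27],
        "L4": [12.5, 11.3, 17.7, 16.2, 29.5, 27.7, 26.9],
        "L5": [12.5, 10.8, 17.2, 16.3, 28.6, 27.4, 27.1]
      }
    },
    {
      "index": 4,
      "label": "middle childhood (4-7 yrs)",
      "specimen_count": 7,
      "levels": {
        "L1": [16.1, 16.3, 20.9, 22.6, 31.4, 32.2, 33.9],
        "L2": [17.6, 15.9, 22, 23.2, 33, 33.4, 34.9],
        "L3": [18.5, 16.1, 22.9, 24.5, 34.4, 35.1, 36.8],
        "L4": [17, 14.7, 23.2, 24.7, 34.8, 35.4, 37.1],
        "L5": [16.7, 13.9, 24.9, 23.1, 36.5, 34.8, 34]
      }
    },
    {
      "index": 5,
      "label": "preadolescent (8-12 yrs)",
      "specimen_count": 6,
      "levels": {
        "L1": [18.9, 18.3, 24.6, 25.6, 32.8, 32.5, 34.1],
        "L2": [20.3, 19.9, 26, 28.5, 34.7, 35.5, 38],
        "L3": [23, 18.2, 28.8, 27.4, 38.4, 36.6, 36.5],
        "L4": [19.8, 16.5, 28.8, 28, 38.4, 37, 37.3],
        "L5": [20.3, 16.3, 28.3, 26.5, 37.8, 35.7, 35.3]
      }
    }
  ]
}
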