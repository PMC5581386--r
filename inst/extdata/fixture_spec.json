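{
  "respondents": 972,
  "consented": 961,
  "birth": 618,
  "health": 895,
  "fever": 325,
  "diarrhea": 202,
  "errors": {
    "r1": 19,
    "r2": 10,
    "r3": 84,
    "r4": 10,
    "r5": 2
  },
  "ticks": [25, 14, 45],
  "enumerators": ["2", "3", "4", "5", "6", "7"],
  "days": 46,
  "start_date": "2016-04-12",
  "allocation": {
    "N": [
      [458, 465, 415],
      [452, 382, 334],
      [605, 506, 393],
      [386, 364, 286],
      [552, 528, 436],
      [512, 380, 363]
    ],
    "E": [
      [14, 2, 5],
      [13, 3, 6],
      [17, 9, 5],
      [7, 6, 3],
      [14, 5, 1],
      [7, 6, 2]
    ],
    "periods": [
      [0, 14],
      [15, 29],
      [30, 45]
    ]
  }
}
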