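[
  {"qid":"q01","text":"Does the input mention anything related to color?","tags":"visual"},
  {"qid":"q02","text":"Does the input describe a visual experience or scene?","tags":"visual"},
  {"qid":"q03","text":"Does the input describe a physical environment?","tags":"visuospatial"},
  {"qid":"q04","text":"Does the input contain visuospatial information?","tags":"visuospatial"},
  {"qid":"q05","text":"Does the input describe relative spatial positions of objects?","tags":"visuospatial"},
  {"qid":"q06","text":"Does the input mention a specific location?","tags":"visuospatial"},
  {"qid":"q07","text":"Does the input describe a journey?","tags":"visuospatial"},
  {"qid":"q08","text":"Does the input describe physical movement of a person?","tags":"motor"},
  {"qid":"q09","text":"Does the input mention a tactile sensation?","tags":"tactile"},
  {"qid":"q10","text":"Does the input describe a texture or surface feel?","tags":"tactile"},
  {"qid":"q11","text":"Does the input mention temperature or a thermal sensation?","tags":"tactile"},
  {"qid":"q12","text":"Does the input mention pain or physical discomfort?","tags":"tactile"},
  {"qid":"q13","text":"Does the input contain a number or a quantity?","tags":"numeric"},
  {"qid":"q14","text":"Does the input involve counting or arithmetic?","tags":"numeric"},
  {"qid":"q15","text":"Does the input mention a measurement or a unit?","tags":"numeric"},
  {"qid":"q16","text":"Does the input mention time?","tags":"numeric"},
  {"qid":"q17","text":"Does the input describe planning or a plan for the future?","tags":"planning"},
  {"qid":"q18","text":"Does the input describe a goal or an intention?","tags":"planning"},
  {"qid":"q19","text":"Does the input describe a decision being made?","tags":"planning"},
  {"qid":"q20","text":"Does the input describe a sequence of steps or instructions?","tags":"planning"},
  {"qid":"q21","text":"Does the input involve communication between people?","tags":"communication"},
  {"qid":"q22","text":"Does the input include dialogue?","tags":"communication"},
  {"qid":"q23","text":"Does the input describe a social interaction?","tags":"communication"},
  {"qid":"q24","text":"Does the input mention a relationship between people?","tags":"communication"},
  {"qid":"q25","text":"Does the input describe speech or the act of speaking?","tags":"communication"},
  {"qid":"q26","text":"Does the input mention an emotion or a feeling?","tags":"abstract"},
  {"qid":"q27","text":"Does the input describe a belief or a value?","tags":"abstract"},
  {"qid":"q28","text":"Does the input involve a moral or ethical judgement?","tags":"abstract"},
  {"qid":"q29","text":"Does the input describe an abstract concept?","tags":"abstract"},
  {"qid":"q30","text":"Does the input mention a person's name?","tags":"lexical"},
  {"qid":"q31","text":"Does the input contain a proper noun?","tags":"lexical"},
  {"qid":"q32","text":"Does the input include technical or specialized terminology?","tags":"lexical"},
  {"qid":"q33","text":"Does the input contain a cultural reference?","tags":"lexical"},
  {"qid":"q34","text":"Does the input mention food or eating?","tags":"semantic"},
  {"qid":"q35","text":"Does the input mention sound or an auditory experience?","tags":"semantic"}
]
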