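{
  "id": "es_castilian_31",
  "comment": "Castilian Spanish phoneme inventory, broad transcription, X-SAMPA-like ASCII symbols. Numeric ids are assigned by listed order (1-based). Vowels carry place/height/rounding; consonants carry place/manner/voicing.",
  "entries": [
    {"symbol": "a",  "class": "vowel",     "place": "central",    "height": "open",  "rounding": "unrounded"},
    {"symbol": "e",  "class": "vowel",     "place": "front",      "height": "mid",   "rounding": "unrounded"},
    {"symbol": "i",  "class": "vowel",     "place": "front",      "height": "close", "rounding": "unrounded"},
    {"symbol": "o",  "class": "vowel",     "place": "back",       "height": "mid",   "rounding": "rounded"},
    {"symbol": "u",  "class": "vowel",     "place": "back",       "height": "close", "rounding": "rounded"},
    {"symbol": "p",  "class": "consonant", "place": "bilabial",   "manner": "plosive",     "voicing": "voiceless"},
    {"symbol": "b",  "class": "consonant", "place": "bilabial",   "manner": "plosive",     "voicing": "voiced"},
    {"symbol": "t",  "class": "consonant", "place": "dental",     "manner": "plosive",     "voicing": "voiceless"},
    {"symbol": "d",  "class": "consonant", "place": "dental",     "manner": "plosive",     "voicing": "voiced"},
    {"symbol": "k",  "class": "consonant", "place": "velar",      "manner": "plosive",     "voicing": "voiceless"},
    {"symbol": "g",  "class": "consonant", "place": "velar",      "manner": "plosive",     "voicing": "voiced"},
    {"symbol": "tS", "class": "consonant", "place": "palatal",    "manner": "affricate",   "voicing": "voiceless"},
    {"symbol": "f",  "class": "consonant", "place": "labiodental","manner": "fricative",   "voicing": "voiceless"},
    {"symbol": "T",  "class": "consonant", "place": "dental",     "manner": "fricative",   "voicing": "voiceless"},
    {"symbol": "s",  "class": "consonant", "place": "alveolar",   "manner": "fricative",   "voicing": "voiceless"},
    {"symbol": "z",  "class": "consonant", "place": "alveolar",   "manner": "fricative",   "voicing": "voiced"},
    {"symbol": "S",  "class": "consonant", "place": "palatal",    "manner": "fricative",   "voicing": "voiceless"},
    {"symbol": "x",  "class": "consonant", "place": "velar",      "manner": "fricative",   "voicing": "voiceless"},
    {"symbol": "jj", "class": "consonant", "place": "palatal",    "manner": "fricative",   "voicing": "voiced"},
    {"symbol": "B",  "class": "consonant", "place": "bilabial",   "manner": "fricative",   "voicing": "voiced"},
    {"symbol": "D",  "class": "consonant", "place": "dental",     "manner": "fricative",   "voicing": "voiced"},
    {"symbol": "G",  "class": "consonant", "place": "velar",      "manner": "fricative",   "voicing": "voiced"},
    {"symbol": "m",  "class": "consonant", "place": "bilabial",   "manner": "nasal",       "voicing": "voiced"},
    {"symbol": "n",  "class": "consonant", "place": "alveolar",   "manner": "nasal",       "voicing": "voiced"},
    {"symbol": "J",  "class": "consonant", "place": "palatal",    "manner": "nasal",       "voicing": "voiced"},
    {"symbol": "l",  "class": "consonant", "place": "alveolar",   "manner": "lateral",     "voicing": "voiced"},
    {"symbol": "L",  "class": "consonant", "place": "palatal",    "manner": "lateral",     "voicing": "voiced"},
    {"symbol": "rr", "class": "consonant", "place": "alveolar",   "manner": "trill",       "voicing": "voiced"},
    {"symbol": "r",  "class": "consonant", "place": "alveolar",   "manner": "tap",         "voicing": "voiced"},
    {"symbol": "j",  "class": "consonant", "place": "palatal",    "manner": "approximant", "voicing": "voiced"},
    {"symbol": "w",  "class": "consonant", "place": "labiovelar", "manner": "approximant", "voicing": "voiced"}
  ]
}
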