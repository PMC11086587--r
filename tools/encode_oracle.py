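#!/usr/bin/env python
"""Independent brute-force form-variable encoder.

Reads an inventory JSON and a lexicon CSV and writes the expected
form-variable matrix for the packaged fixture.  Deliberately written from
the variable definitions alone (no shared code with the R implementation)
so the two can serve as mutual checks.

Usage: python tools/encode_oracle.py inv.json lexicon.csv out.csv
"""
import csv
import json
import sys

PLACES_C = ["bilabial", "labiodental", "dental", "alveolar", "palatal",
            "velar", "labiovelar"]
MANNERS = ["plosive", "nasal", "fricative", "affricate", "lateral",
           "trill", "tap", "approximant"]
VOICINGS = ["voiced", "voiceless"]
PLACES_V = ["front", "central", "back"]
HEIGHTS = ["open", "mid", "close"]
ROUNDINGS = ["rounded", "unrounded"]
CATS = PLACES_C + MANNERS + VOICINGS + PLACES_V + HEIGHTS + ROUNDINGS


def features(entry):
    """Set of feature categories a phoneme belongs to (voicing: consonants only)."""
    f = set()
    if entry["class"] == "vowel":
        f.update([entry["place"], entry["height"], entry["rounding"]])
    else:
        f.update([entry["place"], entry["manner"], entry["voicing"]])
    return f


def main(inv_path, lex_path, out_path):
    with open(inv_path) as fh:
        inv = {e["symbol"]: (i + 1, e)
               for i, e in enumerate(json.load(fh)["entries"])}
    header = (["word", "length_letters", "n_phonemes", "n_syllables",
               "initial_phoneme_id", "final_phoneme_id"]
              + ["n_" + c for c in CATS]
              + ["ini_" + c for c in CATS]
              + ["fin_" + c for c in CATS]
              + ["stress_initial", "stress_medial", "stress_final"])
    rows = []
    with open(lex_path, encoding="utf-8") as fh:
        for rec in csv.DictReader(fh):
            toks = rec["transcription"].split()
            phon = [t for t in toks if t != "."]
            n_syll = toks.count(".") + 1
            stress = int(rec["stress_syllable"])
            assert 1 <= stress <= n_syll, rec["word"]
            counts = {c: 0 for c in CATS}
            for p in phon:
                for c in features(inv[p][1]):
                    counts[c] += 1
            ini = features(inv[phon[0]][1])
            fin = features(inv[phon[-1]][1])
            if stress == n_syll:
                spos = "final"
            elif stress == 1:
                spos = "initial"
            else:
                spos = "medial"
            row = ([rec["word"], len(rec["word"]), len(phon), n_syll,
                    inv[phon[0]][0], inv[phon[-1]][0]]
                   + [counts[c] for c in CATS]
                   + [int(c in ini) for c in CATS]
                   + [int(c in fin) for c in CATS]
                   + [int(spos == s) for s in ("initial", "medial", "final")])
            rows.append(row)
    with open(out_path, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(header)
        w.writerows(rows)


if __name__ == "__main__":
    main(*sys.argv[1:4])
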