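#!/usr/bin/env python
"""Independent zero-order Takagi-Sugeno evaluator.

Reads a rule-base JSON (the package's serialization format) and a CSV of
crisp inputs (one column per linguistic variable), evaluates the system with
numpy, and writes a one-column CSV of defuzzified outputs. Used as a
cross-language oracle in the test suite: it shares no code with the R
implementation.
"""
import csv
import json
import sys

import numpy as np


def membership(term, x):
    xs = np.asarray(term["x"], dtype=float)
    ms = np.asarray(term["m"], dtype=float)
    out = np.interp(x, xs, ms, left=term["left"], right=term["right"])
    return out


def main(rulebase_path, inputs_path, out_path):
    with open(rulebase_path) as fh:
        base = json.load(fh)
    with open(inputs_path) as fh:
        reader = csv.DictReader(fh)
        rows = list(reader)
    cols = {k: np.array([float(r[k]) for r in rows]) for k in rows[0]}
    n = len(rows)

    strengths = []
    values = []
    for rule in base["rules"]:
        degs = []
        for clause in rule["antecedent"]:
            term = base["variables"][clause["variable"]]["terms"][clause["term"]]
            degs.append(membership(term, cols[clause["variable"]]))
        degs = np.vstack(degs)
        if base["tnorm"] == "min":
            strengths.append(degs.min(axis=0))
        else:
            strengths.append(degs.prod(axis=0))
        values.append(rule["consequent_value"])
    strengths = np.vstack(strengths)
    values = np.asarray(values)
    total = strengths.sum(axis=0)
    out = np.full(n, base["zero_strength_output"], dtype=float)
    fired = total > 0
    out[fired] = (strengths[:, fired] * values[:, None]).sum(axis=0) / total[fired]

    with open(out_path, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["output"])
        for v in out:
            w.writerow([repr(float(v))])


if __name__ == "__main__":
    main(*sys.argv[1:4])
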