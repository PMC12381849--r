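"""Atom-level SMARTS matching backend.

Reads molecules from an SDF file and a JSON list of SMARTS patterns,
then writes, for every molecule, the 1-based indices of atoms covered by
each pattern. Called as:

    python smarts_match.py <molecules.sdf> <patterns.json> <out.json>

patterns.json: {"smarts": ["...", ...], "validate_only": false}
out.json: {"valid": [true, ...],
           "matches": [[[a1, a2, ...], ...pattern], ...molecule]}

Matching uses RDKit with its default aromaticity model; sanitization
failures for a molecule yield null in place of its match lists.
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def main(sdf_path, json_in, json_out):
    with open(json_in) as fh:
        req = json.load(fh)
    patterns = [Chem.MolFromSmarts(s) for s in req["smarts"]]
    valid = [p is not None for p in patterns]
    out = {"valid": valid, "matches": []}
    if not req.get("validate_only", False):
        supplier = Chem.SDMolSupplier(sdf_path, removeHs=False,
                                      sanitize=True)
        for mol in supplier:
            if mol is None:
                out["matches"].append(None)
                continue
            per_mol = []
            for patt, ok in zip(patterns, valid):
                if not ok:
                    per_mol.append([])
                    continue
                hits = mol.GetSubstructMatches(patt, maxMatches=100000)
                atoms = sorted({a + 1 for match in hits for a in match})
                per_mol.append(atoms)
            out["matches"].append(per_mol)
    with open(json_out, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], sys.argv[3])
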