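"""Batch chemistry helper for the maskmol R package.

Called as:  python chemtool.py <op> <input.json> <output.json>

All heavy-atom chemistry (SMILES parsing, molecule assembly, sanitization,
canonicalization, physiochemical descriptors) is delegated to RDKit so that
the R side never re-implements a chemistry primitive.  Every op is batch
oriented: one process start-up per call, arbitrarily many molecules.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, rdMolDescriptors
from rdkit import DataStructs
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

CHIRALITY_TO_STR = {
    Chem.ChiralType.CHI_UNSPECIFIED: "unspecified",
    Chem.ChiralType.CHI_TETRAHEDRAL_CW: "cw",
    Chem.ChiralType.CHI_TETRAHEDRAL_CCW: "ccw",
}
STR_TO_CHIRALITY = {
    "unspecified": Chem.ChiralType.CHI_UNSPECIFIED,
    "cw": Chem.ChiralType.CHI_TETRAHEDRAL_CW,
    "ccw": Chem.ChiralType.CHI_TETRAHEDRAL_CCW,
    "other": Chem.ChiralType.CHI_OTHER,
}
BOND_TO_STR = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
    Chem.BondType.TRIPLE: "triple",
    Chem.BondType.AROMATIC: "aromatic",
}
STR_TO_BOND = {v: k for k, v in BOND_TO_STR.items()}


def parse_one(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "error": "parse/sanitize failure", "canonical": None}
    atoms = {"symbol": [], "num_h": [], "charge": [], "chirality": [],
             "in_ring": [], "aromatic": []}
    for a in mol.GetAtoms():
        atoms["symbol"].append(a.GetSymbol())
        atoms["num_h"].append(a.GetTotalNumHs())
        atoms["charge"].append(a.GetFormalCharge())
        atoms["chirality"].append(CHIRALITY_TO_STR.get(a.GetChiralTag(), "other"))
        atoms["in_ring"].append(bool(a.IsInRing()))
        atoms["aromatic"].append(bool(a.GetIsAromatic()))
    bonds = {"i": [], "j": [], "type": []}
    for b in mol.GetBonds():
        i, j = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
        if i > j:
            i, j = j, i
        bonds["i"].append(i)
        bonds["j"].append(j)
        bonds["type"].append(BOND_TO_STR.get(b.GetBondType(), "single"))
    return {"ok": True, "error": None, "canonical": Chem.MolToSmiles(mol),
            "atoms": atoms, "bonds": bonds}


def write_one(g):
    try:
        mol = Chem.RWMol()
        n = len(g["symbol"])
        for k in range(n):
            a = Chem.Atom(str(g["symbol"][k]))
            a.SetNoImplicit(True)  # stored hydrogen count is authoritative
            a.SetNumExplicitHs(int(g["num_h"][k]))
            a.SetFormalCharge(int(g["charge"][k]))
            a.SetChiralTag(STR_TO_CHIRALITY[str(g["chirality"][k])])
            a.SetIsAromatic(bool(g["aromatic"][k]))
            mol.AddAtom(a)
        for i, j, t in zip(g["bond_i"], g["bond_j"], g["bond_type"]):
            mol.AddBond(int(i), int(j), STR_TO_BOND[str(t)])
        m = mol.GetMol()
        Chem.SanitizeMol(m)
        return Chem.MolToSmiles(m)
    except Exception:
        return None


def canon_one(smi):
    mol = Chem.MolFromSmiles(smi)
    return None if mol is None else Chem.MolToSmiles(mol)


DESCRIPTOR_FUNS = {
    "BertzCT": Descriptors.BertzCT,
    "MolLogP": Crippen.MolLogP,
    "MolWt": Descriptors.MolWt,
    "TPSA": Descriptors.TPSA,
    "NumHAcceptors": rdMolDescriptors.CalcNumHBA,
    "NumHDonors": rdMolDescriptors.CalcNumHBD,
    "NumRotatableBonds": rdMolDescriptors.CalcNumRotatableBonds,
    "NumAliphaticRings": rdMolDescriptors.CalcNumAliphaticRings,
    "NumAromaticRings": rdMolDescriptors.CalcNumAromaticRings,
}


def main():
    op, fin, fout = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(fin) as fh:
        payload = json.load(fh)

    if op == "ping":
        out = {"ok": True}
    elif op == "parse":
        out = {"results": [parse_one(s) for s in payload["smiles"]]}
    elif op == "write":
        out = {"smiles": [write_one(g) for g in payload["graphs"]]}
    elif op == "canon":
        out = {"canonical": [canon_one(s) for s in payload["smiles"]]}
    elif op == "descr":
        vals = {k: [] for k in DESCRIPTOR_FUNS}
        ok = []
        for s in payload["smiles"]:
            mol = Chem.MolFromSmiles(s)
            ok.append(mol is not None)
            for k, f in DESCRIPTOR_FUNS.items():
                vals[k].append(float(f(mol)) if mol is not None else None)
        out = {"ok": ok, "descriptors": vals}
    elif op == "simmax":
        # per-molecule maximum Tanimoto similarity to the rest of the sample
        def scalar(x, default):
            if x is None:
                return default
            return int(x[0]) if isinstance(x, list) else int(x)

        radius = scalar(payload.get("radius"), 2)
        nbits = scalar(payload.get("n_bits"), 2048)
        gen = AllChem.GetMorganGenerator(radius=radius, fpSize=nbits)
        mols = [Chem.MolFromSmiles(s) for s in payload["smiles"]]
        fps = [gen.GetFingerprint(m) if m is not None else None for m in mols]
        keep = [f for f in fps if f is not None]
        res = []
        for f in fps:
            if f is None or len(keep) < 2:
                res.append(None)
                continue
            sims = DataStructs.BulkTanimotoSimilarity(f, keep)
            sims = sorted(sims, reverse=True)
            # drop the self-similarity (always 1.0, appears once)
            res.append(float(sims[1]) if len(sims) > 1 else None)
        out = {"simmax": res}
    else:
        raise SystemExit("unknown op: " + op)

    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
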