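"""Batch RDKit worker for the ToxConsensus R package.

Invoked as:  python rdkit_bridge.py <task> <input.json> <output.json>

Every task reads one JSON payload and writes one JSON response; all
molecule-level chemistry (parsing, canonical SMILES, fingerprints with
bit->atom correspondence, SMARTS matching, depiction) lives here so the
R side never needs a cheminformatics stack of its own.  Atom indices are
0-based heavy-atom indices of the canonical molecule.
"""

import json
import sys
import math

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Draw
from rdkit.Chem.Draw import rdMolDraw2D

RDLogger.DisableLog("rdApp.*")


# ---------------------------------------------------------------- utilities

def _largest_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) <= 1:
        return mol
    return max(frags, key=lambda m: m.GetNumHeavyAtoms())


def _standardize_one(smi):
    """Parse, keep the largest covalent fragment, canonicalize.

    Stereochemistry present in the input is retained (canonical isomeric
    SMILES); no tautomer canonicalization is applied.
    """
    if smi is None or not str(smi).strip():
        return {"ok": False, "raw": smi, "error": "empty SMILES"}
    smi = str(smi).strip()
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "raw": smi, "error": "unparsable SMILES"}
    mol = _largest_fragment(mol)
    try:
        Chem.SanitizeMol(mol)
    except Exception as e:  # pragma: no cover - rdkit raises rarely here
        return {"ok": False, "raw": smi, "error": "sanitization failed: %s" % e}
    can = Chem.MolToSmiles(mol)
    if mol.GetNumHeavyAtoms() < 1:
        return {"ok": False, "raw": smi, "error": "no heavy atoms"}
    return {"ok": True, "raw": smi, "canonical": can,
            "n_atoms": mol.GetNumHeavyAtoms()}


def task_standardize(payload):
    return [_standardize_one(s) for s in payload["smiles"]]


# ------------------------------------------------------------- fingerprints

def _morgan(mol, radius, nbits):
    info = {}
    fp = AllChem.GetMorganFingerprintAsBitVect(
        mol, int(radius), nBits=int(nbits), bitInfo=info)
    bits = sorted(fp.GetOnBits())
    amap = {}
    for bit, envs in info.items():
        occ = []
        for (center, rad) in envs:
            if rad == 0:
                occ.append([int(center)])
                continue
            env = Chem.FindAtomEnvironmentOfRadiusN(mol, rad, center)
            atoms = set([center])
            for bidx in env:
                b = mol.GetBondWithIdx(bidx)
                atoms.add(b.GetBeginAtomIdx())
                atoms.add(b.GetEndAtomIdx())
            occ.append(sorted(int(a) for a in atoms))
        amap[str(bit)] = occ
    return bits, amap


def _rdkfp(mol, nbits, min_path, max_path):
    info = {}
    fp = Chem.RDKFingerprint(mol, minPath=int(min_path), maxPath=int(max_path),
                             fpSize=int(nbits), bitInfo=info)
    bits = sorted(fp.GetOnBits())
    amap = {}
    for bit, paths in info.items():
        occ = []
        for path in paths:
            atoms = set()
            for bidx in path:
                b = mol.GetBondWithIdx(bidx)
                atoms.add(b.GetBeginAtomIdx())
                atoms.add(b.GetEndAtomIdx())
            occ.append(sorted(int(a) for a in atoms))
        amap[str(bit)] = occ
    return bits, amap


# -- PubChem-layout keys: definitions supplied by R as a JSON table --------

def _ring_profile(mol):
    """Classify each SSSR ring; returns list of dicts."""
    ri = mol.GetRingInfo()
    out = []
    for aring in ri.AtomRings():
        atoms = list(aring)
        ratoms = [mol.GetAtomWithIdx(i) for i in atoms]
        aromatic = all(a.GetIsAromatic() for a in ratoms)
        hasN = any(a.GetSymbol() == "N" for a in ratoms)
        hasHet = any(a.GetSymbol() != "C" for a in ratoms)
        # bonds of the ring
        nbond = len(atoms)
        sat = True
        for i in range(nbond):
            b = mol.GetBondBetweenAtoms(atoms[i], atoms[(i + 1) % nbond])
            if b is None or b.GetBondType() != Chem.BondType.SINGLE:
                sat = False
                break
        out.append({"size": len(atoms), "aromatic": aromatic,
                    "saturated": sat, "hasN": hasN, "hasHet": hasHet,
                    "atoms": sorted(int(a) for a in atoms)})
    return out


def _ring_matches(rings, d):
    """Rings matching one ring-key definition d."""
    sel = []
    for r in rings:
        if d.get("size") is not None and r["size"] != d["size"]:
            continue
        cls = d.get("rclass", "any")
        satarom = r["saturated"] or r["aromatic"]
        unsat = (not r["saturated"]) and (not r["aromatic"])
        if cls == "carbo_satarom" and not (satarom and not r["hasHet"]):
            continue
        if cls == "n_satarom" and not (satarom and r["hasN"]):
            continue
        if cls == "het_satarom" and not (satarom and r["hasHet"]):
            continue
        if cls == "carbo_unsat" and not (unsat and not r["hasHet"]):
            continue
        if cls == "n_unsat" and not (unsat and r["hasN"]):
            continue
        if cls == "het_unsat" and not (unsat and r["hasHet"]):
            continue
        if cls == "aromatic" and not r["aromatic"]:
            continue
        if cls == "hetero_aromatic" and not (r["aromatic"] and r["hasHet"]):
            continue
        sel.append(r)
    return sel


def _eval_keys(mol, keys):
    """Evaluate PubChem-layout key definitions on one molecule.

    Returns (on_bits, atom_map, unmappable).  atom_map: bit -> list of
    occurrence atom lists; unmappable: on-bits with no heavy-atom
    correspondence (e.g. hydrogen-count bits).
    """
    rings = _ring_profile(mol)
    counts = {}
    for a in mol.GetAtoms():
        counts[a.GetSymbol()] = counts.get(a.GetSymbol(), 0) + 1
    nH = sum(a.GetTotalNumHs() for a in mol.GetAtoms())
    on, amap, unmappable = [], {}, []
    for d in keys:
        bit = int(d["bit"])
        kind = d["kind"]
        if kind == "element_count":
            el, thr = d["element"], int(d["threshold"])
            if el == "H":
                if nH >= thr:
                    on.append(bit)
                    unmappable.append(bit)
                continue
            n = counts.get(el, 0)
            if n >= thr:
                on.append(bit)
                amap[str(bit)] = [[int(a.GetIdx())] for a in mol.GetAtoms()
                                  if a.GetSymbol() == el]
        elif kind == "ring":
            sel = _ring_matches(rings, d)
            if len(sel) >= int(d["threshold"]):
                on.append(bit)
                amap[str(bit)] = [r["atoms"] for r in sel]
        elif kind == "smarts":
            patt = Chem.MolFromSmarts(d["smarts"])
            if patt is None:
                continue
            matches = mol.GetSubstructMatches(patt, uniquify=True)
            if len(matches) >= int(d.get("threshold", 1)):
                on.append(bit)
                amap[str(bit)] = [sorted(int(i) for i in set(m))
                                  for m in matches]
        # kind == "reserved": never set
    return sorted(on), amap, sorted(unmappable)


def task_fingerprint(payload):
    family = payload["family"]
    res = []
    for smi in payload["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            res.append({"ok": False, "error": "unparsable SMILES",
                        "smiles": smi})
            continue
        unmappable = []
        if family == "MORGAN":
            bits, amap = _morgan(mol, payload.get("radius", 2),
                                 payload.get("nbits", 1024))
        elif family == "PATH_TOPOLOGICAL":
            bits, amap = _rdkfp(mol, payload.get("nbits", 2048),
                                payload.get("min_path", 1),
                                payload.get("max_path", 7))
        elif family == "PUBCHEM":
            bits, amap, unmappable = _eval_keys(mol, payload["keys"])
        else:
            raise ValueError("unknown family: %s" % family)
        rec = {"ok": True, "smiles": smi, "bits": [int(b) for b in bits],
               "unmappable": unmappable}
        if payload.get("atom_map", True):
            rec["atom_map"] = amap
        res.append(rec)
    return res


def task_match(payload):
    """Substructure matches of one SMARTS against many molecules."""
    patt = Chem.MolFromSmarts(payload["smarts"])
    if patt is None:
        raise ValueError("invalid SMARTS: %s" % payload["smarts"])
    out = []
    for smi in payload["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "smiles": smi})
            continue
        matches = mol.GetSubstructMatches(patt, uniquify=True)
        out.append({"ok": True, "smiles": smi,
                    "matches": [sorted(int(i) for i in m) for m in matches]})
    return out


def task_depict(payload):
    """SVG depiction with signed atom-weight coloring.

    Positive weights (toward toxicity) in red, negative in blue;
    intensity scales with |w| / max |w|.
    """
    smi = payload["smiles"]
    w = [float(x) for x in payload["weights"]]
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        raise ValueError("unparsable SMILES: %s" % smi)
    if mol.GetNumHeavyAtoms() != len(w):
        raise ValueError("weight/atom count mismatch")
    AllChem.Compute2DCoords(mol)
    wmax = max((abs(x) for x in w), default=0.0)
    highlight, colors = [], {}
    if wmax > 0:
        for i, x in enumerate(w):
            if x == 0:
                continue
            t = min(1.0, abs(x) / wmax)
            if x > 0:
                col = (1.0, 1.0 - 0.75 * t, 1.0 - 0.75 * t)
            else:
                col = (1.0 - 0.75 * t, 1.0 - 0.75 * t, 1.0)
            highlight.append(i)
            colors[i] = col
    d = rdMolDraw2D.MolDraw2DSVG(int(payload.get("width", 450)),
                                 int(payload.get("height", 400)))
    rdMolDraw2D.PrepareAndDrawMolecule(
        d, mol, highlightAtoms=highlight, highlightAtomColors=colors)
    d.FinishDrawing()
    return {"svg": d.GetDrawingText()}


def task_check_smarts(payload):
    return [{"smarts": s, "ok": Chem.MolFromSmarts(s) is not None}
            for s in payload["smarts"]]


TASKS = {
    "standardize": task_standardize,
    "fingerprint": task_fingerprint,
    "match": task_match,
    "depict": task_depict,
    "check_smarts": task_check_smarts,
}


def main(argv):
    task, fin, fout = argv[1], argv[2], argv[3]
    with open(fin) as fh:
        payload = json.load(fh)
    result = TASKS[task](payload)
    with open(fout, "w") as fh:
        json.dump({"ok": True, "result": result}, fh)


if __name__ == "__main__":
    try:
        main(sys.argv)
    except Exception as e:
        out = sys.argv[3] if len(sys.argv) > 3 else None
        if out:
            with open(out, "w") as fh:
                json.dump({"ok": False, "error": str(e)}, fh)
        sys.stderr.write("rdkit_bridge error: %s\n" % e)
        sys.exit(1)
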