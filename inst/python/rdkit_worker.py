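"""RDKit worker: Morgan/MACCS fingerprints and single-cut fragmentation.

Reads <job_dir>/job.json and writes <job_dir>/result.json.

Tasks:
  fingerprint -- {"task", "provider": "morgan_r2"|"maccs", "n_bits",
                  "ids", "smiles"} -> {"bits": {id: bitstring}}
  fragment    -- {"task", "ids", "smiles", "min_ratio"}
                 -> {"cores": {id: [canonical core SMILES, ...]}}
                 Single-cut analog cores: every acyclic single bond between
                 two heavy atoms is cut; the larger fragment is a core key
                 iff heavy_atoms(core) >= min_ratio * heavy_atoms(rest).
"""
import json
import os
import sys

from rdkit import Chem
from rdkit.Chem import AllChem, MACCSkeys, rdmolops
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def fingerprints(job):
    bits = {}
    for cid, smi in zip(job["ids"], job["smiles"]):
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            return {"error": "unparseable SMILES: %s" % smi}
        if job["provider"] == "maccs":
            fp = MACCSkeys.GenMACCSKeys(mol)
        else:
            fp = AllChem.GetMorganFingerprintAsBitVect(
                mol, radius=2, nBits=int(job["n_bits"]))
        bits[cid] = fp.ToBitString()
    return {"bits": bits}


def single_cut_cores(mol, min_ratio):
    cores = set()
    for bond in mol.GetBonds():
        if bond.IsInRing() or bond.GetBondType() != Chem.BondType.SINGLE:
            continue
        frag = Chem.FragmentOnBonds(mol, [bond.GetIdx()], addDummies=True)
        pieces = rdmolops.GetMolFrags(frag, asMols=True,
                                      sanitizeFrags=False)
        if len(pieces) != 2:
            continue
        sizes = [sum(1 for a in p.GetAtoms() if a.GetAtomicNum() > 1)
                 for p in pieces]
        big = int(sizes[1] > sizes[0])
        if sizes[big] >= min_ratio * sizes[1 - big] and sizes[1 - big] > 0:
            try:
                core = Chem.MolToSmiles(pieces[big])
            except Exception:
                continue
            cores.add(core)
    return sorted(cores)


def fragments(job):
    out = {}
    for cid, smi in zip(job["ids"], job["smiles"]):
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            return {"error": "unparseable SMILES: %s" % smi}
        out[cid] = single_cut_cores(mol, float(job["min_ratio"]))
    return {"cores": out}


def main(job_dir):
    with open(os.path.join(job_dir, "job.json")) as fh:
        job = json.load(fh)
    if job["task"] == "fingerprint":
        res = fingerprints(job)
    elif job["task"] == "fragment":
        res = fragments(job)
    else:
        res = {"error": "unknown task %s" % job["task"]}
    with open(os.path.join(job_dir, "result.json"), "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main(sys.argv[1])
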