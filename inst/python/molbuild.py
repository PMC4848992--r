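"""Structure backend: SMILES -> annotated molecular graph (+ optional 3D).

Reads a JSON array of jobs from the file given as argv[1] and writes a JSON
array of results to argv[2].  Each job:

    {"id": str, "smiles": str, "gen3d": bool, "seed": int, "k": int,
     "charge_model": "gasteiger" | "mmff94"}

Result (per job):

    {"id": ..., "ok": true,
     "atoms": [[element, x, y, z, charge, aromatic01], ...],
     "bonds": [[from1, to1, order, aromatic01], ...]}      # 1-based indices

or {"id": ..., "ok": false, "error": "..."} on failure.

3D coordinates come from k seeded ETKDG distance-geometry embeddings, each
refined with the MMFF94 force field (UFF fallback); the lowest-energy
conformer is kept.  Fully deterministic for a fixed (smiles, seed, k).
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdPartialCharges

RDLogger.DisableLog("rdApp.*")


def charges(mol, model):
    if model == "mmff94":
        props = AllChem.MMFFGetMoleculeProperties(mol)
        if props is not None:
            return [props.GetMMFFPartialCharge(i)
                    for i in range(mol.GetNumAtoms())]
        # fall through to Gasteiger when MMFF typing fails
    rdPartialCharges.ComputeGasteigerCharges(mol)
    out = []
    for a in mol.GetAtoms():
        q = float(a.GetProp("_GasteigerCharge"))
        out.append(q if q == q else 0.0)  # NaN guard
    return out


def build(job):
    smi = job["smiles"]
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        raise ValueError("unparsable SMILES")
    if len(Chem.GetMolFrags(mol)) != 1:
        raise ValueError("not a connected molecule")
    mol = Chem.AddHs(mol)
    best = None
    if job.get("gen3d"):
        params = AllChem.ETKDGv3()
        params.randomSeed = int(job.get("seed", 1))
        k = int(job.get("k", 10))
        cids = AllChem.EmbedMultipleConfs(mol, numConfs=k, params=params)
        if len(cids) == 0:
            params.useRandomCoords = True
            cids = AllChem.EmbedMultipleConfs(mol, numConfs=k, params=params)
        if len(cids) == 0:
            raise ValueError("3D embedding failed")
        try:
            res = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=1000)
        except Exception:
            res = AllChem.UFFOptimizeMoleculeConfs(mol, maxIters=1000)
        energies = [e if conv == 0 else float("inf") for conv, e in res]
        if all(e == float("inf") for e in energies):
            energies = [e for _, e in res]
        best = int(min(range(len(energies)), key=lambda i: energies[i]))
    q = charges(mol, job.get("charge_model", "gasteiger"))
    conf = mol.GetConformer(best) if best is not None else None
    atoms = []
    for a in mol.GetAtoms():
        if conf is not None:
            p = conf.GetAtomPosition(a.GetIdx())
            xyz = [round(p.x, 4), round(p.y, 4), round(p.z, 4)]
        else:
            xyz = [0.0, 0.0, 0.0]
        atoms.append([a.GetSymbol()] + xyz +
                     [round(q[a.GetIdx()], 5), int(a.GetIsAromatic())])
    bonds = [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1,
              b.GetBondTypeAsDouble(), int(b.GetIsAromatic())]
             for b in mol.GetBonds()]
    return {"id": job.get("id"), "ok": True, "atoms": atoms, "bonds": bonds}


def main():
    with open(sys.argv[1]) as fh:
        jobs = json.load(fh)
    if isinstance(jobs, dict):  # a singleton batch arrives unboxed
        jobs = [jobs]
    out = []
    for job in jobs:
        try:
            out.append(build(job))
        except Exception as exc:  # report per-job, keep batch going
            out.append({"id": job.get("id"), "ok": False, "error": str(exc)})
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
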