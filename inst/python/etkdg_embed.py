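"""Seeded ETKDG conformer embedding helper.

Reads a JSON job file: {"out": <sdf path>, "prune_rms": <float>,
"molecules": [{"mol_id", "smiles" or "molblock", "max_n", "seed"}, ...]}
and writes one SDF record per generated conformer (heavy atoms only) with
mol_id / gen_order properties. Embedding uses ETKDGv3 with experimental
torsion knowledge, a fixed per-molecule random seed and single-threaded
execution, so output is fully reproducible.
"""
import sys
import json

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def embed(rec, prune_rms, writer):
    if "smiles" in rec and rec["smiles"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
    else:
        mol = Chem.MolFromMolBlock(rec["molblock"])
    if mol is None:
        return {"mol_id": rec["mol_id"], "n": 0, "error": "parse failure"}
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(rec["seed"])
    params.pruneRmsThresh = float(prune_rms)
    params.numThreads = 1
    cids = AllChem.EmbedMultipleConfs(mol, numConfs=int(rec["max_n"]),
                                      params=params)
    if len(cids) == 0:
        return {"mol_id": rec["mol_id"], "n": 0, "error": "embedding failure"}
    mol = Chem.RemoveHs(mol)
    for k, cid in enumerate(cids):
        mol.SetProp("_Name", rec["mol_id"])
        mol.SetProp("mol_id", rec["mol_id"])
        mol.SetProp("gen_order", str(k + 1))
        mol.SetProp("conf_id", str(k + 1))
        mol.SetProp("source", "generated")
        writer.write(mol, confId=cid)
    return {"mol_id": rec["mol_id"], "n": len(cids)}


def main():
    job = json.load(open(sys.argv[1]))
    writer = Chem.SDWriter(job["out"])
    writer.SetForceV3000(False)
    status = []
    for rec in job["molecules"]:
        status.append(embed(rec, job.get("prune_rms", 0.05), writer))
    writer.close()
    json.dump(status, open(job["status"], "w"))


if __name__ == "__main__":
    main()
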