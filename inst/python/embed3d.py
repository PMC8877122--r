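"""Deterministic single-conformer 3D embedding for snapqsar.

Reads tab-separated lines  id<TAB>smiles  from the file given as argv[1],
embeds one conformer per molecule with ETKDG distance geometry (explicit
random seed, argv[2]) followed by MMFF94 minimization, and writes a V2000
SD file to argv[3].  Pre- and post-minimization MMFF94 energies are stored
as SD properties so callers can verify that minimization never increased
the energy.  Failures are reported on one line each to stdout as
FAIL<TAB>id<TAB>reason and the molecule is omitted from the SD file.

Retries embedding up to MAX_RETRIES times with incremented seeds before
giving up on a molecule.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

MAX_RETRIES = 5


def embed_one(mol_id, smiles, seed, writer):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        print("FAIL\t%s\tunparseable SMILES" % mol_id)
        return
    mol = Chem.AddHs(mol)
    conf_id = -1
    for attempt in range(MAX_RETRIES):
        params = AllChem.ETKDGv3()
        params.randomSeed = seed + attempt
        conf_id = AllChem.EmbedMolecule(mol, params)
        if conf_id >= 0:
            break
    if conf_id < 0:
        print("FAIL\t%s\tembedding failed after %d attempts" % (mol_id, MAX_RETRIES))
        return
    props = AllChem.MMFFGetMoleculeProperties(mol)
    if props is None:
        print("FAIL\t%s\tno MMFF94 parameters" % mol_id)
        return
    ff = AllChem.MMFFGetMoleculeForceField(mol, props)
    e_pre = ff.CalcEnergy()
    ff.Minimize(maxIts=2000)
    e_post = ff.CalcEnergy()
    mol.SetProp("_Name", mol_id)
    mol.SetProp("energy_pre", repr(e_pre))
    mol.SetProp("energy", repr(e_post))
    writer.write(mol)


def main():
    infile, seed, outfile = sys.argv[1], int(sys.argv[2]), sys.argv[3]
    writer = Chem.SDWriter(outfile)
    writer.SetForceV3000(False)
    with open(infile) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            mol_id, smiles = line.split("\t", 1)
            embed_one(mol_id, smiles, seed, writer)
    writer.close()


if __name__ == "__main__":
    main()
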