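"""Cheminformatics helper: Morgan fingerprints, SMARTS, substructure match.

Reads one record per stdin line, writes one result line per record.
Modes:
  fp <radius> <nbits>  SMILES -> space-separated on-bit indices (0-based)
  smarts               SMILES -> SMARTS
  match                SMILES<TAB>SMARTS -> 1/0
Errors are reported as a line starting with "ERROR".
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main():
    mode = sys.argv[1]
    lines = [line.rstrip("\n") for line in sys.stdin]
    if mode == "fp":
        radius = int(sys.argv[2])
        nbits = int(sys.argv[3])
        gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius,
                                                        fpSize=nbits)
        for smi in lines:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                print("ERROR invalid SMILES: %s" % smi)
            else:
                fp = gen.GetFingerprint(mol)
                print(" ".join(str(b) for b in fp.GetOnBits()))
    elif mode == "smarts":
        for smi in lines:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                print("ERROR invalid SMILES: %s" % smi)
            else:
                print(Chem.MolToSmarts(mol))
    elif mode == "match":
        for line in lines:
            smi, sma = line.split("\t")
            mol = Chem.MolFromSmiles(smi)
            patt = Chem.MolFromSmarts(sma)
            if mol is None or patt is None:
                print("ERROR invalid input: %s" % line)
            else:
                print("1" if mol.HasSubstructMatch(patt) else "0")
    else:
        print("ERROR unknown mode %s" % mode)
        sys.exit(2)


if __name__ == "__main__":
    main()
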