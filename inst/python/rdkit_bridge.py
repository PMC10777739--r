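"""Batched RDKit helper invoked by the R package.

Reads a task file, writes a result file; one record per line so a single
process handles thousands of molecules (RDKit import cost is paid once).

Modes:
  canon   input line:  <smiles>
          output line: <canonical smiles>   or  ERROR:<message>
  random  input line:  <smiles>\t<n>\t<seed>
          output line: <n randomized forms, tab-joined>  or  ERROR:<message>
"""
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def canon_line(line):
    mol = Chem.MolFromSmiles(line)
    if mol is None:
        return "ERROR:unparseable SMILES '%s'" % line
    return Chem.MolToSmiles(mol)


def random_line(line):
    try:
        smi, n, seed = line.split("\t")
        n, seed = int(n), int(seed)
    except ValueError:
        return "ERROR:malformed random request '%s'" % line
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return "ERROR:unparseable SMILES '%s'" % smi
    forms = Chem.MolToRandomSmilesVect(mol, n, randomSeed=seed)
    return "\t".join(forms)


def main():
    mode, inp, out = sys.argv[1], sys.argv[2], sys.argv[3]
    handler = {"canon": canon_line, "random": random_line}[mode]
    with open(inp, encoding="utf-8") as fh:
        lines = fh.read().splitlines()
    with open(out, "w", encoding="utf-8") as fh:
        for line in lines:
            fh.write(handler(line) + "\n")


if __name__ == "__main__":
    main()
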