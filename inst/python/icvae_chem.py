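"""Batched RDKit backend for the icvae R package.

Usage: python icvae_chem.py <command> <infile> <outfile>

Commands (one SMILES per input line; blank lines preserved as invalid):
  props  -> TSV: smiles, valid, canonical, MW, logP, HBA, HBD, TPSA, QED, SAS
  canon  -> TSV: smiles, valid, canonical
  fp     -> TSV: smiles, valid, 1024-char Morgan (radius 2) bitstring
  brics  -> TSV: smiles, valid, tab-free ';'-joined sorted BRICS fragments
"""
import sys
import os

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import Descriptors, Lipinski, QED, BRICS, AllChem

RDLogger.DisableLog("rdApp.*")
sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def mol_of(smi):
    if not smi:
        return None
    return Chem.MolFromSmiles(smi)  # parses + sanitizes


def run(cmd, lines, out):
    for smi in lines:
        m = mol_of(smi)
        if m is None:
            out.write("%s\t0\t\n" % smi if cmd != "props" else
                      "%s\t0\t\t\t\t\t\t\t\t\n" % smi)
            continue
        can = Chem.MolToSmiles(m)
        if cmd == "canon":
            out.write("%s\t1\t%s\n" % (smi, can))
        elif cmd == "props":
            vals = (Descriptors.MolWt(m), Descriptors.MolLogP(m),
                    Lipinski.NumHAcceptors(m), Lipinski.NumHDonors(m),
                    Descriptors.TPSA(m), QED.qed(m),
                    sascorer.calculateScore(m))
            out.write("%s\t1\t%s\t" % (smi, can) +
                      "\t".join("%.10g" % v for v in vals) + "\n")
        elif cmd == "fp":
            fp = AllChem.GetMorganFingerprintAsBitVect(m, 2, nBits=1024)
            out.write("%s\t1\t%s\n" % (smi, fp.ToBitString()))
        elif cmd == "brics":
            frags = sorted(BRICS.BRICSDecompose(m))
            out.write("%s\t1\t%s\n" % (smi, ";".join(frags)))
        else:
            raise SystemExit("unknown command: %s" % cmd)


def main():
    if len(sys.argv) != 4:
        raise SystemExit(__doc__)
    cmd, infile, outfile = sys.argv[1:4]
    with open(infile) as fh:
        lines = [ln.rstrip("\n") for ln in fh]
    with open(outfile, "w") as out:
        run(cmd, lines, out)


if __name__ == "__main__":
    main()
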