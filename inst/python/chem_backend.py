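"""Batch cheminformatics backend (RDKit).

Reads SMILES one per line on stdin, writes one TSV line per input on stdout.
Invoked by the R package; every command is deterministic.

Commands:
  canon     -> valid(0/1) \t canonical_smiles (empty when invalid)
  props     -> valid \t MW \t TPSA \t LogP \t HBD \t HBA \t QED \t SA
  features  -> valid \t 2533 tab-separated feature values
               (2048-bit FCFP6, 166 MACCS bits, 319 descriptors per the
               manifest passed as argv[2])
  graph     -> one JSON object per line: {"ok":1,"atoms":[sym,...],
               "bonds":[[i,j,order],...]} with 0-based indices, kekulized,
               stereo stripped; {"ok":0,"err":...} when unsupported
"""
import sys
import json
import math

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import Descriptors, QED, MACCSkeys, rdMolDescriptors
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")

sys.path.append(RDConfig.RDContribDir + "/SA_Score")
import sascorer  # noqa: E402

SUPPORTED = {"C", "N", "O", "F", "S", "P", "Cl", "Br", "I", "B"}


def mol_from(smi):
    if smi == "":
        return Chem.MolFromSmiles("")  # zero-atom molecule, parses
    return Chem.MolFromSmiles(smi)


def cmd_canon():
    for line in sys.stdin:
        m = mol_from(line.rstrip("\n"))
        if m is None:
            sys.stdout.write("0\t\n")
        else:
            sys.stdout.write("1\t%s\n" % Chem.MolToSmiles(m))


def cmd_props():
    for line in sys.stdin:
        m = mol_from(line.rstrip("\n"))
        if m is None or m.GetNumAtoms() == 0:
            sys.stdout.write("0\t\t\t\t\t\t\t\n")
            continue
        vals = (
            Descriptors.MolWt(m),
            Descriptors.TPSA(m),
            Descriptors.MolLogP(m),
            Descriptors.NumHDonors(m),
            Descriptors.NumHAcceptors(m),
            QED.qed(m),
            sascorer.calculateScore(m),
        )
        sys.stdout.write("1\t" + "\t".join("%.10g" % v for v in vals) + "\n")


def cmd_features(manifest_path):
    with open(manifest_path) as fh:
        names = [ln.strip() for ln in fh if ln.strip()]
    desc_fns = dict(Descriptors.descList)
    fpgen = rdFingerprintGenerator.GetMorganGenerator(
        radius=3,
        fpSize=2048,
        atomInvariantsGenerator=rdFingerprintGenerator.GetMorganFeatureAtomInvGen(),
    )
    for line in sys.stdin:
        m = mol_from(line.rstrip("\n"))
        if m is None or m.GetNumAtoms() == 0:
            sys.stdout.write("0\n")
            continue
        fp = fpgen.GetFingerprint(m)
        fcfp = [1 if fp.GetBit(i) else 0 for i in range(2048)]
        mk = MACCSkeys.GenMACCSKeys(m)
        maccs = [1 if mk.GetBit(i) else 0 for i in range(1, 167)]  # bit 0 unused
        ac = None
        out = []
        for nm in names:
            if nm.startswith("AUTOCORR2D_"):
                if ac is None:
                    ac = rdMolDescriptors.CalcAUTOCORR2D(m)
                v = ac[int(nm.split("_")[1]) - 1]
            else:
                try:
                    v = desc_fns[nm](m)
                except Exception:
                    v = float("nan")
            if v is None or isinstance(v, float) and not math.isfinite(v):
                v = 0.0  # sentinel for non-finite descriptors
            out.append(v)
        row = fcfp + maccs + out
        sys.stdout.write("1\t" + "\t".join("%.10g" % v for v in row) + "\n")


def cmd_graph():
    for line in sys.stdin:
        smi = line.rstrip("\n")
        m = mol_from(smi)
        if m is None:
            sys.stdout.write(json.dumps({"ok": 0, "err": "unparsable"}) + "\n")
            continue
        try:
            Chem.RemoveStereochemistry(m)
            Chem.Kekulize(m, clearAromaticFlags=True)
        except Exception:
            sys.stdout.write(json.dumps({"ok": 0, "err": "kekulization failed"}) + "\n")
            continue
        bad = None
        for a in m.GetAtoms():
            if a.GetSymbol() not in SUPPORTED:
                bad = "unsupported element " + a.GetSymbol()
            elif a.GetFormalCharge() != 0:
                bad = "charged atom"
            elif a.GetIsotope() != 0:
                bad = "isotope label"
            elif a.GetNumRadicalElectrons() != 0:
                bad = "radical"
        if bad is not None:
            sys.stdout.write(json.dumps({"ok": 0, "err": bad}) + "\n")
            continue
        atoms = [a.GetSymbol() for a in m.GetAtoms()]
        bonds = []
        okb = True
        for b in m.GetBonds():
            o = b.GetBondTypeAsDouble()
            if o not in (1.0, 2.0, 3.0):
                okb = False
                break
            bonds.append([b.GetBeginAtomIdx(), b.GetEndAtomIdx(), int(o)])
        if not okb:
            sys.stdout.write(json.dumps({"ok": 0, "err": "unsupported bond order"}) + "\n")
            continue
        sys.stdout.write(json.dumps({"ok": 1, "atoms": atoms, "bonds": bonds}) + "\n")


def main():
    cmd = sys.argv[1]
    if cmd == "canon":
        cmd_canon()
    elif cmd == "props":
        cmd_props()
    elif cmd == "features":
        cmd_features(sys.argv[2])
    elif cmd == "graph":
        cmd_graph()
    else:
        sys.stderr.write("unknown command: %s\n" % cmd)
        sys.exit(2)


if __name__ == "__main__":
    main()
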