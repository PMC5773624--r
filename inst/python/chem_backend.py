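"""RDKit helper for the ahrscreen R package.

Batch interface: one process call handles a whole library. All exchange is
tab-separated text so the R side never links against the toolkit.

Modes
-----
standardize  in: TSV (id, smiles)  out: TSV (id, status, smiles, detail)
             status: ok | parse_error | excluded_element
descriptors  in: TSV (id, smiles) + registry file (one name per line)
             out: TSV (id, <registry columns>); exits non-zero naming the
             molecule and descriptor on any failure (no silent NaN)
maccs        in: TSV (id, smiles)  out: TSV (id, bits) with bits a
             166-character 0/1 string (public MACCS keys 1..166)
read_sdf     in: SDF path  out: TSV (id, smiles, name); id taken from the
             property named by --id-prop, falling back to the title line
"""

import argparse
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, MACCSkeys

RDLogger.DisableLog("rdApp.*")

EXCLUDED_DEFAULT = ["Al", "As", "Ba", "Bi", "Cd", "Co", "Cr", "Mn", "Ni",
                    "Pb", "Sb", "Sn", "Sr", "Ti", "Zr"]

# ionization rules: strong acids deprotonated, strong bases protonated.
# Applied to the kept (largest organic) fragment, in declaration order.
ACID_SMARTS = [
    "[CX3](=O)[OX2H1]",          # carboxylic
    "[SX4](=O)(=O)[OX2H1]",      # sulfonic
    "[PX4](=O)[OX2H1]",          # phosphonic / phosphoric (each OH)
]
BASE_SMARTS = [
    # aliphatic amine: trivalent N, neutral, no aromatic/carbonyl/hetero
    # neighbor, not conjugated
    "[NX3;+0;!$([N]=*);!$([N]#*);!$([N]a);!$([N][a]);!$([N]C=[O,N,S]);"
    "!$([N][O,N,S,P]);$([N][#6]),$([NH3]);!$([N]C#N)]",
    # amidine / guanidine sp2 nitrogen
    "[NX2;+0](=[CX3][NX3;+0])",
]


def read_tsv(path):
    rows = []
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            rows.append(line.split("\t"))
    return rows


def write_tsv(path, rows):
    with open(path, "w") as fh:
        for row in rows:
            fh.write("\t".join(str(x) for x in row) + "\n")


def largest_organic_fragment(mol):
    """Keep the largest fragment containing carbon; ties by heavy-atom
    count, then by canonical-SMILES order."""
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) == 1:
        return frags[0]

    def has_carbon(m):
        return any(a.GetAtomicNum() == 6 for a in m.GetAtoms())

    pool = [f for f in frags if has_carbon(f)] or list(frags)
    keyed = []
    for f in pool:
        try:
            smi = Chem.MolToSmiles(f)
        except Exception:
            smi = ""
        keyed.append((-f.GetNumHeavyAtoms(), smi, f))
    keyed.sort(key=lambda t: (t[0], t[1]))
    return keyed[0][2]


def apply_ionization(mol):
    rw = Chem.RWMol(mol)
    for sm in ACID_SMARTS:
        patt = Chem.MolFromSmarts(sm)
        for match in rw.GetSubstructMatches(patt):
            o = rw.GetAtomWithIdx(match[-1])
            if o.GetFormalCharge() == 0 and o.GetTotalNumHs() >= 1:
                o.SetFormalCharge(-1)
                o.SetNumExplicitHs(0)
                o.SetNoImplicit(True)
    for sm in BASE_SMARTS:
        patt = Chem.MolFromSmarts(sm)
        for match in rw.GetSubstructMatches(patt):
            n = rw.GetAtomWithIdx(match[0])
            if n.GetFormalCharge() == 0:
                n.SetFormalCharge(1)
                n.SetNumExplicitHs(n.GetTotalNumHs() + 1)
                n.SetNoImplicit(True)
    out = rw.GetMol()
    Chem.SanitizeMol(out)
    return out


def mode_standardize(args):
    excluded = set((args.excluded or ",".join(EXCLUDED_DEFAULT)).split(","))
    excluded.discard("")
    out = []
    for row in read_tsv(args.infile):
        ident, smi = row[0], row[1]
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append([ident, "parse_error", "", "unparseable SMILES"])
            continue
        bad = sorted({a.GetSymbol() for a in mol.GetAtoms()
                      if a.GetSymbol() in excluded})
        if bad:
            out.append([ident, "excluded_element", "", ",".join(bad)])
            continue
        try:
            frag = largest_organic_fragment(mol)
            frag = apply_ionization(frag)
            can = Chem.MolToSmiles(frag)  # canonical, stereo retained
        except Exception as exc:  # sanitization failure after edits
            out.append([ident, "parse_error", "", f"standardization: {exc}"])
            continue
        out.append([ident, "ok", can, ""])
    write_tsv(args.outfile, [["id", "status", "smiles", "detail"]] + out)


def n_aromatic_bonds(mol):
    return float(sum(1 for b in mol.GetBonds() if b.GetIsAromatic()))


def n_halogens(mol):
    return float(sum(1 for a in mol.GetAtoms()
                     if a.GetAtomicNum() in (9, 17, 35, 53)))


CUSTOM_DESCRIPTORS = {
    "AromaticBonds": n_aromatic_bonds,
    "Halogens": n_halogens,
}


def resolve_descriptor(name):
    if name in CUSTOM_DESCRIPTORS:
        return CUSTOM_DESCRIPTORS[name]
    fn = getattr(Descriptors, name, None)
    if fn is None:
        sys.exit(f"unknown descriptor name: {name}")
    return fn


def mode_descriptors(args):
    with open(args.registry) as fh:
        names = [ln.strip() for ln in fh if ln.strip()]
    fns = [resolve_descriptor(n) for n in names]
    out = [["id"] + names]
    for row in read_tsv(args.infile):
        ident, smi = row[0], row[1]
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            sys.exit(f"descriptor computation: cannot parse molecule "
                     f"'{ident}' ({smi})")
        vals = []
        for name, fn in zip(names, fns):
            try:
                v = float(fn(mol))
            except Exception as exc:
                sys.exit(f"descriptor '{name}' failed for molecule "
                         f"'{ident}': {exc}")
            if v != v or v in (float("inf"), float("-inf")):
                sys.exit(f"descriptor '{name}' non-finite for molecule "
                         f"'{ident}'")
            vals.append(repr(v))
        out.append([ident] + vals)
    write_tsv(args.outfile, out)


def mode_maccs(args):
    out = [["id", "bits"]]
    for row in read_tsv(args.infile):
        ident, smi = row[0], row[1]
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            sys.exit(f"fingerprint: cannot parse molecule '{ident}' ({smi})")
        if mol.GetNumHeavyAtoms() == 0:
            sys.exit(f"fingerprint: molecule '{ident}' has no heavy atoms")
        fp = MACCSkeys.GenMACCSKeys(mol)  # 167 bits, bit 0 unused
        bits = "".join("1" if fp.GetBit(i) else "0" for i in range(1, 167))
        out.append([ident, bits])
    write_tsv(args.outfile, out)


def mode_read_sdf(args):
    out = [["id", "smiles", "name"]]
    supplier = Chem.SDMolSupplier(args.infile, sanitize=True)
    for i, mol in enumerate(supplier):
        if mol is None:
            out.append([f"__unparseable_{i + 1}", "", ""])
            continue
        ident = ""
        if args.id_prop and mol.HasProp(args.id_prop):
            ident = mol.GetProp(args.id_prop).strip()
        if not ident and mol.HasProp("_Name"):
            ident = mol.GetProp("_Name").strip()
        if not ident:
            ident = f"mol_{i + 1}"
        name = mol.GetProp("NAME").strip() if mol.HasProp("NAME") else ""
        out.append([ident, Chem.MolToSmiles(mol), name])
    write_tsv(args.outfile, out)


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("mode", choices=["standardize", "descriptors", "maccs",
                                     "read_sdf"])
    ap.add_argument("--in", dest="infile", required=True)
    ap.add_argument("--out", dest="outfile", required=True)
    ap.add_argument("--excluded", default=None)
    ap.add_argument("--registry", default=None)
    ap.add_argument("--id-prop", dest="id_prop", default=None)
    args = ap.parse_args()
    {"standardize": mode_standardize,
     "descriptors": mode_descriptors,
     "maccs": mode_maccs,
     "read_sdf": mode_read_sdf}[args.mode](args)


if __name__ == "__main__":
    main()
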