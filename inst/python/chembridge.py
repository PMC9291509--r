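"""Batched RDKit worker behind the delfrag R package.

Reads one JSON document {"requests": [...]} on stdin and writes
{"results": [...]} on stdout.  Every request is a batch: the chemistry
(parsing, BRICS bond perception, SSSR, SAS, Crippen logP) is RDKit's;
the fragmentation scan rule and the fragment-sequence conventions are
defined here and mirrored by the R documentation.

Fragmentation rule ("ring-entry BRICS scan"): scanning the SMILES left
to right, a molecule is cleaved at every BRICS-breakable bond whose
later-scanned atom belongs to a ring.  Acyclic linkers therefore stay
attached to the preceding fragment and each fragment (after the first)
begins at a ring system.  BRICS bonds are acyclic, hence bridges, so
the cut set always induces a tree of fragments.

Fragment sequence convention: fragments are listed in preorder of that
tree.  Within a fragment SMILES, attachment points are bare "*" dummy
atoms; the first "*" (in reading order) of every fragment except the
first is the bond back to its parent, and the remaining "*"s bond to
its children in the order the children appear in the sequence.
"""

import json
import re
import sys
import math

from rdkit import Chem, RDLogger
from rdkit.Chem import BRICS, Crippen, Descriptors, RDConfig
import os

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

RDLogger.DisableLog("rdApp.*")

ISOTOPE_STAR = re.compile(r"\[\d+\*\]")


def parse(smi):
    if not isinstance(smi, str):
        return None
    return Chem.MolFromSmiles(smi)


def canonical(smi):
    mol = parse(smi)
    return None if mol is None else Chem.MolToSmiles(mol)


def ring_entry_bonds(mol):
    """BRICS-breakable bonds whose later-scanned atom is in a ring."""
    out = set()
    for (i, j), _labels in BRICS.FindBRICSBonds(mol):
        a, b = min(i, j), max(i, j)
        if mol.GetAtomWithIdx(b).IsInRing():
            out.add((a, b))
    return sorted(out)


def fragment_one(smi):
    mol = parse(smi)
    if mol is None:
        return None
    source = Chem.MolToSmiles(mol)
    cuts = ring_entry_bonds(mol)
    if not cuts:
        return {"source": source, "fragments": [source]}
    bond_ids = [mol.GetBondBetweenAtoms(a, b).GetIdx() for a, b in cuts]
    labels = [(k + 1, k + 1) for k in range(len(bond_ids))]
    cut = Chem.FragmentOnBonds(mol, bond_ids, addDummies=True, dummyLabels=labels)
    n_real = mol.GetNumAtoms()
    pieces = Chem.GetMolFrags(cut)

    # For cut k between (a_k, b_k): the piece containing b_k is the child
    # entered through that bond; the piece containing a_k is its parent.
    piece_of = {}
    for pi, atoms in enumerate(pieces):
        for at in atoms:
            if at < n_real:
                piece_of[at] = pi
    children_bonds = {pi: [] for pi in range(len(pieces))}  # rightward cuts
    parent_bond = {}                                        # leftward cut
    for k, (a, b) in enumerate(cuts):
        children_bonds[piece_of[a]].append(k)
        parent_bond[piece_of[b]] = k

    # Emit each piece with a controlled atom order: parent-facing dummy
    # first, then real atoms in scan order, then child-facing dummies.
    mapping = []
    piece_mols = Chem.GetMolFrags(
        cut, asMols=True, sanitizeFrags=True, fragsMolAtomMapping=mapping
    )
    frag_smiles = {}
    child_order = {}
    for pi, atoms in enumerate(pieces):
        piece = piece_mols[pi]
        orig = list(mapping[pi])  # local index -> index in `cut`
        iso = {
            loc: piece.GetAtomWithIdx(loc).GetIsotope()
            for loc in range(piece.GetNumAtoms())
            if piece.GetAtomWithIdx(loc).GetAtomicNum() == 0
        }
        left = [loc for loc in iso if iso[loc] - 1 == parent_bond.get(pi, -2)]
        right = sorted(
            (loc for loc in iso if loc not in left),
            key=lambda loc: cuts[iso[loc] - 1][1],
        )
        real = sorted(
            (loc for loc in range(piece.GetNumAtoms()) if loc not in iso),
            key=lambda loc: orig[loc],
        )
        sub = Chem.RenumberAtoms(piece, left + real + right)
        smi_iso = Chem.MolToSmiles(sub, canonical=False)
        # Children order = reading order of the child-facing stars.
        probe = Chem.MolFromSmiles(smi_iso)
        kid_bonds = []
        for atom in probe.GetAtoms():
            if atom.GetAtomicNum() == 0 and atom.GetIsotope() - 1 != parent_bond.get(pi, -2):
                kid_bonds.append(atom.GetIsotope() - 1)
        child_order[pi] = kid_bonds
        frag_smiles[pi] = ISOTOPE_STAR.sub("*", smi_iso)

    root = piece_of[0]
    seq = []
    stack = [root]
    while stack:
        pi = stack.pop()
        seq.append(frag_smiles[pi])
        kids = [piece_of[cuts[k][1]] for k in child_order[pi]]
        stack.extend(reversed(kids))
    return {"source": source, "fragments": seq}


def star_atoms(mol):
    return [a.GetIdx() for a in mol.GetAtoms() if a.GetAtomicNum() == 0]


def join_at(mol_a, star_a, mol_b, star_b):
    """Bond the neighbours of two dummy atoms and drop the dummies.

    Returns (mol, index_map_a, index_map_b) where the maps give the new
    indices of the old atoms (dummies map to None).
    """
    na = mol_a.GetNumAtoms()
    combo = Chem.RWMol(Chem.CombineMols(mol_a, mol_b))
    sa, sb = star_a, na + star_b
    nb_a = [n.GetIdx() for n in combo.GetAtomWithIdx(sa).GetNeighbors()][0]
    nb_b = [n.GetIdx() for n in combo.GetAtomWithIdx(sb).GetNeighbors()][0]
    # restore the order of the cleaved bond (BRICS type 7 cuts are C=C)
    btype = combo.GetBondBetweenAtoms(sa, nb_a).GetBondType()
    if btype == Chem.BondType.UNSPECIFIED:
        btype = Chem.BondType.SINGLE
    # replacing the dummy by a neighbour appended at the end of the bond
    # list permutes the neighbour order; restore tetrahedral parity
    for atom_idx, star_idx in ((nb_a, sa), (nb_b, sb)):
        atom = combo.GetAtomWithIdx(atom_idx)
        if atom.GetChiralTag() == Chem.ChiralType.CHI_UNSPECIFIED:
            continue
        bonds = list(atom.GetBonds())
        pos = next(
            k for k, b in enumerate(bonds)
            if b.GetOtherAtomIdx(atom_idx) == star_idx
        )
        if (len(bonds) - 1 - pos) % 2 == 1:
            atom.InvertChirality()
    combo.AddBond(nb_a, nb_b, btype)
    drop = sorted([sa, sb], reverse=True)
    for d in drop:
        combo.RemoveAtom(d)
    out = combo.GetMol()

    def remap(old, offset=0):
        idx = old + offset
        if idx in (star_a, na + star_b):
            return None
        return idx - sum(1 for d in drop if d < idx)

    map_a = [remap(i) for i in range(na)]
    map_b = [remap(i, na) for i in range(mol_b.GetNumAtoms())]
    return out, map_a, map_b


def reassemble_one(frags):
    """Invert fragment_one: preorder fragment list -> parent molecule."""
    if not isinstance(frags, list) or not frags:
        return None
    mols = [parse(f) for f in frags]
    if any(m is None for m in mols):
        return None
    if len(mols) == 1:
        try:
            out = mols[0]
            Chem.SanitizeMol(out)
            return Chem.MolToSmiles(out)
        except Exception:
            return None
    try:
        stack = []  # assembled subtrees as (mol, parent-facing star index)
        for i in range(len(mols) - 1, -1, -1):
            mol = mols[i]
            stars = star_atoms(mol)
            if i > 0 and not stars:
                return None
            left = stars[0] if i > 0 else None
            while True:
                # child subtrees are complete before being pushed, so any
                # star other than `left` is a child-facing star of frag i
                rights = [s for s in star_atoms(mol) if s != left]
                if not rights:
                    break
                if not stack:
                    return None
                child, child_left = stack.pop(0)
                mol, map_par, _map_child = join_at(mol, rights[0], child, child_left)
                if left is not None:
                    left = map_par[left]
            stack.insert(0, (mol, left))
        if len(stack) != 1:
            return None
        mol, left = stack[0]
        if left is not None:
            return None
        Chem.SanitizeMol(mol)
        return Chem.MolToSmiles(mol)
    except Exception:
        return None


def assemble_chain_one(frags, allow_open=False):
    """Left-to-right chain assembly used by the sequence decoder.

    Each fragment after the first bonds its first star to the first free
    star of the growing chain.  With allow_open the (still dummy-bearing)
    intermediate is returned, for per-step validity checking.
    """
    if not isinstance(frags, list) or not frags:
        return None
    mols = [parse(f) for f in frags]
    if any(m is None for m in mols):
        return None
    try:
        cur = mols[0]
        open_stars = star_atoms(cur)
        for nxt in mols[1:]:
            nstars = star_atoms(nxt)
            if not open_stars or not nstars:
                return None
            cur, _mp, map_b = join_at(cur, open_stars[0], nxt, nstars[0])
            open_stars = star_atoms(cur)
        Chem.SanitizeMol(cur)
        if star_atoms(cur) and not allow_open:
            return None
        return Chem.MolToSmiles(cur)
    except Exception:
        return None


def graph_one(smi):
    mol = parse(smi)
    if mol is None:
        return None
    bonds = [
        [b.GetBeginAtomIdx(), b.GetEndAtomIdx(), int(b.IsInRing())]
        for b in mol.GetBonds()
    ]
    rings = [list(r) for r in Chem.GetSymmSSSR(mol)]
    return {
        "n": mol.GetNumAtoms(),
        "symbols": [a.GetSymbol() for a in mol.GetAtoms()],
        "bonds": bonds,
        "rings": rings,
    }


def props_one(smi):
    mol = parse(smi)
    if mol is None:
        return None
    return {
        "sas": sascorer.calculateScore(mol),
        "logp": Crippen.MolLogP(mol),
        "mw": Descriptors.MolWt(mol),
        "rings": Chem.rdMolDescriptors.CalcNumRings(mol),
        "heavy": mol.GetNumHeavyAtoms(),
    }


def cluster_smiles_one(item):
    mol = parse(item.get("smiles"))
    if mol is None:
        return None
    out = []
    for atoms in item.get("clusters", []):
        atoms = [int(a) for a in atoms]
        try:
            sub = Chem.MolFragmentToSmiles(mol, atomsToUse=atoms, canonical=True)
            out.append(sub)
        except Exception:
            out.append(None)
    return out


def handle(req):
    op = req.get("op")
    if op == "canonical":
        return [canonical(s) for s in req["smiles"]]
    if op == "valid":
        return [parse(s) is not None for s in req["smiles"]]
    if op == "fragment":
        return [fragment_one(s) for s in req["smiles"]]
    if op == "reassemble":
        return [reassemble_one(f) for f in req["fragments"]]
    if op == "assemble_chain":
        allow = bool(req.get("allow_open", False))
        return [assemble_chain_one(f, allow) for f in req["fragments"]]
    if op == "graph":
        return [graph_one(s) for s in req["smiles"]]
    if op == "props":
        return [props_one(s) for s in req["smiles"]]
    if op == "cluster_smiles":
        return [cluster_smiles_one(it) for it in req["items"]]
    raise ValueError("unknown op: %r" % op)


def main():
    payload = json.load(sys.stdin)
    results = [handle(r) for r in payload.get("requests", [])]
    json.dump({"results": results}, sys.stdout)


if __name__ == "__main__":
    main()
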