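#!/usr/bin/env python
"""JSON-lines cheminformatics helper built on RDKit.

Reads one JSON request per line on stdin, writes one JSON response per line
on stdout.  Each request: {"id": <int>, "op": <str>, ...op args...}.
Each response: {"id": <int>, "ok": true, "result": ...} or
{"id": <int>, "ok": false, "error": "..."}.

Only standard primitives live here (parsing, canonicalization,
standardization, descriptors, BRICS bond perception, fragment-on-bonds,
fragment zipping, fingerprints, scaffold/functional-group extraction).
All fragmentation-rule, sequencing and modelling logic lives in the R
package that drives this process.
"""

import json
import math
import os
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, Lipinski, QED, BRICS
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

# --- RDKit Contrib: Ertl-Schuffenhauer SA score and Ertl functional groups
_sascorer = None
_ifg = None


def _contrib_dir():
    from rdkit import RDConfig
    cand = [RDConfig.RDContribDir,
            os.path.join(sys.prefix, "share", "RDKit", "Contrib")]
    for c in cand:
        if c and os.path.isdir(c):
            return c
    return None


def _get_sascorer():
    global _sascorer
    if _sascorer is None:
        d = _contrib_dir()
        sys.path.insert(0, os.path.join(d, "SA_Score"))
        import sascorer
        _sascorer = sascorer
    return _sascorer


def _get_ifg():
    global _ifg
    if _ifg is None:
        d = _contrib_dir()
        sys.path.insert(0, os.path.join(d, "IFG"))
        import ifg
        _ifg = ifg
    return _ifg


_uncharger = rdMolStandardize.Uncharger()
_lfc_params = rdMolStandardize.CleanupParameters()
_lfc_params.preferOrganic = True
_largest = rdMolStandardize.LargestFragmentChooser(_lfc_params)


def _mol(smi, sanitize=True):
    if smi is None:
        return None
    return Chem.MolFromSmiles(smi, sanitize=sanitize)


def _canon(mol, isomeric=True):
    return Chem.MolToSmiles(mol, isomericSmiles=isomeric)


# ---------------------------------------------------------------- ops

def op_ping(req):
    import rdkit
    return {"rdkit": rdkit.__version__, "pid": os.getpid()}


def op_standardize(req):
    out = []
    keep_stereo = req.get("keep_stereo", True)
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "reason": "parse_failure"})
            continue
        try:
            m = _largest.choose(m)
            if m is None or m.GetNumAtoms() == 0:
                out.append({"ok": False, "reason": "empty_after_desalt"})
                continue
            m = _uncharger.uncharge(m)
            Chem.SanitizeMol(m)
            if not keep_stereo:
                Chem.RemoveStereochemistry(m)
            out.append({"ok": True, "smiles": _canon(m)})
        except Exception:
            out.append({"ok": False, "reason": "parse_failure"})
    return out


def op_descriptors(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        try:
            out.append({
                "qed": float(QED.qed(m)),
                "logp": float(Descriptors.MolLogP(m)),
                "sas": float(_get_sascorer().calculateScore(m)),
                "mw": float(Descriptors.MolWt(m)),
                "hbd": int(Lipinski.NumHDonors(m)),
                "hba": int(Lipinski.NumHAcceptors(m)),
                "rb": int(Lipinski.NumRotatableBonds(m)),
            })
        except Exception:
            out.append(None)
    return out


def op_basic(req):
    """Molecular weight and heavy-atom count; dummies counted separately."""
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        nd = sum(1 for a in m.GetAtoms() if a.GetAtomicNum() == 0)
        out.append({"mw": float(Descriptors.MolWt(m)),
                    "heavy": int(m.GetNumAtoms() - nd),
                    "n_dummy": int(nd)})
    return out


def op_annotate(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        kek = Chem.Mol(m)
        try:
            Chem.Kekulize(kek, clearAromaticFlags=True)
        except Exception:
            kek = m
        ri = m.GetRingInfo()
        ranks = list(Chem.CanonicalRankAtoms(m, breakTies=True))
        atoms = []
        for a in m.GetAtoms():
            atoms.append({
                "idx": a.GetIdx(),
                "z": a.GetAtomicNum(),
                "symbol": a.GetSymbol(),
                "aromatic": a.GetIsAromatic(),
                "charge": a.GetFormalCharge(),
                "inring": a.IsInRing(),
                "nrings": ri.NumAtomRings(a.GetIdx()),
                "degree": a.GetDegree(),
                "isotope": a.GetIsotope(),
                "rank": ranks[a.GetIdx()],
            })
        bonds = []
        for b in m.GetBonds():
            kb = kek.GetBondWithIdx(b.GetIdx())
            bonds.append({
                "b": b.GetBeginAtomIdx(),
                "e": b.GetEndAtomIdx(),
                "order": float(kb.GetBondTypeAsDouble()),
                "ring": b.IsInRing(),
                "nrings": ri.NumBondRings(b.GetIdx()),
                "aromatic": b.GetIsAromatic(),
            })
        brics = []
        try:
            for (u, v), _lab in BRICS.FindBRICSBonds(m):
                brics.append([int(u), int(v)])
        except Exception:
            pass
        rings = [list(map(int, r)) for r in ri.AtomRings()]
        out.append({"natoms": m.GetNumAtoms(), "atoms": atoms,
                    "bonds": bonds, "rings": rings, "brics": brics})
    return out


def op_fragment(req):
    """Cut listed acyclic bonds, labelling both dummies of each cut with the
    bond id as isotope.  Returns per-fragment labelled SMILES plus the
    original atom indices contained in each fragment."""
    out = []
    for item in req["items"]:
        m = _mol(item["smiles"])
        if m is None:
            out.append({"ok": False, "reason": "parse_failure"})
            continue
        n0 = m.GetNumAtoms()
        cuts = item.get("cuts", [])
        if len(cuts) == 0:
            out.append({"ok": True,
                        "frags": [{"smiles": _canon(m),
                                   "orig_atoms": list(range(n0))}]})
            continue
        bidx, labels = [], []
        bad = False
        for (u, v, lab) in cuts:
            b = m.GetBondBetweenAtoms(int(u), int(v))
            if b is None:
                bad = True
                break
            bidx.append(b.GetIdx())
            labels.append((int(lab), int(lab)))
        if bad:
            out.append({"ok": False, "reason": "no_such_bond"})
            continue
        try:
            fm = Chem.FragmentOnBonds(m, bidx, addDummies=True,
                                      dummyLabels=labels)
            mapping = []
            pieces = Chem.GetMolFrags(fm, asMols=True, sanitizeFrags=True,
                                      fragsMolAtomMapping=mapping)
            frags = []
            for piece, amap in zip(pieces, mapping):
                frags.append(_frag_record(piece,
                                          [int(i) if i < n0 else -1
                                           for i in amap]))
            out.append({"ok": True, "frags": frags})
        except Exception as e:
            out.append({"ok": False, "reason": "fragment_error:%s" % e})
    return out


def _frag_record(piece, orig_of_atom):
    """SMILES of a fragment plus, for every atom of the *re-parsed* SMILES in
    order, the originating atom index (-1 for dummies / duplicated atoms)."""
    smi = Chem.MolToSmiles(piece, isomericSmiles=True)
    order = json.loads(piece.GetProp("_smilesAtomOutputOrder"))
    return {"smiles": smi,
            "orig_atoms": [orig_of_atom[k] for k in order]}


def op_fuse_split(req):
    """Separate one fused-ring shared edge (u, v) of a (scaffold) fragment.

    The edge atoms are duplicated into both subrings; all four copies become
    dummy atoms carrying isotope labels lu (copies of u) and lv (copies of
    v).  The shared edge bond itself is kept, with its kekulized order, in
    both subring fragments."""
    out = []
    for item in req["items"]:
        m = _mol(item["smiles"])
        if m is None:
            out.append({"ok": False, "reason": "parse_failure"})
            continue
        u, v = int(item["u"]), int(item["v"])
        lu, lv = int(item["lu"]), int(item["lv"])
        try:
            kek = Chem.Mol(m)
            Chem.Kekulize(kek, clearAromaticFlags=True)
            for a in kek.GetAtoms():
                a.SetIntProp("_orig", a.GetIdx())
            bond = kek.GetBondBetweenAtoms(u, v)
            if bond is None:
                out.append({"ok": False, "reason": "no_such_bond"})
                continue
            nb_u = [a.GetIdx() for a in kek.GetAtomWithIdx(u).GetNeighbors()
                    if a.GetIdx() != v]
            nb_v = [a.GetIdx() for a in kek.GetAtomWithIdx(v).GetNeighbors()
                    if a.GetIdx() != u]
            if len(nb_u) != 2 or len(nb_v) != 2:
                out.append({"ok": False, "reason": "not_simple_fusion"})
                continue
            # decide the two-sided partition by removing u,v
            probe = Chem.RWMol(kek)
            for idx in sorted([u, v], reverse=True):
                probe.RemoveAtom(idx)
            comp = Chem.GetMolFrags(probe.GetMol(),
                                    sanitizeFrags=False)
            if len(comp) != 2:
                out.append({"ok": False, "reason": "not_two_components"})
                continue
            orig_of = [a.GetIntProp("_orig") for a in probe.GetMol().GetAtoms()]
            sides = [set(orig_of[i] for i in c) for c in comp]

            frags = []
            for side in sides:
                rw = Chem.RWMol(kek)
                # drop every atom not on this side (keep u and v)
                drop = [a.GetIdx() for a in rw.GetAtoms()
                        if a.GetIntProp("_orig") not in side
                        and a.GetIntProp("_orig") not in (u, v)]
                for idx in sorted(drop, reverse=True):
                    rw.RemoveAtom(idx)
                sub = rw.GetMol()
                orig_of_atom = []
                for a in sub.GetAtoms():
                    o = a.GetIntProp("_orig")
                    if o == u or o == v:
                        a.SetAtomicNum(0)
                        a.SetIsotope(lu if o == u else lv)
                        a.SetFormalCharge(0)
                        a.SetNoImplicit(True)
                        a.SetNumExplicitHs(0)
                        a.SetChiralTag(Chem.ChiralType.CHI_UNSPECIFIED)
                        orig_of_atom.append(-1)
                    else:
                        orig_of_atom.append(o)
                # keep the kekulized form: re-aromatizing a ring that now
                # contains dummies would desynchronize the shared-edge bond
                # order between the two subring copies
                Chem.SanitizeMol(
                    sub,
                    Chem.SanitizeFlags.SANITIZE_ALL
                    ^ Chem.SanitizeFlags.SANITIZE_SETAROMATICITY
                    ^ Chem.SanitizeFlags.SANITIZE_KEKULIZE)
                frags.append(_frag_record(sub, orig_of_atom))
            out.append({"ok": True, "frags": frags,
                        "edge_order": float(bond.GetBondTypeAsDouble())})
        except Exception as e:
            out.append({"ok": False, "reason": "fuse_split_error:%s" % e})
    return out


def op_motif_token(req):
    """Strip isotope labels from a labelled fragment and emit its (optionally
    rooted) canonical SMILES token, reporting where each labelled dummy ends
    up in the token's atom order."""
    out = []
    for item in req["items"]:
        m = _mol(item["smiles"])
        if m is None:
            out.append({"ok": False, "reason": "parse_failure"})
            continue
        root_label = item.get("root_label", None)
        dummies = {}
        root_idx = -1
        for a in m.GetAtoms():
            if a.GetAtomicNum() == 0:
                dummies[a.GetIdx()] = a.GetIsotope()
                if root_label is not None and a.GetIsotope() == root_label \
                        and root_idx < 0:
                    root_idx = a.GetIdx()
                a.SetIsotope(0)
        if root_label is not None and root_idx < 0:
            out.append({"ok": False, "reason": "root_label_missing"})
            continue
        smi = Chem.MolToSmiles(m, isomericSmiles=True, canonical=True,
                               rootedAtAtom=root_idx)
        order = json.loads(m.GetProp("_smilesAtomOutputOrder"))
        pos_of = {atom_idx: pos for pos, atom_idx in enumerate(order)}
        slot = sorted(dummies.keys(), key=lambda i: pos_of[i])
        labels = [int(dummies[i]) for i in slot]
        adj = []
        for i in range(len(slot)):
            for j in range(i + 1, len(slot)):
                if m.GetBondBetweenAtoms(slot[i], slot[j]) is not None:
                    adj.append([i, j])
        out.append({"ok": True, "token": smi, "slots": labels,
                    "fuse_adjacent": adj})
    return out


def op_token_info(req):
    """Dummy-atom layout of a plain motif token: count, SMILES order,
    and which dummies are mutually bonded (fused-edge slots)."""
    out = []
    for smi in req["tokens"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "reason": "parse_failure"})
            continue
        dummy_idx = [a.GetIdx() for a in m.GetAtoms()
                     if a.GetAtomicNum() == 0]
        # atom indices from MolFromSmiles follow SMILES appearance order
        pairs = []
        for i in range(len(dummy_idx)):
            for j in range(i + 1, len(dummy_idx)):
                if m.GetBondBetweenAtoms(dummy_idx[i], dummy_idx[j]) is not None:
                    pairs.append([i, j])
        out.append({"ok": True, "n_dummy": len(dummy_idx),
                    "heavy": int(m.GetNumAtoms() - len(dummy_idx)),
                    "fuse_pairs": pairs})
    return out


def op_join(req):
    """Assemble a molecule from motif tokens.

    bonds: [[fi, di, fj, dj], ...]  join dummy di of fragment fi to dummy dj
           of fragment fj with a single bond (via molzip).
    fuses: [[fi, di1, di2, fj, dj1, dj2], ...]  identify dummy pair
           (di1,di2) of fi with (dj1,dj2) of fj; the merged atoms become
           carbons and the shared edge keeps fragment fi's bond order.
    Dummy positions d* index the fragment's dummies in SMILES order."""
    out = []
    for item in req["items"]:
        try:
            out.append(_join_one(item))
        except Exception as e:
            out.append({"ok": False, "reason": "join_error:%s" % e})
    return out


def _join_one(item):
    mols = []
    for smi in item["tokens"]:
        m = _mol(smi)
        if m is None:
            return {"ok": False, "reason": "parse_failure"}
        mols.append(m)
    offsets = []
    combined = None
    for m in mols:
        if combined is None:
            offsets.append(0)
            combined = m
        else:
            offsets.append(combined.GetNumAtoms())
            combined = Chem.CombineMols(combined, m)
    rw = Chem.RWMol(combined)
    dummy_at = []  # per fragment, global indices of its dummies in SMILES order
    for k, m in enumerate(mols):
        dummy_at.append([offsets[k] + a.GetIdx() for a in m.GetAtoms()
                         if a.GetAtomicNum() == 0])

    def gidx(f, d):
        return dummy_at[f][d]

    # label bond-join dummy pairs for molzip before any index-shifting edits
    for k, (fi, di, fj, dj) in enumerate(item.get("bonds", []), start=1):
        for g in (gidx(fi, di), gidx(fj, dj)):
            a = rw.GetAtomWithIdx(g)
            if a.GetAtomicNum() != 0 or a.GetAtomMapNum() != 0:
                return {"ok": False, "reason": "slot_reuse"}
            a.SetAtomMapNum(k)

    # --- fused-edge merges (manual surgery; fusion atoms are achiral C)
    remove = []
    for (fi, di1, di2, fj, dj1, dj2) in item.get("fuses", []):
        a1, a2 = gidx(fi, di1), gidx(fi, di2)
        b1, b2 = gidx(fj, dj1), gidx(fj, dj2)
        ba = rw.GetBondBetweenAtoms(a1, a2)
        bb = rw.GetBondBetweenAtoms(b1, b2)
        if ba is None or bb is None or ba.GetBondType() != bb.GetBondType():
            return {"ok": False, "reason": "incompatible_fused_edge"}
        for (src, dst) in ((b1, a1), (b2, a2)):
            for nb in rw.GetAtomWithIdx(src).GetNeighbors():
                ni = nb.GetIdx()
                if ni in (b1, b2):
                    continue
                bt = rw.GetBondBetweenAtoms(src, ni).GetBondType()
                if rw.GetBondBetweenAtoms(dst, ni) is None:
                    rw.AddBond(dst, ni, bt)
        for idx in (a1, a2):
            at = rw.GetAtomWithIdx(idx)
            at.SetAtomicNum(6)
            at.SetIsotope(0)
            at.SetNoImplicit(False)
        remove.extend([b1, b2])
    for idx in sorted(set(remove), reverse=True):
        rw.RemoveAtom(idx)

    mol = rw.GetMol()
    try:
        Chem.SanitizeMol(mol)
    except Exception:
        return {"ok": False, "reason": "valence_violation"}
    params = Chem.MolzipParams()
    params.label = Chem.MolzipLabel.AtomMapNumber
    try:
        zipped = Chem.molzip(mol, params)
        Chem.SanitizeMol(zipped)
    except Exception:
        return {"ok": False, "reason": "valence_violation"}
    for a in zipped.GetAtoms():
        if a.GetAtomicNum() == 0:
            return {"ok": False, "reason": "dangling_marker"}
    frags = Chem.GetMolFrags(zipped)
    if len(frags) != 1:
        return {"ok": False, "reason": "disconnected_result"}
    Chem.AssignStereochemistry(zipped, cleanIt=True, force=True)
    return {"ok": True, "smiles": _canon(zipped)}


def op_canonical(req):
    out = []
    strip = req.get("strip_stereo", False)
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        if strip:
            Chem.RemoveStereochemistry(m)
        out.append(_canon(m))
    return out


def op_fingerprint(req):
    radius = int(req.get("radius", 2))
    nbits = int(req.get("nbits", 2048))
    gen = AllChem.GetMorganGenerator(radius=radius, fpSize=nbits)
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        fp = gen.GetFingerprint(m)
        out.append([int(b) for b in fp.GetOnBits()])
    return out


def op_scaffold(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        try:
            sc = MurckoScaffold.GetScaffoldForMol(m)
            out.append(_canon(sc) if sc is not None else "")
        except Exception:
            out.append(None)
    return out


def op_brics_frags(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        try:
            out.append(sorted(BRICS.BRICSDecompose(m)))
        except Exception:
            out.append(None)
    return out


def op_fgs(req):
    ifg = _get_ifg()
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        try:
            out.append(sorted(set(g.type for g in ifg.identify_functional_groups(m))))
        except Exception:
            out.append(None)
    return out


def op_ring_systems(req):
    """Fused-ring connected components (rings sharing >= 1 atom)."""
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        rings = [set(r) for r in m.GetRingInfo().AtomRings()]
        comps = []
        for r in rings:
            merged = [c for c in comps if c & r]
            newc = set(r)
            for c in merged:
                newc |= c
                comps.remove(c)
            comps.append(newc)
        res = []
        for c in comps:
            try:
                res.append(Chem.MolFragmentToSmiles(
                    m, atomsToUse=sorted(c), isomericSmiles=False,
                    canonical=True))
            except Exception:
                pass
        out.append(sorted(res))
    return out


def op_assemble(req):
    """Join building blocks with new single bonds (fixture construction).
    bonds: [[pi, ai, pj, aj], ...] referring to part index / atom index."""
    out = []
    for item in req["items"]:
        try:
            mols = [_mol(s) for s in item["parts"]]
            if any(m is None for m in mols):
                out.append({"ok": False, "reason": "parse_failure"})
                continue
            offsets = []
            combined = None
            for m in mols:
                offsets.append(0 if combined is None else combined.GetNumAtoms())
                combined = m if combined is None else Chem.CombineMols(combined, m)
            rw = Chem.RWMol(combined)
            ok = True
            for (pi, ai, pj, aj) in item.get("bonds", []):
                u = offsets[pi] + ai
                v = offsets[pj] + aj
                au, av = rw.GetAtomWithIdx(u), rw.GetAtomWithIdx(v)
                if au.GetTotalNumHs() < 1 or av.GetTotalNumHs() < 1 \
                        or rw.GetBondBetweenAtoms(u, v) is not None:
                    ok = False
                    break
                rw.AddBond(u, v, Chem.BondType.SINGLE)
            if not ok:
                out.append({"ok": False, "reason": "no_free_valence"})
                continue
            mol = rw.GetMol()
            Chem.SanitizeMol(mol)
            if len(Chem.GetMolFrags(mol)) != 1:
                out.append({"ok": False, "reason": "disconnected_result"})
                continue
            out.append({"ok": True, "smiles": _canon(mol)})
        except Exception as e:
            out.append({"ok": False, "reason": "assemble_error:%s" % e})
    return out


def op_renumber(req):
    """Rewrite a SMILES with an explicit atom permutation (non-canonical
    output); used to probe atom-order invariance."""
    out = []
    for item in req["items"]:
        m = _mol(item["smiles"])
        if m is None:
            out.append(None)
            continue
        perm = [int(i) for i in item["perm"]]
        if sorted(perm) != list(range(m.GetNumAtoms())):
            out.append(None)
            continue
        m2 = Chem.RenumberAtoms(m, perm)
        out.append(Chem.MolToSmiles(m2, canonical=False, isomericSmiles=True))
    return out


def op_stereocenters(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        centers = Chem.FindMolChiralCenters(m, includeUnassigned=True,
                                            useLegacyImplementation=False)
        out.append([[int(i), tag] for i, tag in centers])
    return out


def op_assign_stereo(req):
    """Set tetrahedral tags (True -> CW, False -> CCW) on the listed atoms."""
    out = []
    for item in req["items"]:
        m = _mol(item["smiles"])
        if m is None:
            out.append(None)
            continue
        try:
            for (idx, cw) in item["tags"]:
                tag = Chem.ChiralType.CHI_TETRAHEDRAL_CW if cw \
                    else Chem.ChiralType.CHI_TETRAHEDRAL_CCW
                m.GetAtomWithIdx(int(idx)).SetChiralTag(tag)
            Chem.AssignStereochemistry(m, cleanIt=True, force=True)
            out.append(_canon(m))
        except Exception:
            out.append(None)
    return out


OPS = {name[3:]: fn for name, fn in list(globals().items())
       if name.startswith("op_")}


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            if req.get("op") == "quit":
                break
            fn = OPS[req["op"]]
            res = {"id": req.get("id"), "ok": True, "result": fn(req)}
        except Exception as e:
            res = {"id": req.get("id") if isinstance(req, dict) else None,
                   "ok": False, "error": "%s: %s" % (type(e).__name__, e)}
        sys.stdout.write(json.dumps(res) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
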