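"""Persistent RDKit worker.

Serves newline-delimited JSON requests over a localhost socket. Started by the
R package; exits when the client disconnects. All operations are deterministic
(no RNG); randomness lives entirely on the R side.

Protocol: one JSON object per line in, one per line out.
  request:  {"op": <name>, ...op-specific fields...}
  response: {"ok": true, "result": ...} | {"ok": false, "error": "..."}
Vectorized ops report per-item failures as null entries plus an "errors" map.
"""

import json
import os
import socket
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, Descriptors, QED, RDConfig, rdFMCS
from rdkit.Chem import rdFingerprintGenerator, rdMolDescriptors
from rdkit import DataStructs

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

_MORGAN = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=2048)


# ---------------------------------------------------------------- helpers

def _mol(smiles, sanitize=True):
    if smiles is None:
        return None
    return Chem.MolFromSmiles(smiles, sanitize=sanitize)


def _canon(smiles):
    m = _mol(smiles)
    return None if m is None else Chem.MolToSmiles(m)


def _strip_dummies(mol):
    em = Chem.RWMol(mol)
    idx = [a.GetIdx() for a in em.GetAtoms() if a.GetAtomicNum() == 0]
    for i in sorted(idx, reverse=True):
        em.RemoveAtom(i)
    m = em.GetMol()
    try:
        Chem.SanitizeMol(m)
    except Exception:
        return None
    return m


def _fingerprint(mol):
    return _MORGAN.GetFingerprint(mol)


# ---------------------------------------------------------------- fragmentation

def _cut_bond_ids(mol):
    """Acyclic single bonds with at least one endpoint inside a ring."""
    out = []
    for b in mol.GetBonds():
        if b.GetBondType() != Chem.BondType.SINGLE or b.IsInRing():
            continue
        if b.GetBeginAtom().IsInRing() or b.GetEndAtom().IsInRing():
            out.append(b.GetIdx())
    return out


def _slot_relabel(frag):
    """Renumber dummy isotopes canonically 1..n; return (smiles, cut_id->slot)."""
    dummies = [a.GetIdx() for a in frag.GetAtoms() if a.GetAtomicNum() == 0]
    if not dummies:
        return Chem.MolToSmiles(frag), {}
    plain = Chem.Mol(frag)
    for a in plain.GetAtoms():
        if a.GetAtomicNum() == 0:
            a.SetIsotope(0)
    ranks = list(Chem.CanonicalRankAtoms(plain, breakTies=True))
    order = sorted(dummies, key=lambda i: ranks[i])
    relab = Chem.Mol(frag)
    cut_to_slot = {}
    for slot, idx in enumerate(order, start=1):
        cut_id = frag.GetAtomWithIdx(idx).GetIsotope()
        cut_to_slot[cut_id] = slot
        relab.GetAtomWithIdx(idx).SetIsotope(slot)
    return Chem.MolToSmiles(relab), cut_to_slot


def op_decompose(req):
    out = []
    for s in req["smiles"]:
        mol = _mol(s)
        if mol is None:
            out.append({"error": "unparsable SMILES: %r" % s})
            continue
        bonds = _cut_bond_ids(mol)
        if not bonds:
            out.append({
                "fragments": [{"smiles": Chem.MolToSmiles(mol), "n_attachments": 0}],
                "topology": [],
            })
            continue
        labels = [(k + 1, k + 1) for k in range(len(bonds))]
        broken = Chem.FragmentOnBonds(mol, bonds, addDummies=True, dummyLabels=labels)
        pieces = Chem.GetMolFrags(broken, asMols=True, sanitizeFrags=True)
        frags, cut_ends = [], {}
        for fi, piece in enumerate(pieces, start=1):
            smi, cut_to_slot = _slot_relabel(piece)
            frags.append({"smiles": smi, "n_attachments": len(cut_to_slot)})
            for cut_id, slot in cut_to_slot.items():
                cut_ends.setdefault(cut_id, []).append((fi, slot))
        topo = []
        for cut_id in sorted(cut_ends):
            ends = cut_ends[cut_id]
            if len(ends) != 2:
                out.append({"error": "internal: cut %d has %d ends" % (cut_id, len(ends))})
                topo = None
                break
            (fi, si), (fj, sj) = ends
            topo.append([fi, si, fj, sj])
        if topo is None:
            continue
        out.append({"fragments": frags, "topology": topo})
    return out


def _parse_fragment(smiles):
    """Parse a marker-bearing fragment SMILES; return (mol, slot->atom_idx)."""
    m = _mol(smiles)
    if m is None:
        return None, None
    dummies = [a for a in m.GetAtoms() if a.GetAtomicNum() == 0]
    slots = {}
    if dummies and all(a.GetIsotope() == 0 for a in dummies):
        for slot, a in enumerate(dummies, start=1):
            slots[slot] = a.GetIdx()
    else:
        for a in dummies:
            slots[a.GetIsotope()] = a.GetIdx()
    return m, slots


def _assemble_one(frag_smiles, topology):
    mols, slot_maps, offsets = [], [], []
    total = 0
    for s in frag_smiles:
        m, slots = _parse_fragment(s)
        if m is None:
            return None, "unparsable fragment SMILES: %r" % s
        mols.append(m)
        slot_maps.append(slots)
        offsets.append(total)
        total += m.GetNumAtoms()
    n_attach = sum(len(s) for s in slot_maps)
    if n_attach % 2 != 0:
        return None, "odd total attachment points (%d)" % n_attach
    if len(topology) * 2 != n_attach:
        return None, "topology covers %d attachment points, fragments carry %d" % (
            len(topology) * 2, n_attach)
    combo = mols[0]
    for m in mols[1:]:
        combo = Chem.CombineMols(combo, m)
    em = Chem.RWMol(combo)
    used = set()
    dummy_idx = []
    for fi, si, fj, sj in topology:
        for fk, sk in ((fi, si), (fj, sj)):
            if not (1 <= fk <= len(mols)) or sk not in slot_maps[fk - 1]:
                return None, "no attachment slot %d on fragment %d" % (sk, fk)
            if (fk, sk) in used:
                return None, "attachment slot %d on fragment %d used twice" % (sk, fk)
            used.add((fk, sk))
        d1 = offsets[fi - 1] + slot_maps[fi - 1][si]
        d2 = offsets[fj - 1] + slot_maps[fj - 1][sj]
        n1 = [a.GetIdx() for a in em.GetAtomWithIdx(d1).GetNeighbors()]
        n2 = [a.GetIdx() for a in em.GetAtomWithIdx(d2).GetNeighbors()]
        if len(n1) != 1 or len(n2) != 1:
            return None, "attachment marker must have exactly one neighbor"
        em.AddBond(n1[0], n2[0], Chem.BondType.SINGLE)
        dummy_idx += [d1, d2]
    for i in sorted(dummy_idx, reverse=True):
        em.RemoveAtom(i)
    prod = em.GetMol()
    try:
        Chem.SanitizeMol(prod)
    except Exception as exc:
        return None, "invalid product %r: %s" % (Chem.MolToSmiles(prod, canonical=False), exc)
    return Chem.MolToSmiles(prod), None


def op_assemble(req):
    out = []
    for job in req["jobs"]:
        smi, err = _assemble_one(job["fragments"], job.get("topology") or [])
        out.append({"smiles": smi, "error": err})
    return out


# ---------------------------------------------------------------- similarity

def op_mcs_tanimoto(req):
    timeout = int(req.get("timeout", 1))
    out = []
    for s1, s2 in req["pairs"]:
        m1, m2 = _mol(s1), _mol(s2)
        if m1 is None or m2 is None:
            out.append(None)
            continue
        m1, m2 = _strip_dummies(m1), _strip_dummies(m2)
        if m1 is None or m2 is None or m1.GetNumAtoms() == 0 or m2.GetNumAtoms() == 0:
            both_empty = (m1 is not None and m2 is not None
                          and m1.GetNumAtoms() == 0 and m2.GetNumAtoms() == 0)
            out.append(1.0 if both_empty else 0.0)
            continue
        res = rdFMCS.FindMCS(
            [m1, m2],
            atomCompare=rdFMCS.AtomCompare.CompareElements,
            bondCompare=rdFMCS.BondCompare.CompareOrder,
            ringMatchesRingOnly=True,
            timeout=timeout,
        )
        mcs = max(res.numAtoms, 0)
        denom = m1.GetNumAtoms() + m2.GetNumAtoms() - mcs
        out.append(1.0 if denom == 0 else mcs / denom)
    return out


def op_fp_tanimoto(req):
    if "ref" in req and req["ref"] is not None:
        ref = _mol(req["ref"])
        if ref is None:
            raise ValueError("unparsable reference SMILES: %r" % req["ref"])
        rfp = _fingerprint(ref)
        out = []
        for s in req["smiles"]:
            m = _mol(s)
            out.append(None if m is None else DataStructs.TanimotoSimilarity(rfp, _fingerprint(m)))
        return out
    out = []
    for s1, s2 in req["pairs"]:
        m1, m2 = _mol(s1), _mol(s2)
        if m1 is None or m2 is None:
            out.append(None)
        else:
            out.append(DataStructs.TanimotoSimilarity(_fingerprint(m1), _fingerprint(m2)))
    return out


# ---------------------------------------------------------------- properties

def _penalized_logp(mol):
    """Crippen logP minus raw SA score minus the oversized-ring penalty."""
    logp = Crippen.MolLogP(mol)
    sa = sascorer.calculateScore(mol)
    ring_sizes = [len(r) for r in mol.GetRingInfo().AtomRings()]
    penalty = max(max(ring_sizes) - 6, 0) if ring_sizes else 0
    return logp - sa - penalty


def _descriptors(mol):
    basic_n = len(mol.GetSubstructMatches(
        Chem.MolFromSmarts("[NX3;H2,H1,H0;!$(NC=O);!$(N=*);!a]")))
    ring_sizes = [len(r) for r in mol.GetRingInfo().AtomRings()]
    return {
        "mw": Descriptors.MolWt(mol),
        "logp": Crippen.MolLogP(mol),
        "tpsa": rdMolDescriptors.CalcTPSA(mol),
        "hba": rdMolDescriptors.CalcNumHBA(mol),
        "hbd": rdMolDescriptors.CalcNumHBD(mol),
        "rotb": rdMolDescriptors.CalcNumRotatableBonds(mol),
        "arom_rings": rdMolDescriptors.CalcNumAromaticRings(mol),
        "rings": rdMolDescriptors.CalcNumRings(mol),
        "heavy_atoms": mol.GetNumHeavyAtoms(),
        "frac_csp3": rdMolDescriptors.CalcFractionCSP3(mol),
        "largest_ring": max(ring_sizes) if ring_sizes else 0,
        "basic_n": basic_n,
        "arom_n": sum(1 for a in mol.GetAtoms()
                      if a.GetIsAromatic() and a.GetAtomicNum() == 7),
        "sa_raw": sascorer.calculateScore(mol),
    }


def op_score(req):
    props = req["properties"]
    lead = _mol(req.get("lead")) if req.get("lead") else None
    lead_fp = _fingerprint(lead) if lead is not None else None
    lead_plogp = _penalized_logp(lead) if lead is not None else None
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out.append(None)
            continue
        row = {}
        for p in props:
            if p == "QED":
                row[p] = QED.qed(m)
            elif p == "LogP":
                row[p] = Crippen.MolLogP(m)
            elif p == "PLogP":
                row[p] = _penalized_logp(m)
            elif p == "PLogP_imp":
                if lead_plogp is None:
                    raise ValueError("PLogP_imp requires a lead molecule")
                row[p] = _penalized_logp(m) - lead_plogp
            elif p == "SA":
                row[p] = (10.0 - sascorer.calculateScore(m)) / 9.0
            elif p == "SIM":
                if lead_fp is None:
                    raise ValueError("SIM requires a lead molecule")
                row[p] = DataStructs.TanimotoSimilarity(lead_fp, _fingerprint(m))
            else:
                raise ValueError("unknown property %r" % p)
        out.append(row)
    return out


def op_descriptors(req):
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        out.append(None if m is None else _descriptors(m))
    return out


def op_substructure(req):
    patt = Chem.MolFromSmarts(req["smarts"])
    if patt is None:
        raise ValueError("unparsable SMARTS: %r" % req["smarts"])
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        out.append(None if m is None else bool(m.HasSubstructMatch(patt)))
    return out


def op_canon(req):
    return [_canon(s) for s in req["smiles"]]


OPS = {
    "ping": lambda req: "pong",
    "canon": op_canon,
    "decompose": op_decompose,
    "assemble": op_assemble,
    "mcs_tanimoto": op_mcs_tanimoto,
    "fp_tanimoto": op_fp_tanimoto,
    "score": op_score,
    "descriptors": op_descriptors,
    "substructure": op_substructure,
}


def main():
    port_file = sys.argv[1]
    srv = socket.socket(socket.AF_INET, socket.SOCK_STREAM)
    srv.setsockopt(socket.SOL_SOCKET, socket.SO_REUSEADDR, 1)
    srv.bind(("127.0.0.1", 0))
    port = srv.getsockname()[1]
    tmp = port_file + ".tmp"
    with open(tmp, "w") as fh:
        fh.write("%d\n" % port)
    os.replace(tmp, port_file)
    srv.listen(1)
    conn, _ = srv.accept()
    srv.close()
    f = conn.makefile("rwb")
    while True:
        line = f.readline()
        if not line:
            break
        try:
            req = json.loads(line)
            if req.get("op") == "shutdown":
                f.write(b'{"ok": true, "result": "bye"}\n')
                f.flush()
                break
            fn = OPS.get(req.get("op"))
            if fn is None:
                resp = {"ok": False, "error": "unknown op %r" % req.get("op")}
            else:
                resp = {"ok": True, "result": fn(req)}
        except Exception as exc:  # noqa: BLE001 - report, keep serving
            resp = {"ok": False, "error": str(exc)}
        f.write((json.dumps(resp) + "\n").encode())
        f.flush()


if __name__ == "__main__":
    main()
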