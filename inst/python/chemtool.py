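#!/usr/bin/env python
"""Batched chemistry kernel for the pathsense R package.

Invoked as:  python chemtool.py <op> <request.json> <response.json>

All heavy cheminformatics (SMILES/InChI parsing, canonicalization, Morgan
fingerprints, retro reaction-SMARTS application) happens here so the R side
never re-implements a chemical parser.  Every op is a pure batch: one JSON
request in, one JSON response out.  Determinism: reactant sets are
canonicalized and sorted before they are returned.
"""

import json
import sys


def _fail(msg, code=1):
    sys.stderr.write("chemtool: %s\n" % msg)
    sys.exit(code)


try:
    from rdkit import Chem, RDLogger
    from rdkit.Chem import AllChem

    RDLogger.DisableLog("rdApp.*")
except Exception as exc:  # pragma: no cover - environment defect
    Chem = None
    _RDKIT_ERR = str(exc)


def _mol_from_structure(s):
    """Parse a SMILES or InChI string; return (mol, error)."""
    if not isinstance(s, str) or not s.strip():
        return None, "empty structure"
    s = s.strip()
    if s.startswith("InChI="):
        mol = Chem.MolFromInchi(s)
    else:
        mol = Chem.MolFromSmiles(s)
    if mol is None:
        return None, "unparsable structure: %r" % s
    return mol, None


def _describe(mol, radius, nbits):
    """Canonical SMILES, InChI, InChIKey and Morgan on-bit indices."""
    smi = Chem.MolToSmiles(mol)
    inchi = Chem.MolToInchi(mol)
    key = Chem.InchiToInchiKey(inchi) if inchi else None
    if not key:
        # Molecules outside the InChI domain (rare) fall back to SMILES key.
        key = "SMI-" + smi
        inchi = None
    fp = AllChem.GetMorganFingerprintAsBitVect(mol, int(radius), nBits=int(nbits))
    return {
        "smiles": smi,
        "inchi": inchi,
        "inchikey": key,
        "fp": sorted(fp.GetOnBits()),
    }


def op_canon(req):
    radius = req.get("fp_radius", 2)
    nbits = req.get("fp_bits", 2048)
    out = []
    for s in req["items"]:
        mol, err = _mol_from_structure(s)
        if mol is None:
            out.append({"input": s, "ok": False, "error": err})
        else:
            rec = _describe(mol, radius, nbits)
            rec.update({"input": s, "ok": True})
            out.append(rec)
    return {"items": out}


def op_check_rules(req):
    """Validate reaction SMARTS; report template arities."""
    out = []
    for r in req["rules"]:
        rid, smarts = r["rule_id"], r["smarts"]
        try:
            rxn = AllChem.ReactionFromSmarts(smarts)
            if rxn is None:
                raise ValueError("not a reaction SMARTS")
            out.append(
                {
                    "rule_id": rid,
                    "ok": True,
                    "n_lhs": rxn.GetNumReactantTemplates(),
                    "n_rhs": rxn.GetNumProductTemplates(),
                }
            )
        except Exception as exc:
            out.append({"rule_id": rid, "ok": False, "error": str(exc)})
    return {"rules": out}


def _apply_rule_mol(rxn, mol):
    """Run a single-substrate retro reaction; return list of reactant
    SMILES tuples (canonical, sorted, de-duplicated).  Unparsable product
    sets are dropped (counted by the caller)."""
    res = []
    dropped = 0
    try:
        prods = rxn.RunReactants((mol,))
    except Exception:
        return [], 1
    seen = set()
    for pset in prods:
        smis = []
        bad = False
        for p in pset:
            try:
                Chem.SanitizeMol(p)
                smis.append(Chem.MolToSmiles(p))
            except Exception:
                bad = True
                break
        if bad or not smis:
            dropped += 1
            continue
        tup = tuple(sorted(set(smis)))
        if tup not in seen:
            seen.add(tup)
            res.append(list(tup))
    return res, dropped


def _compile_rules(rules):
    compiled = []
    for r in rules:
        try:
            rxn = AllChem.ReactionFromSmarts(r["smarts"])
            if rxn is None or rxn.GetNumReactantTemplates() != 1:
                continue
            compiled.append((r["rule_id"], rxn))
        except Exception:
            continue
    return compiled


def op_apply(req):
    """Apply every rule to every compound (one backward step each)."""
    radius = req.get("fp_radius", 2)
    nbits = req.get("fp_bits", 2048)
    compiled = _compile_rules(req["rules"])
    apps = []
    dropped = 0
    new_smiles = {}
    for s in req["compounds"]:
        mol, err = _mol_from_structure(s)
        if mol is None:
            continue
        csmi = Chem.MolToSmiles(mol)
        for rid, rxn in compiled:
            sets, d = _apply_rule_mol(rxn, mol)
            dropped += d
            for rs in sets:
                apps.append({"rule_id": rid, "product": csmi, "reactants": rs})
                for r in rs:
                    new_smiles[r] = True
        new_smiles[csmi] = True
    info = []
    for s in sorted(new_smiles):
        mol = Chem.MolFromSmiles(s)
        if mol is None:
            continue
        rec = _describe(mol, radius, nbits)
        rec["input"] = s
        info.append(rec)
    return {"applications": apps, "compounds": info, "dropped": dropped}


def op_expand(req):
    """Iterated backward expansion (BFS) from seed compounds.

    Returns the full rule-application table up to `depth` steps, bounded by
    `max_compounds` distinct molecules; used by the R side to prefetch and
    memoise rule applications before tree search."""
    radius = req.get("fp_radius", 2)
    nbits = req.get("fp_bits", 2048)
    depth = int(req.get("depth", 3))
    cap = int(req.get("max_compounds", 5000))
    compiled = _compile_rules(req["rules"])

    frontier = []
    known = {}
    for s in req["seeds"]:
        mol, err = _mol_from_structure(s)
        if mol is None:
            continue
        csmi = Chem.MolToSmiles(mol)
        if csmi not in known:
            known[csmi] = mol
            frontier.append(csmi)

    apps = []
    dropped = 0
    expanded = set()
    truncated = False
    for _ in range(depth):
        nxt = []
        for csmi in frontier:
            if csmi in expanded:
                continue
            expanded.add(csmi)
            mol = known[csmi]
            for rid, rxn in compiled:
                sets, d = _apply_rule_mol(rxn, mol)
                dropped += d
                for rs in sets:
                    apps.append({"rule_id": rid, "product": csmi, "reactants": rs})
                    for r in rs:
                        if r not in known:
                            if len(known) >= cap:
                                truncated = True
                                continue
                            m2 = Chem.MolFromSmiles(r)
                            if m2 is None:
                                continue
                            known[r] = m2
                            nxt.append(r)
        frontier = nxt
        if not frontier:
            break

    info = []
    for s in sorted(known):
        rec = _describe(known[s], radius, nbits)
        rec["input"] = s
        info.append(rec)
    return {
        "applications": apps,
        "compounds": info,
        "expanded": sorted(expanded),
        "dropped": dropped,
        "truncated": truncated,
    }


def op_validate_sbml(req):
    """Strict SBML validation through libsbml when available."""
    try:
        import libsbml
    except Exception as exc:
        return {"available": False, "error": str(exc)}
    doc = libsbml.readSBMLFromFile(req["path"])
    n_read = doc.getNumErrors(libsbml.LIBSBML_SEV_ERROR)
    doc.checkConsistency()
    n_cons = doc.getNumErrors(libsbml.LIBSBML_SEV_ERROR)
    msgs = []
    for i in range(doc.getNumErrors()):
        e = doc.getError(i)
        if e.getSeverity() >= libsbml.LIBSBML_SEV_ERROR:
            msgs.append(e.getMessage().strip())
    return {"available": True, "n_errors": int(max(n_read, n_cons)), "messages": msgs}


OPS = {
    "canon": op_canon,
    "check_rules": op_check_rules,
    "apply": op_apply,
    "expand": op_expand,
    "validate_sbml": op_validate_sbml,
}


def main(argv):
    if len(argv) != 4:
        _fail("usage: chemtool.py <op> <request.json> <response.json>", 2)
    op, req_path, resp_path = argv[1], argv[2], argv[3]
    if Chem is None:
        _fail("rdkit unavailable: %s" % _RDKIT_ERR, 3)
    if op not in OPS:
        _fail("unknown op %r" % op, 2)
    with open(req_path) as fh:
        req = json.load(fh)
    resp = OPS[op](req)
    with open(resp_path, "w") as fh:
        json.dump(resp, fh)


if __name__ == "__main__":
    main(sys.argv)
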