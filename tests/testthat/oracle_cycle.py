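import sys
from rdkit import Chem
from rdkit import RDLogger
RDLogger.DisableLog('rdApp.*')
def cyc(smi):
    m = Chem.MolFromSmiles(smi)
    if m is None: return "NA"
    rw = Chem.RWMol(m)
    dummies = [a.GetIdx() for a in rw.GetAtoms() if a.GetAtomicNum()==0]
    if len(dummies)!=2: return "NA"
    nbrs = [rw.GetAtomWithIdx(d).GetNeighbors()[0].GetIdx() for d in dummies]
    if nbrs[0]==nbrs[1]:
        tag="loop:"
    elif rw.GetBondBetweenAtoms(nbrs[0],nbrs[1]) is not None:
        for d in dummies: rw.GetAtomWithIdx(d).SetAtomicNum(54)
        return "fused:"+Chem.MolToSmiles(rw.GetMol())
    else:
        rw.AddBond(nbrs[0],nbrs[1],Chem.BondType.SINGLE)
        tag=""
    for d in sorted(dummies, reverse=True): rw.RemoveAtom(d)
    m2 = rw.GetMol()
    try: Chem.SanitizeMol(m2)
    except Exception: return "NA"
    return tag+Chem.MolToSmiles(m2)
for line in sys.stdin:
    print(cyc(line.strip()))
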