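# Reported (flash-protocol) vs decision-tree-predicted per-Mn oxidation
# states for 38 photosystem II structures, two monomers each.
# reported_s is the experimentally assigned Kok S index; oxidations are the
# predicted Mn1..Mn4 labels from which the predicted S index derives.
pdb_id,method,monomer,reported_s,oxidations
3wu2,X-ray,1,1,"III,III,III,II"
3wu2,X-ray,2,1,"III,IV,III,II"
4il6,X-ray,1,1,"III,IV,III,III"
4il6,X-ray,2,1,"III,IV,III,III"
4pj0,X-ray,1,1,"III,IV,III,II"
4pj0,X-ray,2,1,"III,III,III,II"
4ub6,XFEL,1,1,"III,IV,III,III"
4ub6,XFEL,2,1,"III,IV,IV,III"
4ub8,XFEL,1,1,"III,IV,III,III"
4ub8,XFEL,2,1,"III,IV,III,III"
5b5e,X-ray,1,1,"III,IV,III,III"
5b5e,X-ray,2,1,"III,IV,IV,III"
5b66,X-ray,1,1,"III,IV,III,III"
5b66,X-ray,2,1,"III,IV,IV,II"
5gth,XFEL,1,1,"III,IV,IV,III"
5gth,XFEL,2,1,"III,IV,IV,III"
5gti,XFEL,1,3,"III,IV,IV,III"
5gti,XFEL,2,3,"III,IV,IV,III"
5h2f,X-ray,1,1,"III,III,III,III"
5h2f,X-ray,2,1,"III,IV,III,II"
5tis,XFEL,1,3,"III,IV,III,III"
5tis,XFEL,2,3,"III,III,IV,III"
5ws5,XFEL,1,1,"III,IV,IV,III"
5ws5,XFEL,2,1,"III,IV,IV,III"
5ws6,XFEL,1,3,"III,IV,IV,III"
5ws6,XFEL,2,3,"III,IV,IV,III"
5zzn,cryoEM,1,1,"III,IV,III,II"
5zzn,cryoEM,2,1,"III,IV,III,II"
6dhe,XFEL,1,1,"III,IV,IV,III"
6dhe,XFEL,2,1,"III,IV,IV,III"
6dhf,XFEL,1,2,"III,IV,IV,IV"
6dhf,XFEL,2,2,"III,IV,IV,III"
6dho,XFEL,1,3,"IV,IV,IV,III"
6dho,XFEL,2,3,"III,IV,IV,III"
6dhp,XFEL,1,0,"IV,IV,IV,IV"
6dhp,XFEL,2,0,"III,IV,IV,IV"
6jlj,XFEL,1,1,"III,IV,IV,III"
6jlj,XFEL,2,1,"III,IV,IV,III"
6jlk,XFEL,1,2,"III,IV,IV,III"
6jlk,XFEL,2,2,"III,IV,IV,III"
6jll,XFEL,1,3,"IV,IV,IV,III"
6jll,XFEL,2,3,"IV,IV,IV,III"
6jlm,XFEL,1,1,"III,IV,IV,III"
6jlm,XFEL,2,1,"III,IV,IV,III"
6jln,XFEL,1,2,"III,IV,III,III"
6jln,XFEL,2,2,"III,IV,IV,III"
6jlo,XFEL,1,3,"III,III,IV,III"
6jlo,XFEL,2,3,"III,IV,IV,III"
6jlp,XFEL,1,0,"IV,IV,IV,II"
6jlp,XFEL,2,0,"III,IV,IV,III"
6w1o,XFEL,1,1,"III,IV,IV,III"
6w1o,XFEL,2,1,"III,IV,IV,III"
6w1p,XFEL,1,2,"III,IV,IV,III"
6w1p,XFEL,2,2,"III,IV,IV,III"
6w1v,XFEL,1,3,"IV,IV,IV,IV"
6w1v,XFEL,2,3,"III,IV,IV,III"
7cji,XFEL,1,1,"III,IV,IV,III"
7cji,XFEL,2,1,"III,IV,IV,II"
7cjj,XFEL,1,2,"III,IV,IV,III"
7cjj,XFEL,2,2,"III,IV,IV,III"
7cou,XFEL,1,1,"III,IV,IV,III"
7cou,XFEL,2,1,"III,IV,IV,II"
7d1t,cryoEM,1,1,"III,II,II,II"
7d1t,cryoEM,2,1,"III,II,II,II"
7d1u,cryoEM,1,1,"III,III,III,II"
7d1u,cryoEM,2,1,"III,III,III,II"
7n8o,cryoEM,1,1,"II,II,II,II"
7n8o,cryoEM,2,1,"II,II,II,II"
7rcv,cryoEM,1,1,"II,II,II,II"
7rcv,cryoEM,2,1,"II,II,II,II"
7rf2,XFEL,1,1,"III,IV,IV,IV"
7rf2,XFEL,2,1,"III,IV,IV,III"
7rf3,XFEL,1,2,"III,IV,IV,III"
7rf3,XFEL,2,2,"III,IV,IV,IV"
7rf8,XFEL,1,3,"III,IV,IV,IV"
7rf8,XFEL,2,3,"III,IV,IV,III"
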