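# Synthetic demonstration network (constructed stand-in, not a published
# organism model).  Lumped fermentation pathways: glucose enters a
# balanced pyruvate pool that feeds lactate overflow, oxidative growth
# and product formation; glutamine is consumed through a balanced
# glutamate pool.  The four elementary modes of this network have
# linearly independent external signatures, so each mode is essential:
# removing any active mode strictly worsens the attainable fit.
[species]
Glc external glucose
Lac external lactate
Gln external glutamine
Amm external ammonium
CO2 external carbon-dioxide
mAb external antibody-product
Xv external viable-cells
Pyr internal pyruvate-pool
GluI internal glutamate-pool
[reactions]
upt : Glc -> 2 Pyr
ferm : Pyr -> Lac
ox : Pyr -> 0.3 CO2 + 0.4 Xv
prod : Pyr -> 0.1 CO2 + 0.2 mAb
glnup : Gln -> GluI
glnox : GluI -> Amm + 0.25 CO2 + 0.1 Xv
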