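# 14 temperate deciduous species (Beijing), with the chilling model and
# thresholds assigned to each, the life form and the spring event analysed
# (FLD first leaf date, FFD first flowering date).
species:
  - name: Jasminum nudiflorum
    common: Winter jasmine
    life_form: shrub
    event: FFD
    chill_model: {kind: threshold, T1: 5}
  - name: Cotoneaster horizontalis
    common: Rock cotoneaster
    life_form: shrub
    event: FLD
    chill_model: {kind: triangular, Top: 1}
  - name: Syringa oblata
    common: Early blooming lilac
    life_form: shrub
    event: FLD
    chill_model: {kind: triangular, Top: 5}
  - name: Salix babylonica
    common: Weeping willow
    life_form: tree
    event: FLD
    chill_model: {kind: threshold, T1: 5}
  - name: Viburnum dilatatum
    common: Linden arrowwood
    life_form: shrub
    event: FLD
    chill_model: {kind: threshold, T1: 7}
  - name: Lespedeza bicolor
    common: Shrub lespedeza
    life_form: shrub
    event: FLD
    chill_model: {kind: range, T2: -5, T3: 5}
  - name: Forsythia suspensa
    common: Weeping forsythia
    life_form: shrub
    event: FFD
    chill_model: {kind: triangular, Top: 5}
  - name: Amygdalus triloba
    common: Flowering plum
    life_form: tree
    event: FFD
    chill_model: {kind: threshold, T1: 5}
  - name: Populus simonii
    common: Simon poplar
    life_form: tree
    event: FLD
    chill_model: {kind: triangular, Top: 1}
  - name: Malus micromalus
    common: Kaido crabapple
    life_form: tree
    event: FLD
    chill_model: {kind: triangular, Top: 3}
  - name: Cerasus tomentosa
    common: Nanjing cherry
    life_form: shrub
    event: FLD
    chill_model: {kind: triangular, Top: 5}
  - name: Ginkgo biloba
    common: Maidenhair tree
    life_form: tree
    event: FLD
    chill_model: {kind: threshold, T1: 7}
  - name: Metasequoia glyptostroboides
    common: Dawn redwood
    life_form: tree
    event: FLD
    chill_model: {kind: threshold, T1: 7}
  - name: Fraxinus chinensis
    common: Chinese ash
    life_form: tree
    event: FLD
    chill_model: {kind: threshold, T1: 5}
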