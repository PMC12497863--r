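# SynapseKinetics

Quantitative tools for studying how cytotoxic CD8 T cells and natural
killer (NK) cells interact in time-lapse microscopy, and for screening the
molecular crosstalk behind those interactions. The package is aimed at
immunologists and image analysts who track cells in co-culture movies and
want reproducible, scriptable versions of four common readouts:

1. **Contact kinetics.** Each tracked T cell's trajectory is split into
   three behavioral phases around a contact episode with an NK cell —
   Ph1 (before contact), Ph2 (during contact), Ph3 (after contact). The
   per-phase velocity is total displacement over elapsed time (µm/s), and
   the **deceleration ratio** is

   `ratio = v(Ph2) / v(Ph1)`

   A ratio ≤ 0.2 marks a ≥ 5-fold slowdown on engagement, the kinetic
   signature of a stable immune synapse.

2. **Speed–Distance Index (SDI).** A per-frame pair interaction metric,

   `SDI(t) = v_rel(t) / (d(t) + ε)`

   where `v_rel` is the magnitude of the difference of the two cells'
   velocity vectors, `d` their centroid distance and `ε` a small constant
   that keeps the index finite at contact. High SDI means fast directed
   approach at close range. Series are summarized per time bin and
   interaction modality (NK–NK, NK–T, T–T) as medians with interquartile
   envelopes, and pair distances are classified close/distant at a 250 px
   threshold with a 10 px-bin histogram.

3. **Membrane-transfer quantification (trogocytosis).** Fluorescent
   channels are thresholded (Otsu or fixed) into 8-connected cell masks;
   centroids are linked into tracks; transferred membrane fragments are
   counted as transfer-channel pixels inside recipient masks.

4. **Crosstalk screening and signaling.** Ligand–receptor pair tables
   (complexes as slash-joined subunits) are screened against per-cell-type
   TPM expression: a pair passes at a threshold only if *every* subunit
   clears it (inclusively) in its cell type. Phospho-flow readouts are
   normalized as `(pX_co/X_co) / (pX_mono/X_mono)`, the co-culture versus
   monoculture phospho/total fold change.

A fully seeded synthetic-data generator produces tracks, image stacks,
expression and flow tables with complete ground truth, so every stage of
the pipeline is testable without any external data.

## Worked example

```r
library(SynapseKinetics)

# 20 T + 20 NK cells, 100 frames; 15 T cells scripted to slow 10-fold on
# contact, 5 to slow 2-fold, with 10% step noise
gt  <- simulateTracks(simConfig(seed = 1))
kin <- contactKinetics(gt@trackSet, contactDistance = 10)
head(kin[, c("track_id", "partner_id", "v_ph1", "v_ph2", "ratio", "rank")], 3)
#>   track_id partner_id     v_ph1      v_ph2      ratio rank
#> 1      T13       NK13 0.1553982 0.01487010 0.09569032    1
#> 2      T10       NK10 0.1511617 0.01464703 0.09689643    2
#> 3      T03       NK03 0.1493429 0.01459257 0.09771186    3
# these cells froze to ~0.10 of pre-contact speed: their true scripted factor
mean(kin$ratio[!kin$excluded] <= 0.2)   # 0.75: 75% slowed >= 5-fold

# SDI for the first scripted pair
p <- trackTable(gt)
s <- sdiSeries(getTrack(p, "T01"), getTrack(p, "NK01"))
modality(s)                              # "NK-T"

# the packaged crosstalk table: 16 pairs at >=2 TPM, 9 at >=10 TPM
countByThreshold(lrPairsTable1())
#> tpm2 tpm10
#>   16     9

# phospho-STAT fold change, co-culture vs monoculture
phosphoFoldChange(40, 80, 20, 80)        # 2: phosphorylated share doubled
```

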