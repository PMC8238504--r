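# Key-gene rule table for assigning flavinylation-associated gene clusters
# to the ten extracytosolic electron-transfer systems. Accessions are
# namespace-qualified (pfam: or kofam:). `key_any`: the cluster must contain
# a gene carrying any one of the listed accessions. `tm_required`: that gene
# must additionally have >= 1 predicted transmembrane helix. `architecture`:
# a single member protein must carry the n_term domain starting in its
# N-terminal half and preceding the c_term domain.
systems:
  RNF:
    key_any: ["kofam:K03616"]            # RnfB
  NOS:
    key_any: ["kofam:K00376"]            # NosZ nitrous oxide reductase
  PCE:
    key_any: ["pfam:PF13486"]            # PceA reductive dehalogenase
  EET:
    key_any: ["kofam:K03885"]            # NADH dehydrogenase (Ndh2)
    tm_required: true
  NQR:
    key_any: ["kofam:K00351"]            # NqrF
  NAPH_LIKE:
    key_any: ["pfam:PF12801", "kofam:K19339"]
  MSRQ_LIKE:
    key_any: ["pfam:PF01794"]
  PEPSY:
    key_any: ["pfam:PF03929", "pfam:PF16357"]
  DSBD:
    key_any: ["pfam:PF02683"]
  NQR_RNF_LIKE:
    architecture:
      n_term: "pfam:PF03116"             # NqrB/RnfD membrane domain
      c_term: "pfam:PF00175"             # NqrF NAD-binding domain
accessories:
  NIRS:             "kofam:K15864"
  EXAA:             "kofam:K00114"
  VIT1:             "pfam:PF01988"
  NAD_BINDING:      "pfam:PF00175"
  TONB:             "pfam:PF03544"
  DUF4198:          "pfam:PF10670"
  DUF4266:          "pfam:PF14086"
  THIOREDOXIN_LIKE: "pfam:PF13899"
  P19:              "pfam:PF10634"
  FTR1:             "pfam:PF03239"
  NUOF_LIKE:        "pfam:PF10589"
  CYTC_MULTIHEME:   "pfam:PF14537"
  FRD_SUPERFAMILY:  "pfam:PF00890"
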