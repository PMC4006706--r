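# Published feature-level overlap summaries for the 47 e9.5 TGC UR domains.
# genes: Ensembl genes overlapping UR domains vs randomized expectation.
# gene_deserts_1mb: 1 Mb windows without any gene annotation overlapping UR
#   domains. late_region_deserts: 1 Mb gene deserts overlapping the
#   late-replicating regions that contain UR domains.
# published_enrichment is reproduced verbatim; for the desert rows it does not
# equal the ratio of the rounded printed counts (the published expectations
# were evidently unrounded), so only the genes row is arithmetically exact.
feature	observed	expected	published_enrichment
genes	386	617	0.63
gene_deserts_1mb	47	9	4.96
late_region_deserts	58	18	3.16
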