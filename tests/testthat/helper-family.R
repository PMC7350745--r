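# A reference synthetic family shared across test files: 18 full-length
# members at 5% divergence, with the discovered motif catalogue and the
# anchor geometry derived from it. Built once when the helpers are
# sourced.

ref_spec <- family_spec(substitution_rate = 0.05, truncations = NULL)
ref_family <- generate_family_genome(ref_spec, seed = 42)
ref_proteins <- setNames(ref_family$truth$members$protein,
                         ref_family$truth$members$member_id)
ref_aln <- progressive_msa(ref_proteins, type = "protein")
ref_motifs <- discover_motifs(ref_aln)
ref_spatial <- spatial_order(ref_motifs)
ref_first <- ref_spatial[1]
ref_last <- ref_spatial[length(ref_spatial)]
ref_offsets <- anchor_offsets(ref_proteins, ref_motifs, ref_first, ref_last)
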