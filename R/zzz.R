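# data.table NSE column names used across the package
utils::globalVariables(c(
  "gene_id", "ref_id", "start", "end", "strand", "length_bp", "V1", "mate",
  "read_id", "category", "A", "M", "condition", "bio_rep", "tech_rep", "cp",
  "mean_cp", "i.mean_cp", "i.sd", "wt_ref_cp", "rel_amount_vs_wt",
  "mean_cp_trt", "strain", "sample_id", "replicate", "reads_path",
  "ref_id_1", "ref_id_2", "start_1", "start_2", "end_1", "end_2",
  "strand_1", "strand_2", "origin", "emit_first", "emit_second",
  "m1_start", "m2_start", "frag_id", "pct_identity", "len",
  "upstream_position", "distance_to_start", "candidate", "name",
  "reported_identity", "target_identity", "L", "k", "position",
  "expected_identity", "region", "bio_noise", "sd"
))
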