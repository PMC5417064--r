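# Small deterministic fixtures built in code.

write_tmp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

# A hand-sized community for unit and CLI tests; the full default spec is
# exercised in the acceptance suite.
small_spec <- function(...) {
  defaults <- list(seed = 11L, n_taxon_genomes = 3L, n_genes = 8L,
                   gene_len_aa = c(60L, 100L), within_identity = 85,
                   n_outgroup_genomes = 2L, lgt_genes = 3L,
                   contig_len = c(500L, 800L), n_contigs = 30L,
                   error_rate = 0.005)
  do.call(community_spec, utils::modifyList(defaults, list(...)))
}

make_hit <- function(query_id = "g1", subject_id = "s1", pct_identity = 100,
                     qcov = 100, aln_len = 50L, bitscore = 100,
                     evalue = 1e-30, frame = NA_integer_) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity, qcov = qcov, aln_len = aln_len,
             q_start = 0L, q_end = 50L, s_start = 0L, s_end = 50L,
             bitscore = bitscore, evalue = evalue, frame = frame,
             stringsAsFactors = FALSE)
}

# Build a threshold row directly from the four scores.
make_thr <- function(gene_id = "g1", S1 = 0, Q1 = 0, S2 = 0, Q2 = 0,
                     weights = c(0.5, 0.5), mode = "scalar") {
  compute_threshold(
    data.frame(gene_id = gene_id, S1 = S1, Q1 = Q1, stringsAsFactors = FALSE),
    data.frame(gene_id = gene_id, S2 = S2, Q2 = Q2, stringsAsFactors = FALSE),
    weights, mode)
}
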