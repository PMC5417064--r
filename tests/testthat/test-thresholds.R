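# Deterministic proteins for threshold fixtures (no RNG needed).
.p_gene <- strrep("MKVLATTWEHRD", 8)     # 96 aa "gene" of the taxon

test_that("step one records the most dissimilar within-taxon homolog", {
  genes <- Biostrings::AAStringSet(c(gA = .p_gene,
                                     gU = strrep("WNDYQCHM", 10)))
  close_rel <- Biostrings::AAStringSet(c(A1 = .p_gene))  # identical homolog
  far_rel <- Biostrings::AAStringSet(
    c(A2 = mutate_protein(.p_gene, 70, seed = 9)))       # diverged homolog
  s1 <- step1_within_taxon(genes, list(close = close_rel, far = far_rel),
                           search_params())
  # oracle: the far genome's best hit, recomputed directly
  far_best <- best_hit(homology_search(genes["gA"], far_rel, search_params()))
  row <- s1[s1$gene_id == "gA", ]
  expect_equal(row$source_genome, "far")
  expect_equal(row$S1, far_best$pct_identity)
  expect_equal(row$Q1, far_best$qcov)
  # a gene with no homolog in any relative is unique to the type species
  urow <- s1[s1$gene_id == "gU", ]
  expect_equal(urow$S1, 0)
  expect_equal(urow$Q1, 0)
  expect_true(is.na(urow$source_genome))
})

test_that("single-relative mode reduces to that genome's best hit", {
  genes <- Biostrings::AAStringSet(c(gA = .p_gene))
  rel <- Biostrings::AAStringSet(c(B1 = mutate_protein(.p_gene, 80, seed = 4)))
  s1 <- step1_within_taxon(genes, list(rel = rel), search_params())
  ref <- best_hit(homology_search(genes, rel, search_params()))
  expect_equal(s1$S1, ref$pct_identity)
  expect_equal(s1$Q1, ref$qcov)
  expect_error(step1_within_taxon(genes, list(), search_params()),
               "relative genomes")
})

test_that("step two takes the best out-group hit and rejects id collisions", {
  genes <- Biostrings::AAStringSet(c(gA = .p_gene))
  outg <- Biostrings::AAStringSet(c(
    Z_exact = .p_gene,                            # planted lateral transfer
    Z_far = mutate_protein(.p_gene, 60, seed = 6)))
  s2 <- step2_outgroup(genes, outg, search_params())
  expect_equal(s2$S2, 100)
  expect_equal(s2$Q2, 100)
  expect_equal(s2$source_taxon, "Z_exact")
  # no out-group homolog at all
  none <- step2_outgroup(genes,
                         Biostrings::AAStringSet(c(Z1 = strrep("GNDYQCHW", 10))),
                         search_params())
  expect_equal(none$S2, 0)
  expect_equal(none$Q2, 0)
  expect_error(
    step2_outgroup(genes, Biostrings::AAStringSet(c(gA = .p_gene))),
    "taxon of interest")
})

test_that("threshold arithmetic and gene classification follow T = (S1-S2, Q1-Q2)", {
  thr <- make_thr("g1", S1 = 90, Q1 = 100, S2 = 30, Q2 = 40)
  expect_equal(thr$dS, 60)
  expect_equal(thr$dQ, 60)
  expect_equal(thr$t_scalar, 60)
  expect_equal(thr$gene_class, "informative")
  expect_equal(thr$reason, "ok")

  lgt <- make_thr("g2", S1 = 0, Q1 = 0, S2 = 80, Q2 = 90)
  expect_equal(c(lgt$dS, lgt$dQ), c(-80, -90))
  expect_equal(lgt$gene_class, "uninformative")
  expect_equal(lgt$reason, "outgroup_dominant")

  uniq <- make_thr("g3")
  expect_equal(uniq$t_scalar, 0)
  expect_equal(uniq$gene_class, "uninformative")
  expect_equal(uniq$reason, "unique_to_type")

  expect_error(compute_threshold(
    data.frame(gene_id = "a", S1 = 1, Q1 = 1),
    data.frame(gene_id = "b", S2 = 0, Q2 = 0)), "different gene sets")
})

test_that("componentwise mode demands both components above zero", {
  mixed <- make_thr("g1", S1 = 80, Q1 = 50, S2 = 20, Q2 = 60,
                    mode = "componentwise")
  expect_equal(mixed$gene_class, "uninformative")   # dQ = -10
  expect_equal(make_thr("g1", S1 = 80, Q1 = 50, S2 = 20, Q2 = 60)$gene_class,
               "informative")                       # scalar 25 > 0
})

test_that("raising out-group similarity never rescues an uninformative gene", {
  for (S2 in seq(0, 100, by = 10)) {
    for (Q2 in seq(0, 100, by = 10)) {
      t1 <- make_thr("g", S1 = 50, Q1 = 60, S2 = S2, Q2 = Q2)$t_scalar
      t2 <- make_thr("g", S1 = 50, Q1 = 60, S2 = min(S2 + 10, 100),
                     Q2 = Q2)$t_scalar
      expect_lte(t2, t1)
    }
  }
})

test_that("the scalar threshold is exactly re-weightable from its components", {
  set.seed(106)
  for (i in 1:20) {
    s <- runif(4, 0, 100)
    w <- runif(1)
    thr <- make_thr("g", s[1], s[2], s[3], s[4], weights = c(w, 1 - w))
    expect_equal(thr$t_scalar, w * thr$dS + (1 - w) * thr$dQ)
  }
})

test_that("threshold_table composes the two steps over a toy taxon", {
  set.seed(107)
  prots <- setNames(replicate(3, random_peptide(90)), c("g1", "g2", "g3"))
  genes <- Biostrings::AAStringSet(prots)
  rel <- Biostrings::AAStringSet(setNames(
    vapply(prots, mutate_protein, target_identity = 85, character(1)),
    paste0("R_", names(prots))))
  outg <- Biostrings::AAStringSet(c(Z_lgt = prots[["g2"]]))  # planted transfer
  thr <- threshold_table(genes, list(R = rel), outg, search_params())
  expect_equal(thr$gene_id, c("g1", "g2", "g3"))  # genome order kept
  expect_equal(thr$gene_class, c("informative", "uninformative", "informative"))
  expect_equal(thr$reason[2], "outgroup_dominant")

  # identical genes across members, absent from the out-group: t = 100
  ident <- threshold_table(genes, list(R = genes), Biostrings::AAStringSet(),
                           search_params())
  expect_equal(ident$t_scalar, rep(100, 3))
  expect_equal(ident$gene_class, rep("informative", 3))
})

test_that("threshold_table is invariant to relative-genome input order", {
  set.seed(108)
  prots <- setNames(replicate(2, random_peptide(80)), c("g1", "g2"))
  genes <- Biostrings::AAStringSet(prots)
  relA <- Biostrings::AAStringSet(setNames(
    vapply(prots, mutate_protein, target_identity = 90, character(1)),
    paste0("A_", names(prots))))
  relB <- Biostrings::AAStringSet(setNames(
    vapply(prots, mutate_protein, target_identity = 75, character(1)),
    paste0("B_", names(prots))))
  outg <- Biostrings::AAStringSet(c(Z1 = random_peptide(80)))
  t1 <- threshold_table(genes, list(A = relA, B = relB), outg, search_params())
  t2 <- threshold_table(genes, list(B = relB, A = relA), outg, search_params())
  expect_equal(t1, t2)
})

test_that("threshold TSV write / read round trips at printed precision", {
  thr <- make_thr("g1", S1 = 85.333, Q1 = 99.126, S2 = 10.005, Q2 = 0)
  tf <- tempfile(fileext = ".tsv")
  write_threshold_tsv(thr, tf)
  back <- read_threshold_tsv(tf)
  expect_equal(back$gene_id, thr$gene_id)
  expect_equal(back$S1, round(thr$S1, 2))
  expect_equal(back$t_scalar, round(thr$t_scalar, 2))
  expect_equal(back$gene_class, thr$gene_class)
  expect_error(read_threshold_tsv(write_tmp_fasta(c("a\tb", "1\t2"))),
               "threshold table")
})
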