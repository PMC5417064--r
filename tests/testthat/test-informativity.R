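test_that("informativity attains its stated extremes", {
  # zero threshold + perfect hit: I = (100, 100), scalar 100
  thr0 <- make_thr("g1")
  a <- assess_hit(make_hit(), thr0)
  expect_identical(a$I_S, 100)
  expect_identical(a$I_Q, 100)
  expect_identical(a$I_scalar, 100)
  # a zero threshold also means the gene itself carries no taxonomic signal
  expect_equal(a$hit_class, "gene_uninformative")

  # hit exactly at the threshold: I = 0 and still informative (boundary in)
  thr <- make_thr("g1", S1 = 60, Q1 = 40)
  at <- assess_hit(make_hit(pct_identity = 60, qcov = 40), thr)
  expect_identical(at$I_scalar, 0)
  expect_equal(at$hit_class, "informative")
})

test_that("hits below threshold are uninformative; id mismatches error", {
  thr <- make_thr("g1", S1 = 60, Q1 = 60)
  below <- assess_hit(make_hit(pct_identity = 50, qcov = 50), thr)
  expect_equal(below$I_scalar, -10)
  expect_equal(below$hit_class, "uninformative")
  expect_error(assess_hit(make_hit(query_id = "gX"), thr), "does not match")
})

test_that("hits to uninformative genes are retained but flagged", {
  lgt <- make_thr("g1", S1 = 80, Q1 = 90, S2 = 100, Q2 = 100)
  a <- assess_hit(make_hit(pct_identity = 100, qcov = 100), lgt)
  expect_equal(a$hit_class, "gene_uninformative")
  expect_true(is.finite(a$I_scalar))
})

test_that("informativity is strictly monotone in hit identity and coverage", {
  thr <- make_thr("g1", S1 = 70, Q1 = 80, S2 = 10, Q2 = 20)
  base <- assess_hit(make_hit(pct_identity = 50, qcov = 50), thr)$I_scalar
  upS <- assess_hit(make_hit(pct_identity = 51, qcov = 50), thr)$I_scalar
  upQ <- assess_hit(make_hit(pct_identity = 50, qcov = 51), thr)$I_scalar
  expect_gt(upS, base)
  expect_gt(upQ, base)
})

test_that("I_scalar recomputes exactly from the emitted pair under any weights", {
  set.seed(109)
  for (i in 1:20) {
    w <- runif(1)
    thr <- make_thr("g1", runif(1, 50, 100), runif(1, 50, 100),
                    runif(1, 0, 40), runif(1, 0, 40), weights = c(w, 1 - w))
    a <- assess_hit(make_hit(pct_identity = runif(1, 0, 100),
                             qcov = runif(1, 0, 100)), thr,
                    weights = c(w, 1 - w))
    expect_equal(a$I_scalar, w * a$I_S + (1 - w) * a$I_Q)
  }
})

test_that("for informative genes I_scalar is capped at 100 - t_scalar", {
  thr <- make_thr("g1", S1 = 90, Q1 = 95, S2 = 10, Q2 = 5)
  stopifnot(thr$gene_class == "informative")
  best <- assess_hit(make_hit(pct_identity = 100, qcov = 100), thr)
  expect_equal(best$I_scalar, 100 - thr$t_scalar)
  expect_lt(best$I_scalar, 100)
})

test_that("scanning contigs cut verbatim from the genome recovers perfect hits", {
  set.seed(110)
  prots <- setNames(replicate(3, random_peptide(70)), c("g1", "g2", "g3"))
  cds <- vapply(prots, back_translate, character(1))
  genes <- Biostrings::DNAStringSet(cds)
  thr <- threshold_table(genes,
                         list(R = Biostrings::AAStringSet(
                           setNames(vapply(prots, mutate_protein,
                                           target_identity = 85,
                                           character(1)),
                                    paste0("R_", names(prots))))),
                         Biostrings::AAStringSet(c(Z = random_peptide(70))),
                         search_params())
  contigs <- Biostrings::DNAStringSet(c(c1 = unname(cds[["g1"]]),
                                        c2 = unname(cds[["g2"]])))
  a <- scan_sample(genes, thr, contigs, search_params(), "s1")
  expect_setequal(a$gene_id, c("g1", "g2"))
  expect_equal(a$S_H, c(100, 100))
  expect_equal(a$Q_H, c(100, 100))
  for (i in seq_len(nrow(a))) {
    t <- thr$t_scalar[thr$gene_id == a$gene_id[i]]
    expect_equal(a$I_scalar[i], 100 - t)
  }
  expect_equal(nrow(scan_sample(genes, thr, Biostrings::DNAStringSet(),
                                search_params(), "s1")), 0L)
  expect_error(scan_sample(genes, thr[-1, ], contigs, search_params(), "s1"),
               "lacks gene")
})

test_that("a community carrying only a transferred gene copy yields only flagged hits", {
  set.seed(111)
  prots <- setNames(replicate(3, random_peptide(80)), c("g1", "g2", "g3"))
  genes <- Biostrings::DNAStringSet(vapply(prots, back_translate, character(1)))
  rel <- Biostrings::AAStringSet(setNames(
    vapply(prots, mutate_protein, target_identity = 85, character(1)),
    paste0("R_", names(prots))))
  outg <- Biostrings::AAStringSet(c(Z_lgt = prots[["g2"]]))
  thr <- threshold_table(genes, list(R = rel), outg, search_params())
  stopifnot(thr$gene_class[2] == "uninformative")
  # the sample contains only the out-group genome with the transferred copy
  lgt_contig <- Biostrings::DNAStringSet(c(octg = back_translate(prots[["g2"]])))
  a <- scan_sample(genes, thr, lgt_contig, search_params(), "s1")
  expect_true(all(a$gene_id == "g2"))
  expect_true(all(a$hit_class == "gene_uninformative"))
})

test_that("sample summaries count informative genes and hits consistently", {
  thr <- do.call(rbind, lapply(1:10, function(i)
    make_thr(sprintf("g%02d", i), S1 = 90, Q1 = 90)))
  stopifnot(all(thr$gene_class == "informative"))
  mk <- function(gene, cls, I) data.frame(
    sample_id = "s1", gene_id = gene, contig_id = "c", frame = 1L,
    S_H = 90, Q_H = 90, I_S = I, I_Q = I, I_scalar = I, hit_class = cls,
    stringsAsFactors = FALSE)
  a <- rbind(mk("g01", "informative", 20), mk("g02", "informative", 10),
             mk("g03", "informative", 5), mk("g04", "informative", 5),
             mk("g05", "uninformative", -3))
  s <- summarize_sample(a, thr)
  expect_equal(s$n_genes_informative, 10L)
  expect_equal(s$n_hit, 5L)
  expect_equal(s$n_informative_hits, 4L)
  expect_equal(s$fraction_detected, 0.4)
  expect_equal(s$mean_I, 10)
  expect_equal(s$max_I, 20)

  empty <- summarize_sample(a[0, ], thr)
  expect_equal(empty$fraction_detected, 0)
  expect_true(is.na(empty$mean_I) && is.na(empty$max_I))
  expect_error(summarize_sample(rbind(mk("g01", "informative", 1),
                                      within(mk("g02", "informative", 1),
                                             sample_id <- "s2")), thr),
               "mix")
})

test_that("the informativity matrix has genome-ordered columns and sentinels", {
  thr <- rbind(make_thr("g1", S1 = 90, Q1 = 90),
               make_thr("g2", S1 = 80, Q1 = 80),
               make_thr("g3", S1 = 0, Q1 = 0, S2 = 50, Q2 = 50))
  one_hit <- data.frame(sample_id = "sA", gene_id = "g2", contig_id = "c",
                        frame = 1L, S_H = 90, Q_H = 90, I_S = 10, I_Q = 10,
                        I_scalar = 10, hit_class = "informative",
                        stringsAsFactors = FALSE)
  m <- informativity_matrix(list(sA = one_hit, sB = one_hit[0, ]), thr)
  expect_equal(colnames(m), c("g1", "g2", "g3"))
  expect_equal(rownames(m), c("sA", "sB"))
  expect_equal(sum(!is.na(m)), 1L)
  expect_equal(m["sA", "g2"], 10)
  status <- attr(m, "status")
  expect_equal(status["sA", "g2"], "hit")
  expect_equal(unname(status[, "g3"]), rep("gene_uninformative", 2))
  expect_equal(status["sB", "g1"], "no_hit")
  expect_error(informativity_matrix(list(sA = one_hit, sA = one_hit), thr),
               "duplicate")

  tf <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, tf)
  lines <- readLines(tf)
  expect_equal(length(lines), 3L)
  expect_match(lines[2], "^sA\\t\\.\\t10\\.00\\tuninformative$")
})

test_that("the fitted-model interface mirrors the pipeline functions", {
  set.seed(112)
  comm <- make_community(small_spec())
  fit <- informativity(comm$genes_x, comm$taxon_proteins,
                       comm$outgroup_proteins, exclude_genomes = "TYPE")
  expect_s3_class(fit, "informativity")
  direct <- threshold_table(comm$genes_x, comm$taxon_proteins,
                            comm$outgroup_proteins, search_params(),
                            exclude_genomes = "TYPE")
  expect_equal(fit$thresholds, direct)
  cm <- coef(fit)
  expect_equal(rownames(cm), fit$thresholds$gene_id)
  expect_equal(unname(cm[, "t_scalar"]), fit$thresholds$t_scalar)
  s <- summary(fit)
  expect_equal(sum(s$class_counts), nrow(fit$thresholds))
  expect_output(print(fit), "Taxonomic signal thresholds")

  ctg <- simulate_contigs(comm$genomes_nt, comm$spec)
  pred <- predict(fit, ctg, sample_id = "sim")
  expect_s3_class(pred, "informativity_scan")
  expect_equal(attr(pred, "summary"),
               summarize_sample(as.data.frame(pred)[, names(pred)],
                                fit$thresholds))
})
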