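.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Specification of a synthetic phage community
#'
#' Defines a seeded synthetic evaluation setting: a taxon of several genomes
#' sharing genes at a controlled amino-acid identity, out-group genomes of
#' unrelated genes carrying planted laterally transferred copies of selected
#' taxon genes, and metagenomic contigs sampled from the genomes with point
#' errors. The defaults describe the community used throughout the package's
#' validation: 5 taxon genomes, 30 genes of 60-150 aa conserved at 85%
#' within-taxon identity, 4 out-group genomes with 3 planted transfers, and
#' 200 contigs of 1-2 kb at a 0.5% per-base error rate.
#'
#' @param seed Integer RNG seed; every generator derives its stream from it.
#' @param n_taxon_genomes Number of taxon genomes (type species + relatives).
#' @param n_genes Genes per genome.
#' @param gene_len_aa Length-2 integer range of gene lengths (amino acids).
#' @param within_identity Target within-taxon amino-acid identity (percent,
#'   0 < x <= 100) between each relative's genes and the type species'.
#' @param n_outgroup_genomes Number of unrelated out-group genomes.
#' @param lgt_genes Integer indices (into 1..n_genes) of type-species genes
#'   planted as exact copies into the out-group (simulated lateral transfer).
#' @param contig_len Length-2 integer range of contig lengths (nt).
#' @param n_contigs Number of contigs per simulated sample.
#' @param error_rate Per-base substitution error rate for contigs.
#' @return An object of class \code{"community_spec"}.
#' @export
community_spec <- function(seed = 20170404L, n_taxon_genomes = 5L,
                           n_genes = 30L, gene_len_aa = c(60L, 150L),
                           within_identity = 85, n_outgroup_genomes = 4L,
                           lgt_genes = c(5L, 12L, 21L),
                           contig_len = c(1000L, 2000L), n_contigs = 200L,
                           error_rate = 0.005) {
  spec <- list(seed = as.integer(seed),
               n_taxon_genomes = as.integer(n_taxon_genomes),
               n_genes = as.integer(n_genes),
               gene_len_aa = as.integer(gene_len_aa),
               within_identity = as.numeric(within_identity),
               n_outgroup_genomes = as.integer(n_outgroup_genomes),
               lgt_genes = as.integer(lgt_genes),
               contig_len = as.integer(contig_len),
               n_contigs = as.integer(n_contigs),
               error_rate = as.numeric(error_rate))
  with(spec, {
    stopifnot(within_identity > 0, within_identity <= 100,
              n_taxon_genomes >= 1, n_genes >= 1,
              length(gene_len_aa) == 2, gene_len_aa[1] <= gene_len_aa[2],
              length(contig_len) == 2, contig_len[1] <= contig_len[2],
              n_outgroup_genomes >= 0, n_contigs >= 0,
              error_rate >= 0, error_rate < 1)
    if (length(lgt_genes) && (min(lgt_genes) < 1 || max(lgt_genes) > n_genes)) {
      stop("lgt_genes indices must lie in 1..n_genes")
    }
  })
  structure(spec, class = "community_spec")
}

#' Substitute residues to hit a target amino-acid identity
#'
#' Exactly \code{round((1 - target_identity/100) * nchar(seq))} positions,
#' chosen uniformly without replacement, are replaced by a uniformly chosen
#' different residue. Deterministic under \code{seed}.
#'
#' @param seq Amino-acid string (non-empty).
#' @param target_identity Target percent identity (0 < x <= 100).
#' @param seed Optional integer seed; when \code{NULL} the current RNG
#'   stream is used.
#' @return The mutated amino-acid string.
#' @export
mutate_protein <- function(seq, target_identity, seed = NULL) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  if (!length(s)) stop("cannot mutate an empty sequence")
  stopifnot(target_identity > 0, target_identity <= 100)
  if (!is.null(seed)) set.seed(seed)
  n_sub <- round((1 - target_identity / 100) * length(s))
  if (n_sub == 0) return(paste(s, collapse = ""))
  pos <- sample.int(length(s), n_sub)
  for (p in pos) {
    s[p] <- sample(setdiff(.AA20, s[p]), 1L)
  }
  paste(s, collapse = "")
}

.random_protein <- function(len) {
  paste0("M", paste(sample(.AA20, len - 1L, replace = TRUE), collapse = ""))
}

.CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

#' Back-translate a protein with uniformly random synonymous codons
#'
#' A terminal stop codon (for \code{'*'}) is appended when \code{add_stop}
#' is TRUE. Codon bias is not modelled: downstream comparisons are all in
#' protein space.
#'
#' @param protein Amino-acid string (20 standard residues).
#' @param add_stop Append a random stop codon (default TRUE).
#' @return A nucleotide string.
#' @export
back_translate <- function(protein, add_stop = TRUE) {
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- .CODONS_BY_AA[[a]]
    if (is.null(opts)) stop("cannot back-translate residue '", a, "'")
    opts[sample.int(length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
  if (add_stop) {
    codons <- c(codons, .CODONS_BY_AA[["*"]][sample.int(3L, 1L)])
  }
  paste(codons, collapse = "")
}

#' Generate a synthetic community with planted lateral transfers
#'
#' Builds a type-species genome of random coding sequences, relative genomes
#' whose proteins are mutated copies at the spec's within-taxon identity
#' (back-translated through random synonymous codons), and out-group genomes
#' of unrelated random genes into which exact amino-acid copies of the
#' selected taxon genes are planted. The truth table records which genes
#' should end up classified uninformative.
#'
#' @param spec A \code{\link{community_spec}}.
#' @return A list of class \code{"community"}:
#'   \describe{
#'     \item{genes_x}{\code{DNAStringSet} of the type species' coding
#'       sequences (ids \code{g01, g02, ...}).}
#'     \item{taxon_proteins}{named list, genome id -> \code{AAStringSet}
#'       (type species first, then relatives).}
#'     \item{outgroup_proteins}{\code{AAStringSet} pooling all out-group
#'       proteins, planted copies included.}
#'     \item{genomes_nt}{\code{DNAStringSet} of all genome nucleotide
#'       sequences (concatenated coding regions with short random spacers).}
#'     \item{truth}{data frame \code{gene_id, planted_lgt}.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
make_community <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  gene_ids <- sprintf("g%02d", seq_len(spec$n_genes))
  lens <- sample(spec$gene_len_aa[1]:spec$gene_len_aa[2], spec$n_genes,
                 replace = TRUE)
  type_prot <- vapply(lens, .random_protein, character(1))
  names(type_prot) <- gene_ids

  taxon_ids <- c("TYPE", sprintf("REL%d", seq_len(spec$n_taxon_genomes - 1L)))
  taxon_proteins <- vector("list", spec$n_taxon_genomes)
  names(taxon_proteins) <- taxon_ids
  taxon_cds <- vector("list", spec$n_taxon_genomes)
  for (k in seq_along(taxon_ids)) {
    prots <- if (k == 1L) type_prot else {
      vapply(type_prot, mutate_protein,
             target_identity = spec$within_identity, character(1))
    }
    names(prots) <- paste0(taxon_ids[k], "_", gene_ids)
    taxon_proteins[[k]] <- Biostrings::AAStringSet(prots)
    cds <- vapply(prots, back_translate, character(1))
    taxon_cds[[k]] <- cds
  }
  # the type species' genes double as the query set X, under bare gene ids
  genes_x <- Biostrings::DNAStringSet(taxon_cds[[1L]])
  names(genes_x) <- gene_ids

  out_proteins <- character(0)
  outgroup_cds <- vector("list", max(spec$n_outgroup_genomes, 0L))
  lgt_targets <- if (length(spec$lgt_genes) && spec$n_outgroup_genomes) {
    # distribute planted copies round-robin over out-group genomes
    setNames(rep(seq_len(spec$n_outgroup_genomes),
                 length.out = length(spec$lgt_genes)), spec$lgt_genes)
  } else integer(0)
  for (k in seq_len(spec$n_outgroup_genomes)) {
    og_id <- sprintf("OUT%d", k)
    og_lens <- sample(spec$gene_len_aa[1]:spec$gene_len_aa[2], spec$n_genes,
                      replace = TRUE)
    prots <- vapply(og_lens, .random_protein, character(1))
    names(prots) <- sprintf("%s_u%02d", og_id, seq_along(prots))
    planted_idx <- as.integer(names(lgt_targets)[lgt_targets == k])
    if (length(planted_idx)) {
      planted <- as.character(type_prot[planted_idx])
      names(planted) <- sprintf("%s_lgt_%s", og_id, gene_ids[planted_idx])
      prots <- c(prots, planted)
    }
    out_proteins <- c(out_proteins, prots)
    outgroup_cds[[k]] <- vapply(prots, back_translate, character(1))
  }

  spacer <- function() paste(sample(c("A", "C", "G", "T"),
                                    sample(10:30, 1L), replace = TRUE),
                             collapse = "")
  genome_seq <- function(cds) {
    parts <- character(2L * length(cds))
    parts[seq(1L, by = 2L, length.out = length(cds))] <- unname(cds)
    parts[seq(2L, by = 2L, length.out = length(cds))] <-
      replicate(length(cds), spacer())
    paste(parts, collapse = "")
  }
  genomes_nt <- c(
    setNames(vapply(taxon_cds, genome_seq, character(1)), taxon_ids),
    if (spec$n_outgroup_genomes)
      setNames(vapply(outgroup_cds, genome_seq, character(1)),
               sprintf("OUT%d", seq_len(spec$n_outgroup_genomes)))
  )

  structure(list(
    genes_x = genes_x,
    taxon_proteins = taxon_proteins,
    outgroup_proteins = Biostrings::AAStringSet(out_proteins),
    genomes_nt = Biostrings::DNAStringSet(genomes_nt),
    truth = data.frame(gene_id = gene_ids,
                       planted_lgt = seq_len(spec$n_genes) %in% spec$lgt_genes,
                       stringsAsFactors = FALSE),
    spec = spec), class = "community")
}

#' Sample error-bearing contigs from a set of genomes
#'
#' Contigs are substrings at uniform random positions with lengths uniform in
#' \code{spec$contig_len} (source genome chosen in proportion to its length),
#' reverse-complemented with probability 1/2, and subjected to independent
#' per-base substitution errors at \code{spec$error_rate}. Contig names
#' encode the per-contig truth as \code{ctgNNNN|genome|start-end|strand}
#' (1-based inclusive genomic coordinates).
#'
#' @param genomes Named \code{DNAStringSet} (or named character vector) of
#'   source genome sequences.
#' @param spec A \code{\link{community_spec}} supplying \code{contig_len},
#'   \code{n_contigs} and \code{error_rate}.
#' @param seed Integer seed; defaults to \code{spec$seed + 1} so that a
#'   community and its sample are jointly reproducible yet use distinct
#'   streams.
#' @return A named \code{DNAStringSet} of contigs.
#' @export
simulate_contigs <- function(genomes, spec = community_spec(), seed = NULL) {
  if (is.character(genomes)) genomes <- Biostrings::DNAStringSet(genomes)
  if (!length(genomes)) stop("no genomes supplied")
  glen <- width(genomes)
  if (spec$contig_len[1] > max(glen)) {
    stop("minimum contig length (", spec$contig_len[1],
         ") exceeds the longest genome (", max(glen), " nt)")
  }
  set.seed(if (is.null(seed)) spec$seed + 1L else as.integer(seed))
  bases <- c("A", "C", "G", "T")
  out <- character(spec$n_contigs)
  hdr <- character(spec$n_contigs)
  gseq <- as.character(genomes)
  for (i in seq_len(spec$n_contigs)) {
    # genomes shorter than the minimum contig length cannot be sampled
    ok <- which(glen >= spec$contig_len[1])
    g <- ok[sample.int(length(ok), 1L, prob = glen[ok])]
    len <- sample(spec$contig_len[1]:min(spec$contig_len[2], glen[g]), 1L)
    start <- sample.int(glen[g] - len + 1L, 1L)
    s <- substr(gseq[g], start, start + len - 1L)
    ch <- strsplit(s, "")[[1]]
    nerr <- rbinom(1L, len, spec$error_rate)
    if (nerr > 0) {
      pos <- sample.int(len, nerr)
      for (p in pos) {
        ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      }
      s <- paste(ch, collapse = "")
    }
    strand <- "+"
    if (runif(1) < 0.5) {
      s <- reverse_complement(s)
      strand <- "-"
    }
    out[i] <- s
    hdr[i] <- sprintf("ctg%04d|%s|%d-%d|%s", i, names(genomes)[g],
                      start, start + len - 1L, strand)
  }
  contigs <- Biostrings::DNAStringSet(out)
  names(contigs) <- hdr
  contigs
}

#' Write a synthetic community to disk
#'
#' Produces \code{genes_X.fna} (type-species coding sequences),
#' \code{relative_<id>.faa} per relative genome, \code{outgroup.faa},
#' \code{genomes.fna}, and \code{truth.tsv}.
#'
#' @param community A \code{\link{make_community}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of written paths.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes_x = file.path(dir, "genes_X.fna"))
  write_fasta(community$genes_x, paths["genes_x"])
  rel_ids <- setdiff(names(community$taxon_proteins), "TYPE")
  for (rid in rel_ids) {
    p <- file.path(dir, sprintf("relative_%s.faa", rid))
    write_fasta(community$taxon_proteins[[rid]], p)
    paths[paste0("relative_", rid)] <- p
  }
  paths["outgroup"] <- file.path(dir, "outgroup.faa")
  write_fasta(community$outgroup_proteins, paths["outgroup"])
  paths["genomes"] <- file.path(dir, "genomes.fna")
  write_fasta(community$genomes_nt, paths["genomes"])
  paths["truth"] <- file.path(dir, "truth.tsv")
  write.table(community$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
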