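#' Step one: within-taxon conservation scores (S1, Q1)
#'
#' Each gene of the taxon of interest is compared against the annotated
#' proteins of each within-taxon relative genome. Per genome the best hit is
#' selected; among the genomes where a homolog was detected, the genome whose
#' best hit has the LOWEST weighted score supplies (S1, Q1) — i.e. the most
#' dissimilar within-taxon homolog, which is what makes the threshold
#' conservative. Genes with no hit in any relative genome are unique to the
#' type species and get S1 = Q1 = 0.
#'
#' @param genes_x Named \code{DNAStringSet} of coding sequences (translated
#'   in-frame) or \code{AAStringSet} of proteins for the taxon of interest.
#' @param member_genomes Named list: genome id -> named \code{AAStringSet} of
#'   that relative genome's proteins.
#' @param params A \code{\link{search_params}} object (its \code{weights}
#'   rank the per-genome best hits).
#' @param exclude_genomes Genome ids to drop (e.g. the taxon-of-interest
#'   genome itself when it appears in the list).
#' @return Data frame: \code{gene_id, S1, Q1, source_genome, source_gene}.
#' @export
step1_within_taxon <- function(genes_x, member_genomes,
                               params = search_params(),
                               exclude_genomes = NULL) {
  if (!length(genes_x)) stop("empty gene set")
  if (!is.null(exclude_genomes)) {
    member_genomes <- member_genomes[setdiff(names(member_genomes),
                                             exclude_genomes)]
  }
  if (!length(member_genomes)) stop("no within-taxon relative genomes supplied")
  if (is.null(names(member_genomes)) || any(!nzchar(names(member_genomes)))) {
    stop("member genomes must be a named list")
  }
  w <- params$weights
  gene_ids <- names(genes_x)
  per_genome <- lapply(names(member_genomes), function(gid) {
    hits <- homology_search(genes_x, member_genomes[[gid]], params)
    hits$genome_id <- if (nrow(hits)) gid else character(0)
    hits
  })
  all_hits <- do.call(rbind, per_genome)
  out <- data.frame(gene_id = gene_ids, S1 = 0, Q1 = 0,
                    source_genome = NA_character_,
                    source_gene = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(gene_ids)) {
    gh <- all_hits[all_hits$query_id == gene_ids[i], , drop = FALSE]
    if (!nrow(gh)) next
    # best hit per genome, then the minimum-scoring genome among those with a hit
    bests <- do.call(rbind, lapply(split(gh, gh$genome_id), best_hit, weights = w))
    scores <- w[1] * bests$pct_identity + w[2] * bests$qcov
    ord <- order(scores, bests$genome_id, method = "radix")
    pick <- bests[ord[1L], ]
    out$S1[i] <- pick$pct_identity
    out$Q1[i] <- pick$qcov
    out$source_genome[i] <- pick$genome_id
    out$source_gene[i] <- pick$subject_id
  }
  out
}

#' Step two: out-group homology scores (S2, Q2)
#'
#' Each gene is compared against the full out-group protein reference (all
#' annotated coding regions of the assayed domain minus the taxonomic group
#' of the taxon of interest and its step-one relatives). Many hits may be
#' found; the single best hit (maximum weighted score) supplies (S2, Q2).
#' Genes with no out-group homolog get S2 = Q2 = 0.
#'
#' @param genes_x As in \code{\link{step1_within_taxon}}.
#' @param outgroup_z Named \code{AAStringSet} of out-group proteins. Ids
#'   overlapping \code{names(genes_x)} raise an error, since the out-group
#'   must not contain the taxon of interest.
#' @param params A \code{\link{search_params}} object.
#' @return Data frame: \code{gene_id, S2, Q2, source_taxon}.
#' @export
step2_outgroup <- function(genes_x, outgroup_z, params = search_params()) {
  if (!length(genes_x)) stop("empty gene set")
  clash <- intersect(names(genes_x), names(outgroup_z))
  if (length(clash)) {
    stop("out-group contains id(s) of the taxon of interest: ",
         paste(clash, collapse = ", "))
  }
  gene_ids <- names(genes_x)
  out <- data.frame(gene_id = gene_ids, S2 = 0, Q2 = 0,
                    source_taxon = NA_character_, stringsAsFactors = FALSE)
  if (!length(outgroup_z)) return(out)
  hits <- homology_search(genes_x, outgroup_z, params)
  for (i in seq_along(gene_ids)) {
    bh <- best_hit(hits[hits$query_id == gene_ids[i], , drop = FALSE],
                   params$weights)
    if (is.null(bh)) next
    out$S2[i] <- bh$pct_identity
    out$Q2[i] <- bh$qcov
    out$source_taxon[i] <- bh$subject_id
  }
  out
}

.THRESHOLD_COLS <- c("gene_id", "S1", "Q1", "S2", "Q2", "dS", "dQ",
                     "t_scalar", "gene_class", "reason",
                     "source_genome", "source_gene", "source_taxon")

#' Combine step scores into per-gene taxonomic signal thresholds
#'
#' The threshold pair is T = (dS, dQ) = (S1 - S2, Q1 - Q2); the scalar
#' threshold is \code{t_scalar = w_S * dS + w_Q * dQ}. A gene is informative
#' when its threshold exceeds zero: under \code{mode = "scalar"} (default)
#' when \code{t_scalar > 0}, under \code{mode = "componentwise"} when both
#' \code{dS > 0} and \code{dQ > 0}. Uninformative genes carry a machine-
#' readable reason: \code{unique_to_type} (no homolog inside or outside the
#' taxon — the gene is present only in the type species' genome) or
#' \code{outgroup_dominant} (at least as similar to another taxon as to its
#' own relatives, e.g. via lateral gene transfer).
#'
#' @param step1 Data frame from \code{\link{step1_within_taxon}} (or any
#'   frame with \code{gene_id, S1, Q1}).
#' @param step2 Data frame from \code{\link{step2_outgroup}} (matching
#'   \code{gene_id} order or joinable by id).
#' @param weights Length-2 weights \code{(w_S, w_Q)}.
#' @param mode \code{"scalar"} or \code{"componentwise"}.
#' @return Data frame with columns
#'   \code{gene_id, S1, Q1, S2, Q2, dS, dQ, t_scalar, gene_class, reason,
#'   source_genome, source_gene, source_taxon}.
#' @export
compute_threshold <- function(step1, step2, weights = c(0.5, 0.5),
                              mode = c("scalar", "componentwise")) {
  mode <- match.arg(mode)
  if (!setequal(step1$gene_id, step2$gene_id) ||
      nrow(step1) != nrow(step2)) {
    stop("step-one and step-two scores cover different gene sets")
  }
  step2 <- step2[match(step1$gene_id, step2$gene_id), , drop = FALSE]
  dS <- step1$S1 - step2$S2
  dQ <- step1$Q1 - step2$Q2
  t_scalar <- weights[1] * dS + weights[2] * dQ
  informative <- if (mode == "scalar") t_scalar > 0 else (dS > 0 & dQ > 0)
  no_hit_anywhere <- step1$S1 == 0 & step1$Q1 == 0 &
                     step2$S2 == 0 & step2$Q2 == 0
  reason <- ifelse(informative, "ok",
            ifelse(no_hit_anywhere, "unique_to_type",
            ifelse(step2$S2 > 0 | step2$Q2 > 0, "outgroup_dominant",
                   "unique_to_type")))
  data.frame(gene_id = step1$gene_id,
             S1 = step1$S1, Q1 = step1$Q1, S2 = step2$S2, Q2 = step2$Q2,
             dS = dS, dQ = dQ, t_scalar = t_scalar,
             gene_class = ifelse(informative, "informative", "uninformative"),
             reason = reason,
             source_genome = if ("source_genome" %in% names(step1))
               step1$source_genome else NA_character_,
             source_gene = if ("source_gene" %in% names(step1))
               step1$source_gene else NA_character_,
             source_taxon = if ("source_taxon" %in% names(step2))
               step2$source_taxon else NA_character_,
             stringsAsFactors = FALSE)
}

#' Full two-step threshold table for a gene set
#'
#' Composition of \code{\link{step1_within_taxon}},
#' \code{\link{step2_outgroup}} and \code{\link{compute_threshold}}; output
#' rows follow the gene order of \code{genes_x} (genome order).
#'
#' @inheritParams step1_within_taxon
#' @inheritParams step2_outgroup
#' @param mode \code{"scalar"} or \code{"componentwise"}.
#' @return The per-gene threshold data frame (see
#'   \code{\link{compute_threshold}}).
#' @export
threshold_table <- function(genes_x, member_genomes, outgroup_z,
                            params = search_params(),
                            mode = c("scalar", "componentwise"),
                            exclude_genomes = NULL) {
  mode <- match.arg(mode)
  s1 <- step1_within_taxon(genes_x, member_genomes, params, exclude_genomes)
  s2 <- step2_outgroup(genes_x, outgroup_z, params)
  compute_threshold(s1, s2, params$weights, mode)
}

#' Write / read the threshold table as TSV
#'
#' Fixed column order; floating-point columns printed with 2 decimals.
#'
#' @param thresholds Threshold data frame.
#' @param path File path.
#' @return \code{write_threshold_tsv}: invisibly, \code{path};
#'   \code{read_threshold_tsv}: the threshold data frame.
#' @export
write_threshold_tsv <- function(thresholds, path) {
  out <- thresholds[, .THRESHOLD_COLS]
  for (col in c("S1", "Q1", "S2", "Q2", "dS", "dQ", "t_scalar")) {
    out[[col]] <- sprintf("%.2f", out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_tsv
#' @export
read_threshold_tsv <- function(path) {
  thr <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.THRESHOLD_COLS, names(thr))
  if (length(missing)) {
    stop("not a threshold table (missing columns: ",
         paste(missing, collapse = ", "), "): ", path)
  }
  thr
}
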