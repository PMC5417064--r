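.ASSESSMENT_COLS <- c("sample_id", "gene_id", "contig_id", "frame",
                      "S_H", "Q_H", "I_S", "I_Q", "I_scalar", "hit_class")

#' Assess one metagenomic hit against a gene's threshold
#'
#' The informativity of a hit is its deviation above the gene's taxonomic
#' signal threshold: the pair I = (S_H - dS, Q_H - dQ) and the scalar
#' \code{I_scalar = w_S * I_S + w_Q * I_Q}. I ranges from 0 (a hit exactly at
#' the threshold, which still counts as informative) to 100 (attained only
#' when T = (0,0) and the hit is a perfect full-length match). Hits to genes
#' already classified uninformative are retained but flagged
#' \code{gene_uninformative}; hits below the threshold are
#' \code{uninformative}.
#'
#' @param hit A one-row hit data frame (query = the gene) or a list with
#'   \code{query_id}, \code{pct_identity}, \code{qcov} and optionally
#'   \code{subject_id}, \code{frame}.
#' @param thr The gene's one-row threshold data frame (see
#'   \code{\link{compute_threshold}}).
#' @param weights Length-2 weights \code{(w_S, w_Q)}.
#' @param mode \code{"scalar"} (hit informative iff \code{I_scalar >= 0}) or
#'   \code{"componentwise"} (iff \code{I_S >= 0} and \code{I_Q >= 0}).
#' @param sample_id Optional sample label recorded with the assessment.
#' @param contig_id,frame Override the provenance taken from
#'   \code{hit$subject_id} / \code{hit$frame}.
#' @return One-row data frame:
#'   \code{sample_id, gene_id, contig_id, frame, S_H, Q_H, I_S, I_Q,
#'   I_scalar, hit_class}.
#' @export
assess_hit <- function(hit, thr, weights = c(0.5, 0.5),
                       mode = c("scalar", "componentwise"),
                       sample_id = NA_character_,
                       contig_id = NULL, frame = NULL) {
  mode <- match.arg(mode)
  if (!identical(as.character(hit$query_id), as.character(thr$gene_id))) {
    stop("hit query '", hit$query_id, "' does not match threshold gene '",
         thr$gene_id, "'")
  }
  S_H <- as.numeric(hit$pct_identity)
  Q_H <- as.numeric(hit$qcov)
  I_S <- S_H - thr$dS
  I_Q <- Q_H - thr$dQ
  I_scalar <- weights[1] * I_S + weights[2] * I_Q
  above <- if (mode == "scalar") I_scalar >= 0 else (I_S >= 0 && I_Q >= 0)
  hit_class <- if (thr$gene_class != "informative") "gene_uninformative"
               else if (above) "informative" else "uninformative"
  data.frame(sample_id = sample_id,
             gene_id = as.character(thr$gene_id),
             contig_id = if (!is.null(contig_id)) contig_id
                         else if (!is.null(hit$subject_id))
                           as.character(hit$subject_id) else NA_character_,
             frame = if (!is.null(frame)) as.integer(frame)
                     else if (!is.null(hit$frame)) as.integer(hit$frame)
                     else NA_integer_,
             S_H = S_H, Q_H = Q_H, I_S = I_S, I_Q = I_Q,
             I_scalar = I_scalar, hit_class = hit_class,
             stringsAsFactors = FALSE)
}

#' Scan one metagenomic sample against the gene thresholds
#'
#' Contigs are six-frame translated into a stop-free ORF protein database;
#' each gene is searched against it and the single best hit per gene in the
#' sample is assessed against the gene's threshold. Query coverage Q_H is
#' coverage of the gene (the gene is the query). Genes with no hit are
#' omitted; absence is recoverable from \code{\link{summarize_sample}}.
#'
#' @param genes_x Named \code{DNAStringSet} (coding sequences) or
#'   \code{AAStringSet} (proteins) of the taxon of interest.
#' @param thresholds Threshold data frame covering every gene in
#'   \code{genes_x}.
#' @param contigs Named \code{DNAStringSet} of assembled contigs.
#' @param params A \code{\link{search_params}} object.
#' @param sample_id Sample label.
#' @param mode Comparison mode, as in \code{\link{assess_hit}}.
#' @param min_orf_aa Minimum ORF length for the contig database.
#' @return Assessment data frame, one row per gene with a hit.
#' @export
scan_sample <- function(genes_x, thresholds, contigs,
                        params = search_params(), sample_id = "sample",
                        mode = c("scalar", "componentwise"),
                        min_orf_aa = 20L) {
  mode <- match.arg(mode)
  missing <- setdiff(names(genes_x), thresholds$gene_id)
  if (length(missing)) {
    stop("threshold table lacks gene(s): ", paste(missing, collapse = ", "))
  }
  empty <- .empty_assessments()
  if (!length(contigs)) return(empty)
  db <- orf_database(contigs, min_orf_aa)
  if (!length(db)) return(empty)
  hits <- homology_search(genes_x, db, params)
  if (!nrow(hits)) return(empty)
  meta <- as.data.frame(mcols(db))
  rownames(meta) <- names(db)
  out <- lapply(names(genes_x), function(gid) {
    bh <- best_hit(hits[hits$query_id == gid, , drop = FALSE], params$weights)
    if (is.null(bh)) return(NULL)
    thr <- thresholds[thresholds$gene_id == gid, , drop = FALSE]
    assess_hit(bh, thr, params$weights, mode, sample_id,
               contig_id = meta[bh$subject_id, "contig_id"],
               frame = meta[bh$subject_id, "frame"])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

.empty_assessments <- function() {
  data.frame(sample_id = character(), gene_id = character(),
             contig_id = character(), frame = integer(),
             S_H = numeric(), Q_H = numeric(), I_S = numeric(),
             I_Q = numeric(), I_scalar = numeric(), hit_class = character(),
             stringsAsFactors = FALSE)
}

#' Summarize the evidence for taxon presence in one sample
#'
#' Transparent descriptive aggregates over the sample's hit assessments: the
#' number of informative genes available, how many of them were hit at all,
#' how many hits cleared their gene's threshold, and the mean and maximum
#' informativity among those informative hits. No probability is attached;
#' interpretation of the aggregate is left to the analyst.
#'
#' @param assessments Assessment data frame for one sample (may be empty).
#' @param thresholds The threshold table the assessments were scored against.
#' @return One-row data frame: \code{sample_id, n_genes_informative, n_hit,
#'   n_informative_hits, mean_I, max_I, fraction_detected}.
#' @export
summarize_sample <- function(assessments, thresholds) {
  sid <- unique(assessments$sample_id)
  if (length(sid) > 1L) {
    stop("assessments mix sample ids: ", paste(sid, collapse = ", "))
  }
  if (!length(sid)) sid <- NA_character_
  informative_genes <- thresholds$gene_id[thresholds$gene_class == "informative"]
  n_inf <- length(informative_genes)
  n_hit <- sum(assessments$gene_id %in% informative_genes)
  inf_hits <- assessments[assessments$hit_class == "informative", , drop = FALSE]
  n_ih <- nrow(inf_hits)
  data.frame(sample_id = sid,
             n_genes_informative = n_inf,
             n_hit = n_hit,
             n_informative_hits = n_ih,
             mean_I = if (n_ih) mean(inf_hits$I_scalar) else NA_real_,
             max_I = if (n_ih) max(inf_hits$I_scalar) else NA_real_,
             fraction_detected = if (n_inf) n_ih / n_inf else NA_real_,
             stringsAsFactors = FALSE)
}

#' Samples-by-genes informativity matrix
#'
#' Rows are samples, columns are genes in threshold-table (genome) order;
#' each cell is the I_scalar of the sample's best hit to that gene. Cells
#' with no hit and cells for uninformative genes are distinguished via the
#' \code{"status"} attribute (\code{"hit"}, \code{"no_hit"},
#' \code{"gene_uninformative"}); both are \code{NA} in the numeric matrix for
#' uninformative genes, while hits to uninformative genes keep their numeric
#' I_scalar. Suitable for heatmap rendering.
#'
#' @param per_sample Named list: sample id -> assessment data frame.
#' @param thresholds The threshold table (defines gene/column order).
#' @return A numeric matrix of class \code{"informativity_matrix"} with a
#'   \code{"status"} character matrix attribute.
#' @export
informativity_matrix <- function(per_sample, thresholds) {
  sids <- names(per_sample)
  if (is.null(sids)) sids <- vapply(per_sample, function(a)
    as.character(unique(a$sample_id))[1], character(1))
  if (anyDuplicated(sids)) {
    stop("duplicate sample id(s): ", paste(sids[duplicated(sids)], collapse = ", "))
  }
  genes <- thresholds$gene_id
  m <- matrix(NA_real_, nrow = length(sids), ncol = length(genes),
              dimnames = list(sids, genes))
  status <- matrix("no_hit", nrow = length(sids), ncol = length(genes),
                   dimnames = list(sids, genes))
  uninf <- thresholds$gene_id[thresholds$gene_class != "informative"]
  status[, colnames(status) %in% uninf] <- "gene_uninformative"
  for (i in seq_along(per_sample)) {
    a <- per_sample[[i]]
    for (j in seq_len(nrow(a))) {
      g <- a$gene_id[j]
      if (!g %in% genes) next
      if (a$hit_class[j] == "gene_uninformative") {
        m[sids[i], g] <- a$I_scalar[j]
        status[sids[i], g] <- "gene_uninformative"
      } else {
        m[sids[i], g] <- a$I_scalar[j]
        status[sids[i], g] <- "hit"
      }
    }
  }
  structure(m, status = status, class = c("informativity_matrix", "matrix"))
}

#' Write assessment, summary and matrix TSV files
#'
#' \code{write_hits_tsv} writes one row per assessed hit;
#' \code{write_summary_tsv} one row per sample; \code{write_matrix_tsv} the
#' samples-by-genes matrix with sentinel strings \code{"."} for no-hit cells
#' and \code{"uninformative"} for uninformative-gene cells without a numeric
#' score. Floats are printed with 2 decimals.
#'
#' @param assessments,summaries,m The objects to write.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_hits_tsv <- function(assessments, path) {
  out <- assessments[, .ASSESSMENT_COLS]
  for (col in c("S_H", "Q_H", "I_S", "I_Q", "I_scalar")) {
    out[[col]] <- sprintf("%.2f", out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  a <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.ASSESSMENT_COLS, names(a))
  if (length(missing)) {
    stop("not a hits table (missing columns: ",
         paste(missing, collapse = ", "), "): ", path)
  }
  a
}

#' @rdname write_hits_tsv
#' @export
write_summary_tsv <- function(summaries, path) {
  out <- summaries
  for (col in c("mean_I", "max_I", "fraction_detected")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.4f", out[[col]]))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_matrix_tsv <- function(m, path) {
  status <- attr(m, "status")
  cells <- matrix(sprintf("%.2f", m), nrow = nrow(m), dimnames = dimnames(m))
  cells[is.na(m) & status == "no_hit"] <- "."
  cells[is.na(m) & status == "gene_uninformative"] <- "uninformative"
  df <- data.frame(sample_id = rownames(m), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
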