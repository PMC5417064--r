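.as_gene_set <- function(x, alphabet) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    read_fasta(x, alphabet)
  } else x
}

#' Fit per-gene taxonomic signal thresholds for a taxon of interest
#'
#' The fitting step of the informativity method. Each annotated gene of the
#' taxon of interest is (1) compared against the proteins of one or more
#' within-taxon relative genomes, recording the most dissimilar within-taxon
#' homolog (S1, Q1), and (2) compared against an out-group protein reference,
#' recording the best out-group hit (S2, Q2). The gene's taxonomic signal
#' threshold is the pair T = (S1 - S2, Q1 - Q2); genes whose threshold
#' exceeds zero are informative markers of the taxon's presence, while genes
#' shared across taxa (e.g. through lateral gene transfer) or unique to the
#' single reference genome are uninformative.
#'
#' @param genes Named \code{DNAStringSet} of the taxon's coding sequences (or
#'   \code{AAStringSet} of proteins), or a path to a FASTA file of nucleotide
#'   coding sequences.
#' @param relatives Named list mapping genome id to an \code{AAStringSet} of
#'   that relative's proteins, or a character vector of protein FASTA paths
#'   (file base names become genome ids).
#' @param outgroup Named \code{AAStringSet} of out-group proteins, or a path
#'   to a protein FASTA file.
#' @param weights Length-2 nonnegative weights \code{(w_S, w_Q)} summing to
#'   1; default equal weighting of identity and coverage.
#' @param params A \code{\link{search_params}} object; its weights are
#'   overridden by \code{weights}.
#' @param mode \code{"scalar"} (threshold test \code{t_scalar > 0}) or
#'   \code{"componentwise"} (\code{dS > 0} and \code{dQ > 0}).
#' @param exclude_genomes Relative-genome ids to drop (e.g. the taxon's own
#'   genome).
#' @return An object of class \code{"informativity"} with components
#'   \code{thresholds} (the per-gene table), \code{genes} (the query set),
#'   \code{weights}, \code{params}, \code{mode}, and \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{coef} (the (dS, dQ, t_scalar)
#'   matrix), \code{predict} (scan a metagenomic sample), \code{plot}.
#' @examples
#' comm <- make_community(community_spec(n_genes = 6, n_contigs = 0,
#'                                       lgt_genes = 2))
#' fit <- informativity(comm$genes_x,
#'                      comm$taxon_proteins[-1],
#'                      comm$outgroup_proteins)
#' summary(fit)
#' @export
informativity <- function(genes, relatives, outgroup,
                          weights = c(0.5, 0.5),
                          params = search_params(weights = weights),
                          mode = c("scalar", "componentwise"),
                          exclude_genomes = NULL) {
  mode <- match.arg(mode)
  params$weights <- weights
  genes <- .as_gene_set(genes, "nucleotide")
  if (is.character(relatives)) {
    ids <- sub("\\.[^.]*$", "", basename(relatives))
    relatives <- setNames(lapply(relatives, read_fasta, alphabet = "protein"),
                          ids)
  }
  outgroup <- .as_gene_set(outgroup, "protein")
  thr <- threshold_table(genes, relatives, outgroup, params, mode,
                         exclude_genomes)
  structure(list(thresholds = thr, genes = genes, weights = weights,
                 params = params, mode = mode, call = match.call()),
            class = "informativity")
}

#' @export
print.informativity <- function(x, ...) {
  tab <- table(factor(x$thresholds$gene_class,
                      levels = c("informative", "uninformative")))
  cat("Taxonomic signal thresholds for", nrow(x$thresholds), "genes\n")
  cat(sprintf("  informative:   %d\n  uninformative: %d\n",
              tab["informative"], tab["uninformative"]))
  cat(sprintf("  weights (w_S, w_Q): (%g, %g); mode: %s\n",
              x$weights[1], x$weights[2], x$mode))
  invisible(x)
}

#' @export
summary.informativity <- function(object, ...) {
  thr <- object$thresholds
  out <- list(
    n_genes = nrow(thr),
    class_counts = table(factor(thr$gene_class,
                                levels = c("informative", "uninformative"))),
    reason_counts = table(thr$reason),
    t_quantiles = stats::quantile(thr$t_scalar,
                                  c(0, 0.25, 0.5, 0.75, 1), names = TRUE),
    weights = object$weights, mode = object$mode)
  class(out) <- "summary.informativity"
  out
}

#' @export
print.summary.informativity <- function(x, ...) {
  cat("Gene thresholds:", x$n_genes, "genes;",
      x$class_counts["informative"], "informative,",
      x$class_counts["uninformative"], "uninformative\n")
  cat("Uninformative reasons:\n")
  print(x$reason_counts)
  cat("t_scalar quantiles:\n")
  print(round(x$t_quantiles, 2))
  invisible(x)
}

#' @export
coef.informativity <- function(object, ...) {
  thr <- object$thresholds
  m <- as.matrix(thr[, c("dS", "dQ", "t_scalar")])
  rownames(m) <- thr$gene_id
  m
}

#' Scan a metagenomic sample against fitted gene thresholds
#'
#' @param object An \code{"informativity"} fit.
#' @param contigs Named \code{DNAStringSet} of assembled contigs, or a FASTA
#'   path.
#' @param sample_id Sample label.
#' @param min_orf_aa Minimum ORF length for the six-frame contig database.
#' @param ... Unused.
#' @return The assessment data frame (class \code{"informativity_scan"})
#'   with the per-sample summary attached as attribute \code{"summary"}.
#' @export
predict.informativity <- function(object, contigs, sample_id = "sample",
                                  min_orf_aa = 20L, ...) {
  contigs <- .as_gene_set(contigs, "nucleotide")
  a <- scan_sample(object$genes, object$thresholds, contigs, object$params,
                   sample_id, object$mode, min_orf_aa)
  attr(a, "summary") <- summarize_sample(a, object$thresholds)
  class(a) <- c("informativity_scan", class(a))
  a
}

#' @export
print.informativity_scan <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Sample '%s': %d/%d informative genes detected (fraction %.2f)\n",
              s$sample_id, s$n_informative_hits, s$n_genes_informative,
              s$fraction_detected))
  if (nrow(x)) {
    print.data.frame(x, row.names = FALSE, digits = 4)
  } else {
    cat("(no hits)\n")
  }
  invisible(x)
}

#' Plot per-gene taxonomic signal thresholds
#'
#' Barplot of the scalar threshold per gene in genome order; uninformative
#' genes are drawn in grey, matching the dark-grey convention of
#' threshold heatmaps.
#'
#' @param x An \code{"informativity"} fit.
#' @param ... Passed to \code{barplot}.
#' @export
plot.informativity <- function(x, ...) {
  thr <- x$thresholds
  cols <- ifelse(thr$gene_class == "informative", "steelblue", "grey40")
  graphics::barplot(thr$t_scalar, names.arg = thr$gene_id, las = 2,
                    col = cols, border = NA,
                    ylab = "scalar threshold t", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
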