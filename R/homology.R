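#' Search parameter set
#'
#' Bundles the scoring scheme, acceptance filters and S/Q weighting used by
#' every homology comparison in the pipeline.
#'
#' @param evalue_max Maximum e-value retained (default 1e-3), applied both
#'   when importing BLAST tabular hits and by the builtin aligner, whose
#'   e-values are approximate Karlin-Altschul statistics (published gapped
#'   BLOSUM62 11/1 constants), not BLAST's exact composition-adjusted ones.
#' @param weights Numeric length-2, nonnegative, summing to 1: the weights
#'   \code{(w_S, w_Q)} applied to percent identity and query coverage when
#'   ranking hits and forming scalar thresholds. Default \code{c(0.5, 0.5)}.
#' @param backend \code{"builtin"} (Smith-Waterman via Biostrings) or
#'   \code{"blast_tab"} (precomputed BLAST tabular input).
#' @param matrix Substitution matrix name (default \code{"BLOSUM62"}).
#' @param gap_open,gap_extend Gap penalties; a gap of length k costs
#'   \code{gap_open + k * gap_extend} (BLAST protein defaults 11 and 1).
#' @param min_aln_len Builtin-backend acceptance floor on aligned columns
#'   (default 15 aa); suppresses spurious micro-alignments that BLAST's
#'   word/e-value filtering would drop.
#' @return An object of class \code{"search_params"}.
#' @export
search_params <- function(evalue_max = 1e-3, weights = c(0.5, 0.5),
                          backend = c("builtin", "blast_tab"),
                          matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          min_aln_len = 15L) {
  backend <- match.arg(backend)
  stopifnot(evalue_max > 0, length(weights) == 2, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  structure(list(evalue_max = evalue_max, weights = as.numeric(weights),
                 backend = backend, matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_aln_len = as.integer(min_aln_len)),
            class = "search_params")
}

.empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), qcov = numeric(),
             aln_len = integer(), q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             bitscore = numeric(), evalue = numeric(), frame = integer(),
             stringsAsFactors = FALSE)
}

.subst_matrix <- function(params) {
  get(data(list = params$matrix, package = "Biostrings",
           envir = environment()))
}

.check_protein <- function(seq, what = "sequence") {
  s <- toupper(as.character(seq))
  if (!nchar(s)) stop(what, " is empty")
  bad <- setdiff(unique(strsplit(s, "")[[1]]), .AA_ALPHABET)
  if (length(bad)) {
    stop(what, " contains non-amino-acid residue(s): ", paste(bad, collapse = ""))
  }
  s
}

# Published gapped Karlin-Altschul parameters for BLOSUM62 with gap costs
# 11 + k (lambda in nats per score unit, K dimensionless). Used to convert
# raw Smith-Waterman scores into approximate bit scores and e-values so the
# builtin backend can be filtered at the same evalue_max as BLAST input.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

# Vectorised core: best local alignment of one query protein against each
# sequence of a protein database. The query plays the pairwiseAlignment
# *subject* role so that one C call scores the whole database; coordinates
# are mapped back so that q_* always refer to the query.
.align_query_to_db <- function(query, db, params, query_id,
                               frame = NA_integer_, filter = TRUE) {
  if (!length(db)) return(.empty_hits())
  mat <- .subst_matrix(params)
  db_plain <- db
  mcols(db_plain) <- NULL
  aln <- Biostrings::pairwiseAlignment(db_plain, Biostrings::AAString(query),
                                       type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = params$gap_open,
                                       gapExtension = params$gap_extend)
  sc <- score(aln)
  len <- nchar(aln)
  bits <- (.KA_LAMBDA * sc - log(.KA_K)) / log(2)
  evalue <- nchar(query) * sum(width(db)) * 2^(-bits)
  keep <- if (filter) {
    which(sc > 0 & len >= params$min_aln_len & evalue <= params$evalue_max)
  } else {
    which(sc > 0)
  }
  if (!length(keep)) return(.empty_hits())
  qs <- start(Biostrings::subject(aln))[keep] - 1L   # 0-based half-open
  qe <- end(Biostrings::subject(aln))[keep]
  ss <- start(Biostrings::pattern(aln))[keep] - 1L
  se <- end(Biostrings::pattern(aln))[keep]
  data.frame(query_id = query_id, subject_id = names(db)[keep],
             pct_identity = Biostrings::pid(aln, type = "PID1")[keep],
             qcov = 100 * (qe - qs) / nchar(query),
             aln_len = len[keep], q_start = qs, q_end = qe,
             s_start = ss, s_end = se,
             bitscore = bits[keep], evalue = evalue[keep],
             frame = frame, stringsAsFactors = FALSE)
}

#' Best local alignment between two protein sequences
#'
#' Smith-Waterman alignment under the configured substitution matrix and gap
#' penalties. Percent identity is computed over aligned columns (gaps
#' included); query coverage is the percent of query residues spanned by the
#' local alignment. \code{bitscore} and \code{evalue} are approximate
#' Karlin-Altschul statistics derived from the raw score with published
#' gapped BLOSUM62 11/1 constants; they are monotone in the raw score and
#' comparable across hits but are not BLAST's exact composition-adjusted
#' values. Unlike \code{\link{homology_search}}, no alignment-length or
#' e-value filter is applied here.
#'
#' @param query,subject Amino-acid strings.
#' @param params A \code{\link{search_params}} object.
#' @return A one-row hit data frame, or \code{NULL} when the optimal local
#'   score is not positive.
#' @examples
#' align_protein_pair("MKVLATTWE" , "MKVLATTWEGGGGG", search_params(min_aln_len = 5))
#' @export
align_protein_pair <- function(query, subject, params = search_params()) {
  q <- .check_protein(query, "query")
  s <- .check_protein(subject, "subject")
  db <- Biostrings::AAStringSet(s)
  names(db) <- "subject"
  hits <- .align_query_to_db(q, db, params, "query", filter = FALSE)
  if (!nrow(hits)) NULL else hits
}

#' Search gene queries against a protein database
#'
#' Nucleotide queries (annotated coding sequences) are translated in-frame
#' before the protein-vs-protein comparison, recording frame 1; protein
#' queries are used as-is. Each (query, subject) pair contributes at most its
#' single best local alignment. Hits are retained when the raw score is
#' positive, the alignment spans at least \code{params$min_aln_len} columns,
#' and the approximate e-value (over the search space of the query against
#' the whole database) is at most \code{params$evalue_max}.
#'
#' @param queries A named \code{DNAStringSet} of coding sequences or a named
#'   \code{AAStringSet} of proteins (or named character vector of proteins).
#' @param db A named \code{AAStringSet} protein database (non-empty).
#' @param params A \code{\link{search_params}} object.
#' @return A hit data frame (zero or more rows) with columns
#'   \code{query_id, subject_id, pct_identity, qcov, aln_len, q_start, q_end,
#'   s_start, s_end, bitscore, evalue, frame}.
#' @export
homology_search <- function(queries, db, params = search_params()) {
  if (!length(db)) stop("protein database is empty")
  if (is.null(names(db))) stop("database sequences must be named")
  nucleotide <- is(queries, "DNAStringSet")
  if (is.character(queries)) queries <- Biostrings::AAStringSet(queries)
  ids <- names(queries)
  if (is.null(ids)) stop("query sequences must be named")
  prots <- if (nucleotide) {
    vapply(seq_along(queries),
           function(i) gsub("\\*+$", "", translate_cds(queries[[i]])),
           character(1))
  } else {
    as.character(queries)
  }
  frame <- if (nucleotide) 1L else NA_integer_
  out <- lapply(seq_along(prots), function(i) {
    .align_query_to_db(prots[i], db, params, ids[i], frame)
  })
  do.call(rbind, c(list(.empty_hits()), out))
}

#' Select the best hit for a query
#'
#' The best hit is the one maximizing the weighted score
#' \code{w_S * pct_identity + w_Q * qcov}; ties are broken by higher bitscore,
#' then lower evalue, then lexicographically smallest subject id, making the
#' choice deterministic and permutation-invariant.
#'
#' @param hits A hit data frame sharing a single \code{query_id}.
#' @param weights Length-2 weights \code{(w_S, w_Q)}.
#' @return The single best one-row hit data frame, or \code{NULL} for empty
#'   input.
#' @export
best_hit <- function(hits, weights = c(0.5, 0.5)) {
  if (is.null(hits) || !nrow(hits)) return(NULL)
  if (length(unique(hits$query_id)) > 1L) {
    stop("best_hit() requires hits for a single query; got: ",
         paste(unique(hits$query_id), collapse = ", "))
  }
  w <- weights[1] * hits$pct_identity + weights[2] * hits$qcov
  ord <- order(-w, -hits$bitscore, hits$evalue,
               as.character(hits$subject_id), method = "radix")
  hits[ord[1L], , drop = FALSE]
}

.BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Parse BLAST tabular output (outfmt 6)
#'
#' Accepts the standard 12-column layout, optionally extended with
#' \code{qlen} (13 columns) or \code{qlen qcovs} (14 columns). Query coverage
#' is taken from \code{qcovs} when present, otherwise computed as
#' \code{100 * (qend - qstart + 1) / qlen}; with neither available it can be
#' supplied through \code{qlen}. BLAST's 1-based inclusive coordinates are
#' converted to 0-based half-open.
#'
#' @param path Path to a tab-separated BLAST result file.
#' @param dialect \code{"auto"} (detect from column count), \code{"std"},
#'   \code{"std_qlen"}, or \code{"std_qlen_qcovs"}.
#' @param qlen Optional named numeric vector of query lengths (protein-space)
#'   used to compute coverage for 12-column files.
#' @param evalue_max Hits with larger e-value are dropped (default keeps all).
#' @return A hit data frame as produced by \code{\link{homology_search}}.
#' @export
parse_blast_tab <- function(path, dialect = c("auto", "std", "std_qlen",
                                              "std_qlen_qcovs"),
                            qlen = NULL, evalue_max = Inf) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(.empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  expected <- switch(dialect, std = 12L, std_qlen = 13L,
                     std_qlen_qcovs = 14L, auto = nf[1])
  if (dialect == "auto" && !expected %in% 12:14) {
    stop("line 1: unsupported column count ", expected,
         " (expected 12, 13, or 14)")
  }
  bad <- which(nf != expected)
  if (length(bad)) {
    stop("line ", bad[1], ": expected ", expected, " columns, found ", nf[bad[1]])
  }
  m <- do.call(rbind, fields)
  cols <- .BLAST6_COLS
  if (expected >= 13L) cols <- c(cols, "qlen")
  if (expected >= 14L) cols <- c(cols, "qcovs")
  colnames(m) <- cols
  num <- function(col) as.numeric(m[, col])
  qstart <- num("qstart"); qend <- num("qend")
  qcov <- if ("qcovs" %in% cols) {
    num("qcovs")
  } else if ("qlen" %in% cols) {
    100 * (qend - qstart + 1) / num("qlen")
  } else if (!is.null(qlen)) {
    ql <- qlen[m[, "qseqid"]]
    if (anyNA(ql)) stop("query length missing for: ",
                        paste(unique(m[is.na(ql), "qseqid"]), collapse = ", "))
    100 * (qend - qstart + 1) / ql
  } else {
    stop("cannot compute query coverage: file has neither qcovs nor qlen ",
         "columns and no qlen vector was supplied")
  }
  hits <- data.frame(query_id = m[, "qseqid"], subject_id = m[, "sseqid"],
                     pct_identity = num("pident"), qcov = qcov,
                     aln_len = as.integer(num("length")),
                     q_start = as.integer(qstart) - 1L,
                     q_end = as.integer(qend),
                     s_start = as.integer(num("sstart")) - 1L,
                     s_end = as.integer(num("send")),
                     bitscore = num("bitscore"), evalue = num("evalue"),
                     frame = NA_integer_, stringsAsFactors = FALSE)
  hits[hits$evalue <= evalue_max, , drop = FALSE]
}

#' Write hits as BLAST tabular (outfmt 6, "std qlen qcovs" dialect)
#'
#' Coordinates are converted back to BLAST's 1-based inclusive convention.
#' \code{mismatch} is reconstructed from identity over aligned columns and
#' \code{gapopen} is written as 0 (per-gap counts are not retained in the hit
#' contract). Numeric fields are written at full precision so that
#' \code{parse_blast_tab()} round-trips them exactly.
#'
#' @param hits A hit data frame.
#' @param path Output path.
#' @param qlen Named numeric vector of query lengths; defaults to lengths
#'   implied by \code{qcov} and the query interval.
#' @return Invisibly, \code{path}.
#' @export
write_blast_tab <- function(hits, path, qlen = NULL) {
  ql <- if (!is.null(qlen)) as.numeric(qlen[hits$query_id])
        else round(100 * (hits$q_end - hits$q_start) / hits$qcov)
  n_id <- round(hits$pct_identity * hits$aln_len / 100)
  m <- cbind(hits$query_id, hits$subject_id,
             as.character(hits$pct_identity), hits$aln_len,
             as.integer(hits$aln_len - n_id), 0L,
             hits$q_start + 1L, hits$q_end, hits$s_start + 1L, hits$s_end,
             as.character(hits$evalue), as.character(hits$bitscore),
             as.character(ql), as.character(hits$qcov))
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}
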