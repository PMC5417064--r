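#' @import Biostrings
#' @importFrom BiocGenerics start end width score
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

.NT_ALPHABET <- strsplit("ACGTURYSWKMBDHVN", "")[[1]]
.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYBXZJUO*", "")[[1]]

#' Read a FASTA file into a validated sequence set
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file. Record identifiers
#' are the first whitespace-delimited token of each header; the remainder of
#' the header is kept as a per-record \code{description} in \code{mcols()}.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either \code{"nucleotide"} or \code{"protein"}; sequences
#'   are validated against the corresponding IUPAC alphabet (ambiguity codes
#'   permitted for nucleotides, \code{X}/\code{*} permitted for proteins).
#' @return A \code{DNAStringSet} or \code{AAStringSet} named by record id, in
#'   file order.
#' @details Records with an empty sequence, a duplicated id, or residues
#'   outside the declared alphabet raise an error naming the offending record.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 hypothetical", "ATGAAA", ">g2", "ATGTTT"), tf)
#' read_fasta(tf, "nucleotide")
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop("FASTA record ", which(!nzchar(ids))[1], " in ", path, " has an empty id")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  empty <- which(width(raw) == 0L)
  if (length(empty)) {
    stop("FASTA record '", ids[empty[1]], "' in ", path, " has an empty sequence")
  }
  seqs <- toupper(as.character(raw))
  allowed <- if (alphabet == "nucleotide") .NT_ALPHABET else .AA_ALPHABET
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), allowed)
    if (length(bad)) {
      stop("record '", ids[i], "' contains residue(s) outside the ", alphabet,
           " alphabet: ", paste(bad, collapse = ""))
    }
  }
  out <- if (alphabet == "nucleotide") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param x A named \code{XStringSet} (or named character vector). Descriptions
#'   in \code{mcols(x)$description}, when present and non-empty, are appended
#'   to the header after a space.
#' @param path Output file path.
#' @param width Line-wrap width (columns), default 60.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named")
  desc <- mcols(x)$description
  headers <- if (!is.null(desc)) ifelse(nzchar(desc), paste(ids, desc), ids) else ids
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- as.character(x)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", headers[i]), con)
    s <- seqs[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.genetic_code <- function(table = 1L) {
  Biostrings::getGeneticCode(as.character(table))
}

#' Translate a nucleotide sequence to protein
#'
#' Standard-code translation of an in-frame coding sequence. Trailing 1-2
#' nucleotides (an incomplete codon) are ignored. Codons containing ambiguity
#' codes are translated when every resolution gives the same amino acid and to
#' \code{'X'} otherwise; stop codons translate to \code{'*'}.
#'
#' @param seq A nucleotide string, \code{DNAString}, or \code{DNAStringSet}.
#' @param table Genetic code table id: 1 (standard, default) or 11 (bacterial).
#' @return A character string (or named character vector for a set input).
#' @examples
#' translate_cds("ATGAAATAA")  # "MK*"
#' translate_cds("ATGNAA")     # "MX"
#' @export
translate_cds <- function(seq, table = 1L) {
  if (is(seq, "DNAStringSet")) {
    return(vapply(seq_along(seq), function(i) translate_cds(seq[[i]], table),
                  character(1), USE.NAMES = FALSE) |> setNames(names(seq)))
  }
  s <- toupper(as.character(seq))
  if (!nchar(s)) stop("cannot translate an empty sequence")
  if (nchar(s) < 3L) stop("sequence shorter than one codon (", nchar(s), " nt)")
  s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     genetic.code = .genetic_code(table),
                                     if.fuzzy.codon = "solve"))
}

#' Six-frame translation of a contig
#'
#' Translates a nucleotide contig in frames +1, +2, +3 of the forward strand
#' and +1, +2, +3 of the reverse complement (reported as -1, -2, -3). Frame
#' offsets are 0-based on the strand being read.
#'
#' @param contig A nucleotide string or \code{DNAString}.
#' @param table Genetic code table id.
#' @return A data frame with columns \code{frame}, \code{offset},
#'   \code{peptide} (six rows; frames with fewer than 3 usable nt yield an
#'   empty peptide).
#' @export
six_frame_translate <- function(contig, table = 1L) {
  s <- toupper(as.character(contig))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  peps <- character(6)
  for (k in seq_along(frames)) {
    f <- frames[k]
    src <- if (f > 0) s else rc
    off <- abs(f) - 1L
    sub <- substr(src, off + 1L, nchar(src))
    peps[k] <- if (nchar(sub) >= 3L) translate_cds(sub, table) else ""
  }
  data.frame(frame = frames, offset = abs(frames) - 1L, peptide = peps,
             stringsAsFactors = FALSE)
}

#' Extract stop-free ORF peptides from all six frames of a contig
#'
#' Each frame translation is split at stop symbols; every stop-free segment of
#' at least \code{min_orf_aa} residues is emitted. Segments are not required
#' to begin with methionine, which keeps partial genes on fragmentary contigs
#' recoverable. Output order is deterministic: frames +1, +2, +3, -1, -2, -3,
#' then left to right within a frame.
#'
#' @param contig A nucleotide string or \code{DNAString}.
#' @param contig_id Identifier recorded with each ORF.
#' @param min_orf_aa Minimum ORF length in amino acids (default 20).
#' @param table Genetic code table id.
#' @return A data frame with columns \code{contig_id}, \code{frame},
#'   \code{start_aa}, \code{end_aa} (0-based half-open coordinates within the
#'   frame peptide), and \code{peptide}. A contig shorter than 3 nt yields
#'   zero rows.
#' @export
six_frame_orfs <- function(contig, contig_id = "contig", min_orf_aa = 20L,
                           table = 1L) {
  stopifnot(min_orf_aa >= 1L)
  empty <- data.frame(contig_id = character(), frame = integer(),
                      start_aa = integer(), end_aa = integer(),
                      peptide = character(), stringsAsFactors = FALSE)
  s <- toupper(as.character(contig))
  if (nchar(s) < 3L) return(empty)
  ft <- six_frame_translate(s, table)
  out <- vector("list", nrow(ft))
  for (k in seq_len(nrow(ft))) {
    pep <- ft$peptide[k]
    if (!nchar(pep)) next
    # split at stops, tracking 0-based coordinates within the frame peptide
    segs <- strsplit(pep, "*", fixed = TRUE)[[1]]
    pos <- 0L
    rows <- list()
    for (seg in segs) {
      if (nchar(seg) >= min_orf_aa) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = contig_id, frame = ft$frame[k],
          start_aa = pos, end_aa = pos + nchar(seg),
          peptide = seg, stringsAsFactors = FALSE)
      }
      pos <- pos + nchar(seg) + 1L
    }
    if (length(rows)) out[[k]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Build the six-frame ORF protein database for a set of contigs
#'
#' The database headers follow \code{"contigID|frame|start-end"} with ORF
#' coordinates in amino acids, 0-based half-open, within the frame peptide.
#'
#' @param contigs A named \code{DNAStringSet} (or named character vector) of
#'   contigs.
#' @param min_orf_aa Minimum ORF length in amino acids.
#' @param table Genetic code table id.
#' @return An \code{AAStringSet} of ORF peptides with provenance columns
#'   (\code{contig_id}, \code{frame}, \code{start_aa}, \code{end_aa}) in
#'   \code{mcols()}.
#' @export
orf_database <- function(contigs, min_orf_aa = 20L, table = 1L) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  ids <- names(contigs)
  if (is.null(ids)) stop("contigs must be named")
  tabs <- lapply(seq_along(contigs), function(i) {
    six_frame_orfs(contigs[[i]], ids[i], min_orf_aa, table)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || !nrow(tab)) {
    db <- Biostrings::AAStringSet()
    mcols(db) <- S4Vectors::DataFrame(contig_id = character(),
                                      frame = integer(),
                                      start_aa = integer(),
                                      end_aa = integer())
    return(db)
  }
  db <- Biostrings::AAStringSet(tab$peptide)
  names(db) <- sprintf("%s|%d|%d-%d", tab$contig_id, tab$frame,
                       tab$start_aa, tab$end_aa)
  mcols(db) <- S4Vectors::DataFrame(tab[c("contig_id", "frame",
                                          "start_aa", "end_aa")])
  db
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq A nucleotide string or \code{DNAString}.
#' @return A character string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(as.character(seq)))))
}
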