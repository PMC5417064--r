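#' Parse CDS features from a GenBank flat file
#'
#' Minimal reader for the FEATURES block of a GenBank-format record: returns
#' one row per CDS feature with its location string and, when annotated, the
#' locus tag, gene name, protein id, and product. Intended for counting and
#' labelling a reference genome's annotated coding regions (e.g. the 93
#' annotated genes of Pseudomonas phage PB1, accession NC_011810).
#'
#' @param path Path to a GenBank flat file (\code{.gb}/\code{.gbk}).
#' @return Data frame: \code{location, locus_tag, gene, protein_id, product}.
#' @export
read_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start)) stop("no FEATURES block found in ", path)
  feat_end <- grep("^(ORIGIN|CONTIG|//)", lines)
  feat_end <- feat_end[feat_end > feat_start[1]]
  feat_end <- if (length(feat_end)) feat_end[1] - 1L else length(lines)
  block <- lines[(feat_start[1] + 1L):feat_end]
  # a feature key starts at column 6; qualifiers/continuations start later
  is_key <- grepl("^ {5}\\S", block)
  key_idx <- which(is_key)
  if (!length(key_idx)) {
    return(data.frame(location = character(), locus_tag = character(),
                      gene = character(), protein_id = character(),
                      product = character(), stringsAsFactors = FALSE))
  }
  keys <- sub("^ {5}(\\S+).*$", "\\1", block[key_idx])
  bounds <- c(key_idx, length(block) + 1L)
  rows <- list()
  for (k in which(keys == "CDS")) {
    chunk <- block[bounds[k]:(bounds[k + 1L] - 1L)]
    txt <- paste(trimws(chunk), collapse = "\n")
    loc_lines <- chunk[!grepl("^\\s+/", chunk)]
    loc <- gsub("\\s", "", paste(sub("^ {5}CDS", "", loc_lines), collapse = ""))
    qual <- function(name) {
      m <- regmatches(txt, regexpr(sprintf('/%s="[^"]*"', name), txt))
      if (length(m)) sub(sprintf('/%s="([^"]*)"', name), "\\1", m)
      else NA_character_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      location = loc, locus_tag = qual("locus_tag"), gene = qual("gene"),
      protein_id = qual("protein_id"), product = qual("product"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(location = character(), locus_tag = character(),
                      gene = character(), protein_id = character(),
                      product = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Download a GenBank record from NCBI
#'
#' Fetches a nucleotide record in GenBank flat-file format through the NCBI
#' E-utilities. Requires network access.
#'
#' @param accession Accession (e.g. \code{"NC_011810"}).
#' @param dest Destination path; defaults to a temp file.
#' @param timeout Download timeout in seconds.
#' @return The path to the downloaded file.
#' @export
fetch_genbank <- function(accession, dest = tempfile(fileext = ".gb"),
                          timeout = 60) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", accession, "&rettype=gb&retmode=text")
  old <- options(timeout = timeout)
  on.exit(options(old))
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  dest
}
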