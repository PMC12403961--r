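#' Sequence sets
#'
#' A `sequence_set` is the container for one species' protein or nucleotide
#' sequences: a named character vector of uppercase residue strings plus a
#' species label and a declared alphabet. Ids must be unique, sequences
#' non-empty, and residues drawn from the declared alphabet plus the masking
#' letter (`X` for protein, `N` for DNA).
#'
#' @param seqs Named character vector of sequences.
#' @param species_label Short species label.
#' @param alphabet `"protein"` or `"dna"`.
#' @return An object of class `sequence_set`.
#' @export
sequence_set <- function(seqs, species_label = "unnamed", alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) > 0) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("all sequences must be named")
    dup <- names(seqs)[duplicated(names(seqs))]
    if (length(dup))
      stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
    seqs <- toupper(seqs)
    if (any(!nzchar(seqs)))
      stop("empty sequence(s): ",
           paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
    ok <- switch(alphabet,
      protein = paste0(paste(AA20, collapse = ""), "X"),
      dna = "ACGTN")
    bad <- grepl(sprintf("[^%s]", ok), seqs)
    if (any(bad))
      stop("sequence(s) with residues outside the ", alphabet, " alphabet: ",
           paste(names(seqs)[bad], collapse = ", "))
  }
  structure(list(species_label = species_label, seqs = seqs, alphabet = alphabet),
            class = "sequence_set")
}

#' @exportS3Method base::print
print.sequence_set <- function(x, ...) {
  cat(sprintf("<sequence_set> %s: %d %s sequence(s)\n",
              x$species_label, length(x$seqs), x$alphabet))
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$seqs)

#' Read a FASTA file into a sequence set
#'
#' Headers are truncated at the first whitespace to form sequence ids
#' (matching common search-tool behaviour); record order is preserved.
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @param species_label Label attached to the set; defaults to the file name.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"),
                       species_label = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(species_label))
    species_label <- sub("\\.[^.]*$", "", basename(path))
  ss <- if (alphabet == "protein") Biostrings::readAAStringSet(path)
        else Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1), 1)
  if (length(seqs) == 0) names(seqs) <- character(0)
  sequence_set(seqs, species_label = species_label, alphabet = alphabet)
}

#' Write a sequence set to FASTA
#'
#' @param x A [sequence_set()].
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "sequence_set"))
  ss <- if (x$alphabet == "protein") Biostrings::AAStringSet(x$seqs)
        else Biostrings::DNAStringSet(x$seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene positions from a BED-like table or GFF3 gene lines
#'
#' Accepts either a 6-column BED-like TSV (`chrom start end gene_id score
#' strand`, 0-based half-open) or a GFF3 file, from which `type == "gene"`
#' lines are taken (1-based inclusive, converted to 0-based half-open on
#' load; `gene_id` from the `ID=` attribute).
#'
#' @param path Input file.
#' @param format `"bed"` or `"gff3"`; default guesses from the extension.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open coordinates).
#' @export
read_gene_positions <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  format <- match.arg(format, c("bed", "gff3"))
  if (format == "bed") {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 4) stop("BED-like file needs >= 4 columns")
    out <- data.frame(gene_id = as.character(tab[[4]]),
                      chrom = as.character(tab[[1]]),
                      start = as.integer(tab[[2]]),
                      end = as.integer(tab[[3]]),
                      strand = if (ncol(tab) >= 6) as.character(tab[[6]]) else "+",
                      stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    f <- f[vapply(f, function(x) length(x) >= 9 && x[3] == "gene", logical(1))]
    if (length(f) == 0)
      return(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    ids <- vapply(f, function(x) {
      m <- regmatches(x[9], regexpr("ID=[^;]+", x[9]))
      if (length(m)) sub("^ID=", "", m) else NA_character_
    }, character(1))
    out <- data.frame(gene_id = ids,
                      chrom = vapply(f, `[`, character(1), 1),
                      start = as.integer(vapply(f, `[`, character(1), 4)) - 1L,
                      end = as.integer(vapply(f, `[`, character(1), 5)),
                      strand = vapply(f, `[`, character(1), 7),
                      stringsAsFactors = FALSE)
  }
  validate_gene_positions(out)
  out
}

validate_gene_positions <- function(pos) {
  stopifnot(is.data.frame(pos),
            all(c("gene_id", "chrom", "start", "end") %in% names(pos)))
  if (nrow(pos) == 0) return(invisible(pos))
  if (any(is.na(pos$start)) || any(pos$start < 0) || any(pos$start >= pos$end))
    stop("gene positions must satisfy 0 <= start < end")
  if (any(!nzchar(pos$chrom))) stop("empty chromosome id")
  invisible(pos)
}

#' Write gene positions as a BED-like table
#'
#' @param pos Gene-position data.frame (0-based half-open).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(pos, path) {
  validate_gene_positions(pos)
  strand <- if ("strand" %in% names(pos)) pos$strand else rep("+", nrow(pos))
  tab <- data.frame(pos$chrom, pos$start, pos$end, pos$gene_id, 0L, strand)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column annotation table (gene to family, gene to GO term, ...)
#'
#' One row per (gene, label) pair; genes may carry several labels.
#'
#' @param path TSV with two columns and no header.
#' @param col_names Names for the two columns.
#' @return data.frame with the two named columns.
#' @export
read_annotation_tsv <- function(path, col_names = c("gene_id", "label")) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- file.info(path)
  if (info$size == 0)
    return(setNames(data.frame(character(), character(),
                               stringsAsFactors = FALSE), col_names))
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2) stop("annotation table needs 2 columns")
  setNames(data.frame(as.character(tab[[1]]), as.character(tab[[2]]),
                      stringsAsFactors = FALSE), col_names)
}
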