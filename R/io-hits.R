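#' Read a 12-column tabular similarity hit table
#'
#' Parses the standard BLAST/DIAMOND tabular dialect (outfmt 6): `query,
#' subject, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore`. Extra columns are ignored with a warning. Subjects are
#' assigned a taxon group (`Metazoa`, `Bacteria`, `Other`) through
#' `taxon_map`; subjects absent from the map are labelled `Other`.
#'
#' @param path Tab-separated hit table.
#' @param taxon_map Named character vector or 2-column data.frame mapping
#'   subject id or subject species to a taxon group. May be `NULL`.
#' @param species_map Optional named character vector mapping subject id to
#'   subject species label (used by the self-hit exclusion filter).
#' @return data.frame of hit records with columns `query_id`, `subject_id`,
#'   `pident`, `length`, `evalue`, `bitscore`, `subject_species`,
#'   `subject_taxon_group`.
#' @export
read_hit_table <- function(path, taxon_map = NULL, species_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (length(ln) == 0) return(empty_hit_table())
  f <- strsplit(ln, "\t", fixed = TRUE)
  ncols <- lengths(f)
  if (any(ncols < 12))
    stop("line ", which(ncols < 12)[1], ": expected 12 tab-separated columns")
  if (any(ncols > 12))
    warning("extra columns beyond the 12-column dialect ignored")
  get <- function(i) vapply(f, `[`, character(1), i)
  ev <- suppressWarnings(as.numeric(get(11)))
  if (anyNA(ev))
    stop("line ", which(is.na(ev))[1], ": non-numeric e-value field")
  if (any(ev < 0))
    stop("line ", which(ev < 0)[1], ": negative e-value")
  hits <- data.frame(
    query_id = get(1), subject_id = get(2),
    pident = suppressWarnings(as.numeric(get(3))),
    length = suppressWarnings(as.integer(get(4))),
    evalue = ev,
    bitscore = suppressWarnings(as.numeric(get(12))),
    stringsAsFactors = FALSE)
  hits$subject_species <- if (!is.null(species_map)) {
    sp <- unname(species_map[hits$subject_id])
    ifelse(is.na(sp), hits$subject_id, sp)
  } else hits$subject_id
  hits$subject_taxon_group <- assign_taxon_group(hits, taxon_map)
  hits
}

empty_hit_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), length = integer(), evalue = numeric(),
             bitscore = numeric(), subject_species = character(),
             subject_taxon_group = character(), stringsAsFactors = FALSE)
}

assign_taxon_group <- function(hits, taxon_map) {
  if (is.null(taxon_map)) return(rep("Other", nrow(hits)))
  if (is.data.frame(taxon_map))
    taxon_map <- setNames(as.character(taxon_map[[2]]),
                          as.character(taxon_map[[1]]))
  grp <- unname(taxon_map[hits$subject_id])
  miss <- is.na(grp)
  grp[miss] <- unname(taxon_map[hits$subject_species[miss]])
  grp[is.na(grp)] <- "Other"
  bad <- !grp %in% c("Metazoa", "Bacteria", "Other")
  if (any(bad))
    stop("taxon group(s) outside {Metazoa, Bacteria, Other}: ",
         paste(unique(grp[bad]), collapse = ", "))
  grp
}

#' Read a 2-column taxon map TSV (subject id or species, taxon group)
#'
#' @param path TSV without header.
#' @return Named character vector.
#' @export
read_taxon_map <- function(path) {
  tab <- read_annotation_tsv(path, c("subject", "group"))
  setNames(tab$group, tab$subject)
}

#' Write hits in the 12-column tabular dialect
#'
#' Columns not tracked internally (pident, coordinates) are written as
#' placeholder values so that the file round-trips through
#' [read_hit_table()].
#'
#' @param hits Hit data.frame as returned by [read_hit_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  n <- nrow(hits)
  pid <- if ("pident" %in% names(hits) && !anyNA(hits$pident)) hits$pident else rep(100, n)
  len <- if ("length" %in% names(hits) && !anyNA(hits$length)) hits$length else rep(0L, n)
  tab <- data.frame(hits$query_id, hits$subject_id, pid, len,
                    0L, 0L, 1L, len, 1L, len,
                    format(hits$evalue, scientific = TRUE, digits = 6),
                    hits$bitscore)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
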