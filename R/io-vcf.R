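#' Read biallelic SNP records (and flagged indels) from a VCF
#'
#' Extracts genotype dosages, site QUAL and per-genotype depth from a VCF
#' 4.x file. Multiallelic SNP sites are excluded from the biallelic set and
#' counted in a skip log. Indel records are retained with `is_indel = TRUE`
#' (their positions feed the downstream indel-flank exclusion filter) but
#' carry no dosages. Positions stay 1-based, as in the VCF.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return Object of class `vcf_records`: list with `sample_ids`, `sites`
#'   (data.frame `chrom, pos, ref, alt, qual, is_indel`), `geno`
#'   (samples x sites dosage matrix in `{0,1,2}`, `NA` = missing), `depth`
#'   (same shape, `NA` when the VCF has no DP), and `skip_log`.
#' @export
read_vcf_biallelic <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(vcf@gt) == 0 || ncol(vcf@gt) < 2)
    stop("VCF carries no genotype columns")
  if (any(!grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"])))
    stop("missing GT in FORMAT field")
  sample_ids <- colnames(vcf@gt)[-1]

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_alleles <- strsplit(alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_alleles)
  is_indel <- nchar(ref) != 1L |
    vapply(alt_alleles, function(a) any(nchar(a) != 1L), logical(1))
  multi_snp <- !is_indel & n_alt > 1L
  keep <- !multi_snp

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)

  dosage_from_gt <- function(g) {
    # count ALT alleles; any '.' allele makes the call missing
    ifelse(is.na(g) | grepl("\\.", g),
           NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }

  geno <- matrix(NA_integer_, nrow = length(sample_ids), ncol = sum(keep),
                 dimnames = list(sample_ids, NULL))
  depth <- matrix(NA_real_, nrow = length(sample_ids), ncol = sum(keep),
                  dimnames = list(sample_ids, NULL))
  kept_idx <- which(keep)
  for (s in seq_along(sample_ids)) {
    g <- gt[kept_idx, s]
    geno[s, ] <- dosage_from_gt(g)
    if (!is.null(dp)) depth[s, ] <- dp[kept_idx, s]
  }
  geno[, is_indel[kept_idx]] <- NA_integer_

  sites <- data.frame(
    chrom = fix[kept_idx, "CHROM"],
    pos = as.integer(fix[kept_idx, "POS"]),
    ref = ref[kept_idx], alt = alt[kept_idx],
    qual = suppressWarnings(as.numeric(fix[kept_idx, "QUAL"])),
    is_indel = is_indel[kept_idx],
    stringsAsFactors = FALSE)
  structure(list(sample_ids = sample_ids, sites = sites, geno = geno,
                 depth = depth,
                 skip_log = c(multiallelic_snp = sum(multi_snp))),
            class = "vcf_records")
}

#' @exportS3Method base::print
print.vcf_records <- function(x, ...) {
  cat(sprintf("<vcf_records> %d sample(s), %d site(s) (%d indel-flagged), skipped multiallelic SNPs: %d\n",
              length(x$sample_ids), nrow(x$sites), sum(x$sites$is_indel),
              x$skip_log[["multiallelic_snp"]]))
  invisible(x)
}

#' Genotype matrix of biallelic SNPs
#'
#' Samples x sites alt-allele dosages in `{0, 1, 2}` with site metadata.
#' After filtering there are no missing entries.
#'
#' @param geno Integer matrix, samples in rows, sites in columns.
#' @param sites data.frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param sample_ids Sample names; default from `rownames(geno)`.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, sample_ids = rownames(geno)) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(sites) == ncol(geno))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(geno)))
  vals <- geno[!is.na(geno)]
  if (length(vals) && any(!vals %in% 0:2))
    stop("genotype dosages must lie in {0, 1, 2}")
  rownames(geno) <- sample_ids
  structure(list(sample_ids = sample_ids, sites = sites, geno = geno),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sample(s) x %d biallelic site(s) on %d chromosome(s)\n",
              length(x$sample_ids), nrow(x$sites),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Write a genotype matrix (plus optional indels) as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT (and DP when supplied) fields, suitable
#' for round-tripping synthetic data through [read_vcf_biallelic()].
#'
#' @param gm A [genotype_matrix()], or a `vcf_records` object.
#' @param path Output file.
#' @param qual Per-site QUAL values (recycled); default `"."`.
#' @param depth Optional samples x sites depth matrix written as DP.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, qual = NULL, depth = NULL) {
  if (inherits(gm, "vcf_records")) {
    sites <- gm$sites; geno <- gm$geno
    if (is.null(qual)) qual <- sites$qual
    if (is.null(depth) && !all(is.na(gm$depth))) depth <- gm$depth
    samples <- gm$sample_ids
  } else {
    stopifnot(inherits(gm, "genotype_matrix"))
    sites <- gm$sites; geno <- gm$geno; samples <- gm$sample_ids
    sites$is_indel <- FALSE
  }
  n_site <- nrow(sites)
  qual_chr <- if (is.null(qual)) rep(".", n_site) else {
    q <- rep(qual, length.out = n_site)
    ifelse(is.na(q), ".", format(q, trim = TRUE, scientific = FALSE))
  }
  gt_str <- matrix("./.", nrow = length(samples), ncol = n_site)
  known <- !is.na(geno)
  gt_str[known] <- c("0/0", "0/1", "1/1")[geno[known] + 1L]
  fmt <- "GT"
  if (!is.null(depth)) {
    fmt <- "GT:DP"
    dp_str <- ifelse(is.na(depth), ".", format(depth, trim = TRUE, scientific = FALSE))
    gt_str[] <- paste(gt_str, dp_str, sep = ":")
  }
  body <- vapply(seq_len(n_site), function(j) {
    paste(c(sites$chrom[j], sites$pos[j], ".", sites$ref[j], sites$alt[j],
            qual_chr[j], "PASS", ".", fmt, gt_str[, j]), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              if (!is.null(depth))
                "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
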