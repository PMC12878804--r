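#' Read phased SNP genotypes from a VCF
#'
#' Extracts biallelic (or multi-allelic) SNP records with fully phased
#' genotypes into a [site_records()] object. A diploid sample `S` with GT
#' `a|b` yields haplotypes `S_0` and `S_1`; haploid-coded columns (as
#' written by tree-sequence exporters) are accepted and yield `S_0`.
#' Records that are not SNPs, or contain missing (`.`) or unphased (`/`)
#' genotypes, are skipped and counted.
#'
#' @param path VCF file (uncompressed or bgzipped; requires the vcfR
#'   package).
#' @return a [site_records()] with attributes `n_skipped_non_snp` and
#'   `n_skipped_genotype`.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_list <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  is_snp <- nchar(ref) == 1L & ref %in% NUCS &
    vapply(alt_list, function(a) length(a) >= 1L && all(nchar(a) == 1L) &&
             all(a %in% NUCS), logical(1))
  n_non_snp <- sum(!is_snp)
  keep <- which(is_snp)
  pos_out <- integer(0)
  chrom_out <- character(0)
  geno_rows <- list()
  n_bad_gt <- 0L
  hap_names <- NULL
  for (r in keep) {
    g <- gt[r, ]
    if (anyNA(g) || any(grepl(".", g, fixed = TRUE)) ||
        any(grepl("/", g, fixed = TRUE))) {
      n_bad_gt <- n_bad_gt + 1L
      next
    }
    parts <- strsplit(g, "|", fixed = TRUE)
    ploidy <- lengths(parts)
    if (any(!ploidy %in% c(1L, 2L))) {
      n_bad_gt <- n_bad_gt + 1L
      next
    }
    idx <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(idx)) {
      n_bad_gt <- n_bad_gt + 1L
      next
    }
    alleles <- c(ref[r], alt_list[[r]])
    if (any(idx + 1L > length(alleles)))
      stop("allele index out of range in record at position ",
           fix[r, "POS"])
    if (is.null(hap_names)) {
      hap_names <- unlist(lapply(seq_along(parts), function(k)
        paste0(colnames(gt)[k], "_", seq_len(ploidy[k]) - 1L)))
    }
    pos_out <- c(pos_out, as.integer(fix[r, "POS"]) - 1L)  # to 0-based
    chrom_out <- c(chrom_out, fix[r, "CHROM"])
    geno_rows[[length(geno_rows) + 1L]] <- alleles[idx + 1L]
  }
  if (!length(geno_rows))
    stop("no usable phased SNP records in ", path)
  geno <- do.call(rbind, geno_rows)
  colnames(geno) <- hap_names
  sr <- site_records(pos_out, geno, chrom = chrom_out)
  attr(sr, "n_skipped_non_snp") <- n_non_snp
  attr(sr, "n_skipped_genotype") <- n_bad_gt
  sr
}

#' Write site records as a phased diploid VCF
#'
#' Consecutive haplotype pairs become diploid samples with phased GT. If
#' `ancestral` is given (named by 1-based position or in site order), the
#' call is written into the standard `AA` INFO field.
#'
#' @param sites a [site_records()].
#' @param path output file.
#' @param ancestral optional character vector of ancestral alleles.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path, ancestral = NULL) {
  geno <- sites$genotypes
  n_hap <- ncol(geno)
  if (n_hap %% 2L != 0L) stop("need an even number of haplotypes")
  samples <- unique(sub("_[01]$", "", colnames(geno)))
  if (length(samples) != n_hap / 2L)
    samples <- paste0("S", seq_len(n_hap / 2L) - 1L)
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- character(length(sites$position))
  for (i in seq_along(sites$position)) {
    row <- geno[i, ]
    alleles <- unique(row)
    ref <- alleles[[1L]]
    alt <- setdiff(alleles, ref)
    if (!length(alt)) alt <- "."
    code <- match(row, c(ref, alt)) - 1L
    gts <- paste(code[seq(1, n_hap, 2)], code[seq(2, n_hap, 2)], sep = "|")
    info <- "."
    if (!is.null(ancestral)) {
      aa <- if (!is.null(names(ancestral)))
        ancestral[[as.character(sites$position[i] + 1L)]]
      else ancestral[[i]]
      if (!is.null(aa) && !is.na(aa)) info <- paste0("AA=", aa)
    }
    lines[i] <- paste(c(sites$chrom[i], sites$position[i] + 1L, ".", ref,
                        paste(alt, collapse = ","), ".", "PASS", info, "GT",
                        gts), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write local genealogies as one newick per line
#'
#' Each line is `<position> <newick>`; branch lengths are time differences
#' in generations, readable back with [read_newick_trees()].
#'
#' @param trees list of `local_tree` (or a `tree_list`).
#' @param positions 0-based positions, one per tree (taken from a
#'   `tree_list` automatically).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick_trees <- function(trees, path, positions = NULL) {
  if (inherits(trees, "tree_list")) {
    positions <- trees$positions
    trees <- trees$trees
  }
  stopifnot(length(trees) == length(positions))
  lines <- vapply(seq_along(trees), function(i) {
    paste(format(positions[[i]], scientific = FALSE),
          ape::write.tree(as_phylo(trees[[i]])))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
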